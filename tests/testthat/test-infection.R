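pitch <- c(0.2, 0.2, 0.5)

test_that("infected fraction hits its trivial extremes and flags empty masks", {
  m <- array(FALSE, c(10, 10, 6)); m[3:8, 3:8, 1:3] <- TRUE
  msk <- seg_mask(m, pitch)
  zero <- infected_fraction(msk, array(0, dim(m)), threshold = 10)
  expect_equal(zero$fraction, 0)
  all_on <- infected_fraction(msk, array(100, dim(m)), threshold = 10)
  expect_equal(all_on$fraction, 1)
  expect_equal(all_on$infected_um3, all_on$total_um3)

  empty <- infected_fraction(seg_mask(array(FALSE, c(4, 4, 4)), pitch),
                             array(0, c(4, 4, 4)), threshold = 10)
  expect_true(empty$undefined)
  expect_true(is.na(empty$fraction))
})

test_that("a fixed threshold makes the fraction respond only to reporter dynamics", {
  m <- array(FALSE, c(10, 10, 6)); m[2:9, 2:9, 1:4] <- TRUE
  msk <- seg_mask(m, pitch)
  mk_rep <- function(p) {
    r <- array(0, dim(m))
    set.seed(99)
    r[m] <- ifelse(runif(sum(m)) < p, 100, 1)
    r
  }
  out <- infection_timeseries(list(msk, msk, msk),
                              lapply(c(0.1, 0.5, 0.9), mk_rep),
                              times = 0:2, threshold = 50)
  expect_equal(out$threshold, rep(50, 3))
  expect_true(all(diff(out$fraction) > 0))
})

test_that("ground-truth infected fractions are recovered from rendered scenes", {
  kern <- seg_params()$kernel
  ref <- mk_infection_scene(0, seed = 21)
  mref <- segment_stack(ref$stack)
  rref <- normalize_reporter(ref$stack, mref, "infection", kernel = kern)
  thr <- infection_threshold(mref, rref, fold = 10)

  ests <- vapply(c(0, 0.3, 1), function(fr) {
    sc <- mk_infection_scene(fr, seed = 22)
    m <- segment_stack(sc$stack)
    r <- normalize_reporter(sc$stack, m, "infection", kernel = kern)
    infected_fraction(m, r, thr)$fraction
  }, numeric(1))
  expect_lt(abs(ests[1] - 0), 0.05)
  expect_lt(abs(ests[2] - 0.3), 0.05)
  expect_lt(abs(ests[3] - 1), 0.05)
  # monotone in the true infected load
  expect_true(all(diff(ests) > 0))
})

test_that("the unimodal guard keeps a phage-free reference from splitting its own noise", {
  sc <- mk_infection_scene(0, seed = 25)
  m <- segment_stack(sc$stack)
  r <- normalize_reporter(sc$stack, m, "infection",
                          kernel = seg_params()$kernel)
  thr <- infection_threshold(m, r)               # otsu + guard
  expect_lt(infected_fraction(m, r, thr)$fraction, 0.02)
})

test_that("peak infection picks maxima per replicate with earliest-time ties", {
  rising <- data.frame(time_h = 0:3, fraction = c(0.1, 0.2, 0.3, 0.6))
  flat <- data.frame(time_h = 0:3, fraction = rep(0.25, 4))
  pk <- peak_infection(list(g1 = list(rising, rising), g2 = list(flat, flat)))
  expect_equal(pk$peaks$peak[pk$peaks$group == "g1"], c(0.6, 0.6))
  expect_equal(pk$peaks$peak_time_h[pk$peaks$group == "g1"], c(3, 3))
  expect_equal(pk$peaks$peak_time_h[pk$peaks$group == "g2"], c(0, 0))
  expect_equal(pk$difference, 0.35)
  expect_error(peak_infection(list(g = list())), "empty group")
})

test_that("a simulated exposure contrast in peak infection is recovered", {
  kern <- seg_params()$kernel
  series <- function(peak, seed) {
    fr <- peak * c(1 / 6, 1 / 2, 1, 2 / 3)
    scenes <- lapply(fr, function(f)
      mk_infection_scene(f, seed = seed, radius = 4, arena = c(12, 12, 6)))
    masks <- lapply(scenes, function(s) segment_stack(s$stack))
    reps <- lapply(seq_along(scenes), function(i)
      normalize_reporter(scenes[[i]]$stack, masks[[i]], "infection",
                         kernel = kern))
    thr <- infection_threshold(masks[[1]], reps[[1]], fold = 10)
    infection_timeseries(masks, reps, times = 0:3, threshold = thr)
  }
  pk <- peak_infection(list(unexposed = lapply(31:32, function(s)
    series(0.6, s)),
    protected = lapply(41:42, function(s) series(0.2, s))))
  expect_lt(abs(pk$difference - 0.4), 0.1)
})
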