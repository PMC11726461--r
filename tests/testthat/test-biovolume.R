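test_that("voxel heights follow the centre convention", {
  expect_equal(voxel_height(0, 0.5), 0.25)
  expect_equal(voxel_height(5, 0.5), 2.75)
  h <- voxel_height(0:20, 0.5)
  expect_true(all(diff(h) > 0))
  expect_error(voxel_height(-1, 0.5), ">= 0")
})

test_that("biovolume is voxel count times voxel volume and is additive over components", {
  pitch <- c(0.2, 0.2, 0.5)
  m <- array(FALSE, c(20, 20, 10))
  m[1:10, 1:10, 1:10] <- TRUE      # 1000 voxels
  expect_equal(biovolume(seg_mask(m, pitch)), 20)
  expect_equal(biovolume(seg_mask(array(FALSE, c(4, 4, 4)), pitch)), 0)

  m2 <- array(FALSE, c(12, 12, 6))
  m2[1:2, 1:2, 1] <- TRUE
  m2[8:9, 8:9, 4:5] <- TRUE
  msk <- seg_mask(m2, pitch)
  cc <- label_components(m2)
  expect_equal(biovolume(msk), sum(cc$sizes) * prod(pitch))
})

test_that("the fraction is 0 below the cutoff, 1 above it, and flagged when empty", {
  pitch <- c(0.2, 0.2, 0.5)
  low <- array(FALSE, c(10, 10, 12)); low[3:6, 3:6, 1:4] <- TRUE
  expect_equal(biofilm_fraction(seg_mask(low, pitch))$fraction, 0)

  high <- array(FALSE, c(10, 10, 12)); high[3:6, 3:6, 8:12] <- TRUE
  expect_equal(biofilm_fraction(seg_mask(high, pitch))$fraction, 1)

  rec <- biofilm_fraction(seg_mask(array(FALSE, c(5, 5, 8)), pitch))
  expect_true(rec$undefined)
  expect_true(is.na(rec$fraction))
})

test_that("the strict cutoff with centre heights breaks boundary ties deterministically", {
  pitch <- c(0.2, 0.2, 0.5)
  m <- array(FALSE, c(4, 4, 8))
  m[1, 1, 6] <- TRUE   # z index 5 (0-based), centre height 2.75 um
  m[1, 1, 7] <- TRUE   # centre height 3.25 um
  rec <- biofilm_fraction(seg_mask(m, pitch), cutoff = 3)
  expect_equal(rec$fraction, 0.5)
  # a cutoff exactly at a centre height excludes that slice (strict >)
  rec2 <- biofilm_fraction(seg_mask(m, pitch), cutoff = 3.25)
  expect_equal(rec2$fraction, 0)
})

test_that("a dense hemisphere reproduces the spherical-cap ratio", {
  hm <- hemisphere_mask(6, c(0.15, 0.15, 0.25))
  fr <- biofilm_fraction(hm, 3)
  expect_lt(abs(fr$fraction - cap_ratio(6, 3)) / cap_ratio(6, 3), 0.01)
})

test_that("the fraction is non-increasing in the cutoff", {
  set.seed(17)
  for (i in 1:8) {
    m <- array(runif(16 * 16 * 12) < 0.2, c(16, 16, 12))
    msk <- seg_mask(m, c(0.2, 0.2, 0.5))
    fr <- vapply(c(0, 1, 2, 3, 4, 5),
                 function(h) biofilm_fraction(msk, h)$fraction, numeric(1))
    expect_true(all(diff(fr) <= 1e-12))
  }
})

test_that("time courses keep one ordered record per timepoint and check shapes", {
  pitch <- c(0.2, 0.2, 0.5)
  mk <- function(n) {
    m <- array(FALSE, c(8, 8, 8)); if (n > 0) m[seq_len(n), 1, 1] <- TRUE
    seg_mask(m, pitch)
  }
  out <- timeseries_metrics(list(mk(4), mk(2), mk(6)), times = c(2, 1, 3))
  expect_equal(nrow(out), 3)
  expect_equal(out$time_h, c(1, 2, 3))
  expect_equal(out$total_um3, c(2, 4, 6) * prod(pitch))

  bad <- seg_mask(array(FALSE, c(4, 4, 4)), pitch)
  expect_error(timeseries_metrics(list(mk(1), bad), c(0, 1)), "shape")
})

test_that("dose-response aggregation reports mean, n-1 SD and n per condition", {
  out <- dose_response(list(unexposed = c(0.2, 0.3, 0.4),
                            high = c(0.7, 0.8, 0.9),
                            low = c(0.5)),
                       doses = c(0, 1e6, 1e3))
  expect_equal(out$condition, c("unexposed", "low", "high"))
  expect_equal(out$mean[1], 0.3)
  expect_equal(out$sd[1], 0.1)
  expect_equal(out$n, c(3L, 1L, 3L))
  expect_true(is.na(out$sd[2]))
  expect_error(dose_response(list()), "non-empty")
  expect_error(dose_response(list(a = numeric(0))), "replicate")
})
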