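pitch <- c(0.2, 0.2, 0.5)

block_mask <- function(dims, ylim, xlim, zlim) {
  m <- array(FALSE, dims)
  m[ylim[1]:ylim[2], xlim[1]:xlim[2], zlim[1]:zlim[2]] <- TRUE
  seg_mask(m, pitch)
}

test_that("cube geometry realizes round(side/pitch) voxels per axis", {
  msk <- block_mask(c(20, 20, 10), c(1, 20), c(1, 20), c(1, 10))
  g <- cube_decompose(msk, side = 1)
  expect_equal(unname(g$meta$cube_vox), c(5L, 5L, 2L))
  expect_equal(unname(g$meta$cube_um), c(1, 1, 1))
  expect_equal(unname(g$meta$grid_dim), c(4L, 4L, 5L))
})

test_that("cube occupancies account for every foreground voxel, including border cubes", {
  set.seed(5)
  m <- array(runif(18 * 23 * 9) < 0.3, c(18, 23, 9))   # ragged extents
  msk <- seg_mask(m, pitch)
  g <- cube_decompose(msk, side = 1)
  expect_equal(sum(g$cubes$n_fg), sum(m))
  expect_equal(sum(g$cubes$n_vox), length(m))
  expect_true(all(g$cubes$occupancy >= 0 & g$cubes$occupancy <= 1))
  # border cubes keep their true (partial) voxel capacity
  expect_true(any(g$cubes$n_vox < prod(g$meta$cube_vox)))
})

test_that("uniform intensity gives every included cube that mean intensity", {
  msk <- block_mask(c(20, 20, 10), c(3, 14), c(3, 14), c(1, 6))
  x <- array(0, c(20, 20, 10)); x[msk$mask] <- 137
  st <- image_stack(list(constitutive = x), pitch)
  g <- cube_decompose(msk, st, side = 1)
  inc <- g$cubes[g$cubes$included, ]
  expect_true(all(abs(inc$mean_constitutive - 137) < 1e-12))
})

test_that("an isolated included cube is its own interface at distance zero", {
  msk <- block_mask(c(10, 10, 6), c(3, 7), c(3, 7), c(2, 3))
  g <- interface_distance(cube_decompose(msk, side = 1))
  inc <- g$cubes[g$cubes$included, ]
  expect_true(nrow(inc) >= 1)
  expect_true(all(is.finite(inc$distance_um)))
  one <- block_mask(c(10, 10, 6), c(1, 5), c(1, 5), c(1, 2))  # single cube
  g1 <- interface_distance(cube_decompose(one, side = 1))
  expect_equal(g1$cubes$distance_um[g1$cubes$included], 0)
})

test_that("a full-footprint column reads distances 0,1,2,... down from its top", {
  # column fills the whole xy arena: the only liquid contact is the top face
  msk <- block_mask(c(10, 10, 24), c(1, 10), c(1, 10), c(1, 20))
  g <- interface_distance(cube_decompose(msk, side = 1))
  inc <- g$cubes[g$cubes$included, ]
  for (z in sort(unique(inc$gz)))
    expect_equal(unique(inc$distance_um[inc$gz == z]), max(inc$gz) - z)
})

test_that("interface distances are invariant under 90-degree rotation about z", {
  m <- array(FALSE, c(20, 20, 8))
  m[3:12, 5:16, 1:5] <- TRUE
  m[4:8, 6:9, 6] <- TRUE
  mr <- array(FALSE, c(20, 20, 8))
  for (k in 1:8) mr[, , k] <- t(m[20:1, , k])     # rotate each slice
  d_of <- function(mm) {
    g <- interface_distance(cube_decompose(seg_mask(mm, c(0.2, 0.2, 0.5)),
                                           side = 1))
    sort(round(g$cubes$distance_um[g$cubes$included], 9))
  }
  expect_equal(d_of(m), d_of(mr))
})

test_that("neighbouring cube distances change by at most one cube pitch", {
  set.seed(23)
  m <- array(FALSE, c(20, 20, 10))
  m[4:16, 4:16, 1:7] <- runif(13 * 13 * 7) < 0.8
  g <- interface_distance(cube_decompose(seg_mask(m, pitch), side = 1))
  cb <- g$cubes[g$cubes$included & is.finite(g$cubes$distance_um), ]
  step <- max(g$meta$cube_um)
  for (i in seq_len(nrow(cb))) {
    nb <- cb[abs(cb$gy - cb$gy[i]) + abs(cb$gx - cb$gx[i]) +
               abs(cb$gz - cb$gz[i]) == 1, ]
    if (nrow(nb) > 0)
      expect_true(all(abs(nb$distance_um - cb$distance_um[i]) <= step + 1e-9))
  }
})

test_that("channel ratios divide cube means and respect the denominator floor", {
  msk <- block_mask(c(20, 20, 10), c(3, 14), c(3, 14), c(1, 6))
  den <- array(0, c(20, 20, 10)); den[msk$mask] <- 200
  num <- den * 2
  st <- image_stack(list(constitutive = den, reporter = num), pitch)
  g <- cube_decompose(msk, st, side = 1)
  g1 <- channel_ratio(g, "reporter", "constitutive")
  expect_true(all(abs(g1$cubes$ratio[g1$cubes$included] - 2) < 1e-12))
  g2 <- channel_ratio(g, "reporter", "reporter")
  expect_true(all(abs(g2$cubes$ratio[g2$cubes$included] - 1) < 1e-12))
  g3 <- channel_ratio(g, "reporter", "constitutive", floor = 500)
  expect_true(all(is.na(g3$cubes$ratio[g3$cubes$included])))
  expect_true(all(g3$cubes$ratio_flagged[g3$cubes$included]))
  expect_error(channel_ratio(g, "missing", "constitutive"), "missing")
})

test_that("kymographs average per distance bin with counts partitioning the cubes", {
  msk <- block_mask(c(20, 20, 12), c(1, 20), c(1, 20), c(1, 10))
  x <- array(0, c(20, 20, 12)); x[msk$mask] <- 100
  st <- image_stack(list(constitutive = x, reporter = x), pitch)
  g <- channel_ratio(interface_distance(cube_decompose(msk, st, side = 1)),
                     "reporter", "constitutive")
  k <- build_kymograph(list(g, g), times = c(0, 1))
  vals <- k$values[k$counts[, 1] > 0, ]
  expect_true(all(abs(vals - 1) < 1e-12))
  expect_equal(colSums(k$counts),
               rep(sum(g$cubes$included & is.finite(g$cubes$distance_um)), 2))
  expect_error(build_kymograph(list(), numeric(0)), "empty")
})

test_that("the count-weighted kymograph mean equals the grand cube mean", {
  set.seed(31)
  m <- array(FALSE, c(20, 20, 10)); m[3:17, 3:17, 1:6] <- TRUE
  msk <- seg_mask(m, pitch)
  den <- array(0, dim(m)); den[m] <- 100
  num <- den * rep(runif(10, 0.5, 2), each = 400)[seq_along(den)]
  st <- image_stack(list(constitutive = den, reporter = num), pitch)
  g <- channel_ratio(interface_distance(cube_decompose(msk, st, side = 1)),
                     "reporter", "constitutive")
  k <- build_kymograph(list(g), times = 0)
  ok <- is.finite(g$cubes$ratio) & is.finite(g$cubes$distance_um) &
    g$cubes$included
  grand <- mean(g$cubes$ratio[ok])
  wmean <- sum(k$values[, 1] * k$counts[, 1], na.rm = TRUE) /
    sum(k$counts[, 1])
  expect_equal(wmean, grand, tolerance = 1e-12)
})

test_that("an imposed linear reporter profile is recovered from the kymograph", {
  sp <- scene_spec(mode = "colony", fill = "solid", colony_radius_um = 6,
                   arena_um = c(16, 16, 8), seed = 11,
                   channels = list(constitutive = list(type = "constitutive"),
                                   reporter = list(type = "reporter",
                                                   profile = c(1, 0.5))))
  sc <- generate_scene(sp)
  bg <- estimate_background(sc$stack, sc$mask)
  g <- channel_ratio(
    interface_distance(cube_decompose(sc$mask, sc$stack, background = bg)),
    "reporter", "constitutive", floor = 10)
  k <- build_kymograph(list(g), times = 0)
  d <- k$bin_edges[-length(k$bin_edges)] + k$bin_width / 2
  ok <- is.finite(k$values[, 1])
  slope <- stats::coef(stats::lm(k$values[ok, 1] ~ d[ok]))[2]
  expect_lt(abs(slope - 0.5) / 0.5, 0.1)
})

test_that("fold change against the first timepoint maps a constant scene to one", {
  msk <- block_mask(c(16, 16, 8), c(1, 16), c(1, 16), c(1, 6))
  x <- array(0, c(16, 16, 8)); x[msk$mask] <- 80
  st <- image_stack(list(constitutive = x, reporter = x), pitch)
  g <- channel_ratio(interface_distance(cube_decompose(msk, st, side = 1)),
                     "reporter", "constitutive")
  k <- kymo_fold_change(build_kymograph(list(g, g, g), times = 0:2))
  expect_true(all(abs(k$values[k$counts > 0] - 1) < 1e-12))
})
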