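test_that("spec invariants are enforced", {
  expect_error(scene_spec(pitch_um = c(0, 0.2, 0.5)), "pitch")
  expect_error(scene_spec(cell_diameter_um = 3, cell_length_um = 2.5),
               "diameter")
  expect_error(scene_spec(mode = "colony", colony_radius_um = 12,
                          arena_um = c(20, 20, 10)), "radius")
  expect_error(scene_spec(arena_um = c(0, 10, 10)), "arena")
  expect_error(scene_spec(background = -1), "amplitude")
  expect_error(scene_spec(channels = list(a = list(type = "nope"))),
               "channel type")
})

test_that("a cell-free noise-free scene is a uniform background with undefined fraction", {
  sp <- scene_spec(mode = "monolayer", n_cells = 0, arena_um = c(8, 8, 4),
                   background = 100, noise = FALSE, seed = 1)
  sc <- generate_scene(sp)
  expect_equal(unique(as.vector(sc$stack$channels$constitutive)), 100)
  expect_equal(sc$truth$total_um3, 0)
  expect_true(sc$truth$undefined)
  expect_true(is.na(sc$truth$fraction))
})

test_that("monolayer ground truth always lies below the 3 um cutoff", {
  for (seed in c(3, 4)) {
    sc <- mk_monolayer(seed = seed, n_cells = 20, arena = c(12, 12, 6))
    expect_equal(sc$truth$above_um3, 0)
    expect_equal(sc$truth$fraction, 0)
    expect_true(all(sc$cells$z + sc$cells$diameter_um / 2 < 3))
  }
})

test_that("identical spec and seed give bit-identical scenes", {
  sp <- scene_spec(mode = "colony", fill = "lattice", colony_radius_um = 4,
                   arena_um = c(12, 12, 6), seed = 77)
  a <- generate_scene(sp); b <- generate_scene(sp)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$mask$mask, b$mask$mask)
  expect_identical(a$cells, b$cells)
})

test_that("rasterized volume converges to the analytic volume as pitch halves", {
  err <- vapply(c(0.2, 0.1), function(p) {
    sc <- generate_scene(scene_spec(mode = "monolayer", n_cells = 15,
                                    arena_um = c(12, 12, 6),
                                    pitch_um = c(p, p, p), seed = 4,
                                    noise = FALSE))
    abs(sc$truth$total_um3 - sc$truth$total_analytic_um3) /
      sc$truth$total_analytic_um3
  }, numeric(1))
  expect_lt(err[2], err[1] * 0.55)   # error halves or better
})

test_that("mask voxels lie within the union of rasterized cells", {
  sc <- mk_colony(seed = 9, radius = 4, arena = c(12, 12, 6))
  # re-rasterize from the per-cell table at the same pitch
  geom <- biofilmr:::grid_geom(sc$spec)
  ras <- biofilmr:::rasterize_cells(sc$cells, geom$dims, geom$pitch)
  expect_identical(sc$mask$mask, ras$mask)
})

test_that("a fully packed hemisphere reaches the spherical-cap fraction", {
  sp <- scene_spec(mode = "colony", fill = "solid", colony_radius_um = 6,
                   arena_um = c(14, 14, 7), pitch_um = c(0.1, 0.1, 0.1),
                   noise = FALSE, seed = 2)
  sc <- generate_scene(sp)
  expect_lt(abs(sc$truth$fraction - cap_ratio(6, 3)) / cap_ratio(6, 3), 0.01)
  expect_lt(abs(sc$truth$above_analytic_um3 -
                  cap_ratio(6, 3) * sc$truth$total_analytic_um3) /
              sc$truth$above_analytic_um3, 1e-6)
})

test_that("unplaceable packings raise an explicit failure", {
  sp <- scene_spec(mode = "monolayer", n_cells = 500,
                   arena_um = c(6, 6, 4), retry_budget = 20, seed = 1)
  expect_error(generate_scene(sp), "packing failure")
})

test_that("floating cells appear in the stack but not in the ground truth", {
  sp <- scene_spec(mode = "monolayer", n_cells = 10, n_floating = 5,
                   arena_um = c(14, 14, 10), seed = 8)
  sc <- generate_scene(sp)
  expect_equal(sum(sc$cells$floating), 5)
  expect_gt(sum(sc$float_mask$mask), 0)
  expect_equal(sum(sc$mask$mask & sc$float_mask$mask), 0)
  # truth counts only surface-attached biomass
  expect_equal(sc$truth$total_um3, sum(sc$mask$mask) * prod(sc$stack$pitch))
})

test_that("time series keep identities, halve volume under 0.5 lysis and grow monotonically", {
  sp <- scene_spec(mode = "colony", fill = "lattice", colony_radius_um = 4.5,
                   arena_um = c(14, 14, 7), seed = 9, noise = FALSE)

  const <- generate_timeseries(sp, time_spec(times = c(0, 1, 2)))
  vols <- vapply(const, function(s) s$truth$total_um3, numeric(1))
  expect_equal(vols, rep(vols[1], 3))
  expect_identical(const[[1]]$cells$cell_id, const[[3]]$cells$cell_id)

  lys <- generate_timeseries(sp, time_spec(times = c(0, 1),
                                           lysis_fraction = c(0, 0.5)))
  n1 <- nrow(lys[[1]]$cells); n2 <- nrow(lys[[2]]$cells)
  expect_equal(n2, n1 - round(0.5 * n1))
  one_cell <- sphero_volume(sp$cell_length_um, sp$cell_diameter_um)
  expect_lt(abs(lys[[2]]$truth$total_analytic_um3 -
                  0.5 * lys[[1]]$truth$total_analytic_um3), one_cell)
  expect_true(all(lys[[2]]$cells$cell_id %in% lys[[1]]$cells$cell_id))

  gr <- generate_timeseries(sp, time_spec(times = c(0, 1, 2),
                                          growth_rate_um_h = 0.75))
  gvols <- vapply(gr, function(s) s$truth$total_um3, numeric(1))
  expect_true(all(diff(gvols) > 0))
})

test_that("time-series validation rejects bad dynamics", {
  expect_error(time_spec(times = c(1, 1, 2)), "strictly increasing")
  expect_error(time_spec(times = c(0, 1), lysis_fraction = c(0, 1.5)),
               "lysis")
  sp <- scene_spec(mode = "monolayer", n_cells = 5, seed = 1)
  expect_error(generate_timeseries(sp, time_spec(0:1, growth_rate_um_h = 1)),
               "growth")
})

test_that("scenes round-trip through TIFF/CSV/JSON exactly and the sidecar seed regenerates them", {
  sc <- mk_colony(seed = 31, radius = 4, arena = c(10, 10, 6), n_floating = 2)
  d <- withr::local_tempdir()
  write_scene(sc, d)
  rd <- read_scene(d)
  expect_identical(as.numeric(rd$stack$channels$constitutive),
                   as.numeric(sc$stack$channels$constitutive))
  expect_identical(rd$mask$mask, sc$mask$mask)
  expect_equal(nrow(rd$cells), nrow(sc$cells))
  expect_equal(unname(rd$stack$pitch), c(0.2, 0.2, 0.5))

  meta <- jsonlite::read_json(file.path(d, "scene_scene.json"))
  sp2 <- sc$spec; sp2$seed <- as.integer(meta$seed)
  again <- generate_scene(sp2)
  expect_identical(again$stack$channels$constitutive,
                   sc$stack$channels$constitutive)
})
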