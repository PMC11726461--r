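# Independent oracles and scene shorthands shared across tests.

# mean filter by direct shift-and-add over the mirror-padded array
brute_mean_filter <- function(x, kernel) {
  d <- dim(x)
  h <- (kernel - 1L) %/% 2L
  pad_idx <- function(n, hh) if (hh == 0L) 1:n else c(hh:1, 1:n, n:(n - hh + 1L))
  xp <- x[pad_idx(d[1], h[1]), pad_idx(d[2], h[2]), pad_idx(d[3], h[3]),
          drop = FALSE]
  acc <- array(0, d)
  for (a in 0:(kernel[1] - 1L)) for (b in 0:(kernel[2] - 1L))
    for (c3 in 0:(kernel[3] - 1L))
      acc <- acc + xp[(a + 1L):(a + d[1]), (b + 1L):(b + d[2]),
                      (c3 + 1L):(c3 + d[3]), drop = FALSE]
  acc / prod(kernel)
}

# grayscale opening by per-offset accumulation (edge-clamped SE)
brute_offset_morph <- function(sl, r, op, init) {
  offs <- disc_offsets(r)
  n1 <- nrow(sl); n2 <- ncol(sl)
  acc <- matrix(init, n1, n2)
  for (i in seq_len(nrow(offs))) {
    dy <- offs[i, 1]; dx <- offs[i, 2]
    r1 <- max(1, 1 - dy):min(n1, n1 - dy)
    c1 <- max(1, 1 - dx):min(n2, n2 - dx)
    acc[r1, c1] <- op(acc[r1, c1], sl[r1 + dy, c1 + dx])
  }
  acc
}

brute_tophat_slice <- function(sl, r) {
  op <- brute_offset_morph(brute_offset_morph(sl, r, pmin, Inf),
                           r, pmax, -Inf)
  out <- sl - op
  out[out < 0] <- 0
  out
}

# per-pixel definition of erosion/dilation, for tiny slices only
pixel_morph <- function(sl, r, fun) {
  offs <- disc_offsets(r)
  out <- sl
  for (y in seq_len(nrow(sl))) for (x in seq_len(ncol(sl))) {
    ys <- y + offs[, 1]; xs <- x + offs[, 2]
    ok <- ys >= 1 & ys <= nrow(sl) & xs >= 1 & xs <= ncol(sl)
    out[y, x] <- fun(sl[cbind(ys[ok], xs[ok])])
  }
  out
}

# exhaustive between-class-variance search over all histogram splits
otsu_exhaustive <- function(counts) {
  n <- length(counts); tot <- sum(counts)
  best <- -Inf; bi <- 1L
  for (k in 1:(n - 1)) {
    c1 <- counts[1:k]; c2 <- counts[(k + 1):n]
    w1 <- sum(c1) / tot; w2 <- 1 - w1
    if (w1 == 0 || w2 == 0) next
    m1 <- sum(c1 * (1:k)) / sum(c1)
    m2 <- sum(c2 * ((k + 1):n)) / sum(c2)
    v <- w1 * w2 * (m1 - m2)^2
    if (v > best) { best <- v; bi <- k }
  }
  bi
}

# spherical-cap volume ratio above height h, by numeric integration
cap_ratio <- function(R, h) {
  stats::integrate(function(z) pi * (R^2 - z^2), h, R)$value /
    ((2 / 3) * pi * R^3)
}

mk_monolayer <- function(seed, n_cells = 25, amplitude = 300,
                         arena = c(16, 16, 8), noise = TRUE) {
  generate_scene(scene_spec(mode = "monolayer", n_cells = n_cells,
                            arena_um = arena, amplitude = amplitude,
                            noise = noise, seed = seed))
}

mk_colony <- function(seed, radius = 5, amplitude = 300,
                      arena = c(16, 16, 8), noise = TRUE, ...) {
  generate_scene(scene_spec(mode = "colony", fill = "lattice",
                            colony_radius_um = radius, arena_um = arena,
                            amplitude = amplitude, noise = noise,
                            seed = seed, ...))
}

mk_infection_scene <- function(frac, seed, radius = 5, arena = c(14, 14, 8)) {
  generate_scene(scene_spec(
    mode = "colony", fill = "lattice", colony_radius_um = radius,
    arena_um = arena, seed = seed,
    channels = list(constitutive = list(type = "constitutive"),
                    infection = list(type = "infection",
                                     infected_fraction = frac,
                                     multiplier = 10, baseline = 1))))
}
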