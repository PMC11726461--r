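#' Specification of a synthetic confocal scene
#'
#' Describes a flow-chamber imaging scenario to be simulated with exact
#' ground truth: surface-attached rod-shaped cells (spherocylinders) as a 2D
#' monolayer, a hemispherical 3D colony, or both; optional free-floating
#' planktonic cells; one or more fluorescence channels (constitutive,
#' depth-dependent ratiometric reporter, or per-cell infection reporter);
#' and Poisson photon shot noise around `background + amplitude * occupancy`.
#'
#' Colonies can be filled three ways: `"lattice"` (dense rectangular lattice
#' of rods with stable lattice identities, leaving sub-µm gaps as in real
#' cell packings), `"random"` (sequential random placement with overlap
#' rejection) or `"solid"` (the dense-biofilm limit: the hemisphere itself
#' is the biomass, with no per-cell resolution).
#'
#' @param arena_um arena size in µm, `(x, y, z)`.
#' @param pitch_um voxel pitch in µm, `(x, y, z)`; the default
#'   0.2 x 0.2 x 0.5 keeps desk-sized stacks, finer pitches (e.g. the
#'   acquisition profile's 0.0632 µm xy) are supported.
#' @param mode `"monolayer"`, `"colony"` or `"mixed"`.
#' @param colony_radius_um hemisphere radius in µm (colony/mixed modes).
#' @param fill colony fill policy: `"lattice"`, `"random"` or `"solid"`.
#' @param cell_length_um rod length tip-to-tip (µm).
#' @param cell_diameter_um rod diameter (µm); must not exceed the length.
#' @param n_cells monolayer/random-colony cell count; `NULL` uses a default
#'   surface coverage (monolayer) or packing density (random colony), and
#'   fills every fitting lattice site (lattice colony).
#' @param lattice_spacing_um lattice spacing `(x, y, z)` in µm (x = along
#'   the cell axis).
#' @param n_floating number of free-floating planktonic cells.
#' @param background background level (photons per voxel).
#' @param amplitude cellular signal amplitude (photons) for the
#'   constitutive channel and default for the others.
#' @param noise draw Poisson shot noise (`TRUE`) or return expected photon
#'   counts (`FALSE`).
#' @param channels named list of channel definitions. Each is a list with
#'   `type` in `"constitutive"`, `"reporter"`, `"infection"`, optional
#'   `amplitude`; reporters take `profile = c(a, b)` for the ratio profile
#'   `r(d) = a + b d` in distance-to-interface d (µm); infection channels
#'   take `infected_fraction`, `multiplier` (signal of infected over
#'   baseline) and `baseline`.
#' @param cutoff_um height cutoff used for the ground-truth fraction.
#' @param retry_budget placement attempts per cell before a packing
#'   failure.
#' @param seed integer random seed.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(arena_um = c(20, 20, 10),
                       pitch_um = c(0.2, 0.2, 0.5),
                       mode = c("colony", "monolayer", "mixed"),
                       colony_radius_um = 6,
                       fill = c("lattice", "random", "solid"),
                       cell_length_um = 2.5, cell_diameter_um = 0.8,
                       n_cells = NULL,
                       lattice_spacing_um = c(3.0, 1.2, 1.3),
                       n_floating = 0L,
                       background = 100, amplitude = 300,
                       noise = TRUE,
                       channels = list(constitutive =
                                         list(type = "constitutive")),
                       cutoff_um = 3, retry_budget = 200L, seed = 1L) {
  mode <- match.arg(mode)
  fill <- match.arg(fill)
  arena_um <- as.numeric(arena_um); pitch_um <- check_pitch(pitch_um)
  if (length(arena_um) != 3L || any(arena_um <= 0))
    stop("invalid spec: arena must be 3 positive extents (um)")
  if (cell_diameter_um > cell_length_um)
    stop("invalid spec: cell diameter exceeds cell length")
  if (cell_diameter_um <= 0) stop("invalid spec: cell diameter must be > 0")
  if (background < 0 || amplitude < 0)
    stop("invalid spec: amplitudes must be >= 0")
  if (mode != "monolayer" && colony_radius_um > arena_um[3L])
    stop("invalid spec: colony radius exceeds arena height")
  for (ch in channels)
    if (!isTRUE(ch$type %in% c("constitutive", "reporter", "infection")))
      stop("invalid channel type")
  structure(list(arena_um = arena_um, pitch_um = pitch_um, mode = mode,
                 colony_radius_um = colony_radius_um, fill = fill,
                 cell_length_um = cell_length_um,
                 cell_diameter_um = cell_diameter_um, n_cells = n_cells,
                 lattice_spacing_um = as.numeric(lattice_spacing_um),
                 n_floating = as.integer(n_floating),
                 background = background, amplitude = amplitude,
                 noise = isTRUE(noise), channels = channels,
                 cutoff_um = cutoff_um,
                 retry_budget = as.integer(retry_budget),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Analytic volume of a spherocylinder
#'
#' @param length_um tip-to-tip length (µm).
#' @param diameter_um diameter (µm).
#' @return volume in µm³.
#' @export
sphero_volume <- function(length_um, diameter_um) {
  r <- diameter_um / 2
  pi * r^2 * (length_um - diameter_um) + 4 / 3 * pi * r^3
}

# run code under a temporary seed, restoring caller RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# unit axis vector from azimuth/elevation
axis_vec <- function(az, el)
  c(cos(el) * cos(az), cos(el) * sin(az), sin(el))

# cap-centre endpoints of the central segment of a cell row
cell_segment <- function(cell) {
  u <- axis_vec(cell$azimuth, cell$elevation)
  h <- (cell$length_um - cell$diameter_um) / 2
  c0 <- c(cell$x, cell$y, cell$z)
  list(a = c0 - h * u, b = c0 + h * u)
}

# minimum distance between two 3D segments (Eberly's clamped quadratic)
segseg_dist <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- 1e-12
  if (a <= eps && e <= eps) return(sqrt(sum(r * r)))
  if (a <= eps) {
    s <- 0; t <- min(1, max(0, f / e))
  } else {
    c_ <- sum(d1 * r)
    if (e <= eps) {
      t <- 0; s <- min(1, max(0, -c_ / a))
    } else {
      b <- sum(d1 * d2); denom <- a * e - b * b
      s <- if (denom > eps) min(1, max(0, (b * f - c_ * e) / denom)) else 0
      t <- (b * s + f) / e
      if (t < 0) {
        t <- 0; s <- min(1, max(0, -c_ / a))
      } else if (t > 1) {
        t <- 1; s <- min(1, max(0, (b - c_) / a))
      }
    }
  }
  v <- (p1 + s * d1) - (p2 + t * d2)
  sqrt(sum(v * v))
}

# distances from point rows P (n x 3) to segment a-b
point_segment_dist <- function(P, a, b) {
  u <- b - a; L2 <- sum(u * u)
  if (L2 < 1e-12) {
    dv <- sweep(P, 2L, a, "-")
    return(sqrt(rowSums(dv * dv)))
  }
  t <- pmin(1, pmax(0, (sweep(P, 2L, a, "-") %*% u) / L2))
  cx <- a[1L] + t * u[1L]; cy <- a[2L] + t * u[2L]; cz <- a[3L] + t * u[3L]
  sqrt((P[, 1L] - cx)^2 + (P[, 2L] - cy)^2 + (P[, 3L] - cz)^2)
}

# voxel grid geometry for a spec
grid_geom <- function(spec) {
  p <- spec$pitch_um
  nvox <- pmax(1L, as.integer(round(spec$arena_um / p)))   # (x, y, z)
  list(dims = c(nvox[2L], nvox[1L], nvox[3L]),             # (y, x, z)
       pitch = p,
       centre = c(spec$arena_um[1L] / 2, spec$arena_um[2L] / 2, 0))
}

# rasterize cell rows into (mask, infected) logical arrays
rasterize_cells <- function(cells, dims, pitch) {
  mask <- array(FALSE, dims)
  infected <- array(FALSE, dims)
  if (is.null(cells) || nrow(cells) == 0L)
    return(list(mask = mask, infected = infected))
  px <- pitch[["x"]]; py <- pitch[["y"]]; pz <- pitch[["z"]]
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    sg <- cell_segment(cl)
    r <- cl$diameter_um / 2
    lo <- pmin(sg$a, sg$b) - r; hi <- pmax(sg$a, sg$b) + r
    ix <- max(1L, floor(lo[1L] / px + 0.5)):min(dims[2L], ceiling(hi[1L] / px + 0.5))
    iy <- max(1L, floor(lo[2L] / py + 0.5)):min(dims[1L], ceiling(hi[2L] / py + 0.5))
    iz <- max(1L, floor(lo[3L] / pz + 0.5)):min(dims[3L], ceiling(hi[3L] / pz + 0.5))
    g <- expand.grid(iy = iy, ix = ix, iz = iz)
    P <- cbind((g$ix - 0.5) * px, (g$iy - 0.5) * py, (g$iz - 0.5) * pz)
    hit <- point_segment_dist(P, sg$a, sg$b) <= r
    if (!any(hit)) next
    li <- g$iy[hit] + (g$ix[hit] - 1L) * dims[1L] +
      (g$iz[hit] - 1L) * dims[1L] * dims[2L]
    mask[li] <- TRUE
    if (isTRUE(cl$infected)) infected[li] <- TRUE
  }
  list(mask = mask, infected = infected)
}

# hemisphere occupancy on the voxel grid (solid colony / oracle helper)
hemisphere_occupancy <- function(radius, dims, pitch, centre) {
  xs <- (seq_len(dims[2L]) - 0.5) * pitch[["x"]] - centre[1L]
  ys <- (seq_len(dims[1L]) - 0.5) * pitch[["y"]] - centre[2L]
  zs <- (seq_len(dims[3L]) - 0.5) * pitch[["z"]]
  r2 <- outer(outer(ys^2, xs^2, "+"), zs^2, "+")
  r2 <= radius^2
}

#' Rasterized solid hemisphere mask
#'
#' The dense-biofilm limit of a hemispherical colony sitting on the
#' substrate: all voxels whose centre lies within `radius` of the
#' hemisphere centre on the glass. Useful as a geometric oracle for
#' height-cutoff statistics.
#'
#' @param radius hemisphere radius (µm).
#' @param pitch voxel pitch (µm, `(x, y, z)`).
#' @param margin_um lateral/vertical clearance around the hemisphere.
#' @return a [seg_mask].
#' @export
hemisphere_mask <- function(radius, pitch = c(0.2, 0.2, 0.5),
                            margin_um = 1) {
  pitch <- check_pitch(pitch)
  side <- 2 * (radius + margin_um)
  nx <- as.integer(ceiling(side / pitch[["x"]]))
  ny <- as.integer(ceiling(side / pitch[["y"]]))
  nz <- as.integer(ceiling((radius + margin_um) / pitch[["z"]]))
  dims <- c(ny, nx, nz)
  centre <- c(nx * pitch[["x"]] / 2, ny * pitch[["y"]] / 2, 0)
  occ <- hemisphere_occupancy(radius, dims, pitch, centre)
  seg_mask(occ, pitch, provenance = list(synthetic = "solid hemisphere",
                                         radius_um = radius))
}

# --- cell placement ---------------------------------------------------------

place_monolayer <- function(spec, n = NULL) {
  r <- spec$cell_diameter_um / 2
  L <- spec$cell_length_um
  if (is.null(n)) {
    n <- spec$n_cells
    if (is.null(n))
      n <- max(1L, round(0.2 * prod(spec$arena_um[1:2]) /
                           (L * spec$cell_diameter_um)))
  }
  placed <- list()
  segs <- list()
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(spec$retry_budget)) {
      az <- stats::runif(1, 0, 2 * pi)
      cx <- stats::runif(1, L / 2, spec$arena_um[1L] - L / 2)
      cy <- stats::runif(1, L / 2, spec$arena_um[2L] - L / 2)
      cand <- data.frame(cell_id = i, x = cx, y = cy, z = r, azimuth = az,
                         elevation = 0, length_um = L,
                         diameter_um = spec$cell_diameter_um,
                         floating = FALSE, infected = FALSE)
      sg <- cell_segment(cand)
      clash <- FALSE
      for (s in segs)
        if (segseg_dist(sg$a, sg$b, s$a, s$b) < spec$cell_diameter_um) {
          clash <- TRUE; break
        }
      if (!clash) {
        placed[[i]] <- cand; segs[[i]] <- sg; ok <- TRUE; break
      }
    }
    if (!ok)
      stop("packing failure: could not place ", n,
           " monolayer cells within the retry budget")
  }
  do.call(rbind, placed)
}

# full lattice of colony cells for radius R; ids are stable lattice indices
lattice_cells <- function(spec, radius, centre) {
  s <- spec$lattice_spacing_um
  r <- spec$cell_diameter_um / 2
  L <- spec$cell_length_um
  h <- (L - spec$cell_diameter_um) / 2
  nmax <- ceiling(radius / pmin(s, radius))
  ii <- seq(-nmax[1L] - 1L, nmax[1L] + 1L)
  jj <- seq(-nmax[2L] - 1L, nmax[2L] + 1L)
  kk <- seq(0L, ceiling(radius / s[3L]) + 1L)
  g <- expand.grid(i = ii, j = jj, k = kk)
  x <- centre[1L] + g$i * s[1L]
  y <- centre[2L] + g$j * s[2L]
  z <- r + g$k * s[3L]
  # capsule inside hemisphere: farthest endpoint + cap radius within R
  ex <- h  # axis along x
  dfar <- sqrt((abs(x - centre[1L]) + ex)^2 + (y - centre[2L])^2 + z^2)
  keep <- dfar + r <= radius & z >= r
  if (!any(keep)) return(NULL)
  idk <- g$i * 1e6 + g$j * 1e3 + g$k     # stable lattice identity
  data.frame(cell_id = idk[keep], x = x[keep], y = y[keep], z = z[keep],
             azimuth = 0, elevation = 0, length_um = L,
             diameter_um = spec$cell_diameter_um,
             floating = FALSE, infected = FALSE)
}

place_colony_random <- function(spec, radius, centre, n = NULL) {
  r <- spec$cell_diameter_um / 2
  L <- spec$cell_length_um
  h <- (L - spec$cell_diameter_um) / 2
  if (is.null(n)) {
    n <- spec$n_cells
    if (is.null(n))
      n <- max(1L, round(0.25 * (2 / 3) * pi * radius^3 /
                           sphero_volume(L, spec$cell_diameter_um)))
  }
  placed <- list(); segs <- list()
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(spec$retry_budget)) {
      rho <- radius * stats::runif(1)^(1 / 3)
      costh <- stats::runif(1)            # upper hemisphere
      phi <- stats::runif(1, 0, 2 * pi)
      sinth <- sqrt(1 - costh^2)
      cx <- centre[1L] + rho * sinth * cos(phi)
      cy <- centre[2L] + rho * sinth * sin(phi)
      cz <- rho * costh
      az <- stats::runif(1, 0, 2 * pi)
      el <- asin(stats::runif(1, -1, 1))
      cand <- data.frame(cell_id = i, x = cx, y = cy, z = max(cz, r),
                         azimuth = az, elevation = el, length_um = L,
                         diameter_um = spec$cell_diameter_um,
                         floating = FALSE, infected = FALSE)
      sg <- cell_segment(cand)
      inside <- max(sqrt(sum((sg$a - c(centre[1:2], 0))^2)),
                    sqrt(sum((sg$b - c(centre[1:2], 0))^2))) + r <= radius &&
        min(sg$a[3L], sg$b[3L]) >= r
      if (!inside) next
      clash <- FALSE
      for (s in segs)
        if (segseg_dist(sg$a, sg$b, s$a, s$b) < spec$cell_diameter_um) {
          clash <- TRUE; break
        }
      if (!clash) {
        placed[[length(placed) + 1L]] <- cand
        segs[[length(segs) + 1L]] <- sg
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop("packing failure: could not place ", n,
           " colony cells within the retry budget")
  }
  do.call(rbind, placed)
}

place_floating <- function(spec, n) {
  if (n <= 0L) return(NULL)
  L <- spec$cell_length_um
  zlo <- min(spec$arena_um[3L] * 0.45, spec$arena_um[3L] - L)
  data.frame(cell_id = -(seq_len(n)),
             x = stats::runif(n, L / 2, spec$arena_um[1L] - L / 2),
             y = stats::runif(n, L / 2, spec$arena_um[2L] - L / 2),
             z = stats::runif(n, zlo, spec$arena_um[3L] - L / 2),
             azimuth = stats::runif(n, 0, 2 * pi),
             elevation = asin(stats::runif(n, -1, 1)),
             length_um = L, diameter_um = spec$cell_diameter_um,
             floating = TRUE, infected = FALSE)
}

place_cells <- function(spec) {
  geom <- grid_geom(spec)
  cells <- switch(
    spec$mode,
    monolayer = place_monolayer(spec),
    colony = switch(spec$fill,
                    lattice = lattice_cells(spec, spec$colony_radius_um,
                                            geom$centre),
                    random = place_colony_random(spec, spec$colony_radius_um,
                                                 geom$centre),
                    solid = NULL),
    mixed = {
      col <- if (spec$fill == "solid") NULL
      else if (spec$fill == "lattice")
        lattice_cells(spec, spec$colony_radius_um, geom$centre)
      else place_colony_random(spec, spec$colony_radius_um, geom$centre)
      mono <- place_monolayer(spec)
      # keep monolayer cells clear of the colony footprint
      keep <- sqrt((mono$x - geom$centre[1L])^2 +
                     (mono$y - geom$centre[2L])^2) >
        spec$colony_radius_um + spec$cell_length_um / 2
      mono <- mono[keep, , drop = FALSE]
      if (nrow(mono) > 0L)
        mono$cell_id <- max(0, col$cell_id, 0) + 1e7 + seq_len(nrow(mono))
      rbind(col, mono)
    })
  if (!is.null(cells)) rownames(cells) <- NULL
  cells
}
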