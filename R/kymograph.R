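#' Decompose a segmented stack into ~1 µm cubes
#'
#' Partitions the voxel grid into axis-aligned cubes with a target physical
#' side length (default 1 µm; the realized voxel counts per axis are
#' `round(side / pitch)`, at least 1). Partial cubes at the domain border are
#' kept with their true occupancy. For every cube the biomass occupancy
#' (foreground voxel fraction) and the mean intensity of each channel over
#' foreground voxels only are recorded. Cubes with occupancy below the
#' inclusion threshold carry no reporter values downstream.
#'
#' @param mask a [seg_mask].
#' @param stack optional [image_stack] aligned to the mask, for intensities.
#' @param side target cube side length in µm.
#' @param include_occupancy minimum occupancy for a cube to be included
#'   (default 0.1).
#' @param background per-channel background level subtracted from the
#'   intensities before averaging (named numeric vector, a single value for
#'   all channels, or 0). Ratiometric readouts require background-corrected
#'   intensities; see [estimate_background].
#' @return an object of class `cube_grid`: list with `cubes` (data.frame:
#'   grid indices `gy, gx, gz` (1-based), centre coordinates `x_um, y_um,
#'   z_um`, `n_vox`, `n_fg`, `occupancy`, `included`, one `mean_<channel>`
#'   column per channel) and `meta` (cube voxel/physical sizes, grid
#'   dimensions, pitch).
#' @export
cube_decompose <- function(mask, stack = NULL, side = 1,
                           include_occupancy = 0.1, background = 0) {
  stopifnot(inherits(mask, "seg_mask"))
  d <- dim(mask$mask)
  p <- mask$pitch                                  # (x, y, z)
  cvox <- pmax(1L, as.integer(round(side / p[c("y", "x", "z")])))
  if (any(side < p[c("y", "x", "z")] / 2))
    stop("cube side smaller than one voxel on some axis")
  names(cvox) <- c("y", "x", "z")
  ng <- as.integer(ceiling(d / cvox))              # grid dims (y, x, z)

  iy <- (seq_len(d[1L]) - 1L) %/% cvox[1L]
  ix <- (seq_len(d[2L]) - 1L) %/% cvox[2L]
  iz <- (seq_len(d[3L]) - 1L) %/% cvox[3L]
  gid <- 1L + outer(outer(iy, ix * ng[1L], "+"), iz * (ng[1L] * ng[2L]), "+")
  gid_v <- as.vector(gid)
  ncube <- prod(ng)

  agg <- function(v) {
    out <- numeric(ncube)
    s <- rowsum(v, gid_v, reorder = FALSE)
    out[as.integer(rownames(s))] <- s[, 1L]
    out
  }
  mvec <- as.numeric(mask$mask)
  n_vox <- agg(rep(1, length(gid_v)))
  n_fg <- agg(mvec)
  occ <- n_fg / n_vox

  g0 <- seq_len(ncube) - 1L
  gy <- g0 %% ng[1L]
  gx <- (g0 %/% ng[1L]) %% ng[2L]
  gz <- g0 %/% (ng[1L] * ng[2L])
  cube_um <- cvox * p[c("y", "x", "z")]            # (y, x, z) physical size
  cubes <- data.frame(
    gy = gy + 1L, gx = gx + 1L, gz = gz + 1L,
    y_um = (gy + 0.5) * cube_um[["y"]],
    x_um = (gx + 0.5) * cube_um[["x"]],
    z_um = (gz + 0.5) * cube_um[["z"]],
    n_vox = n_vox, n_fg = n_fg, occupancy = occ,
    included = occ >= include_occupancy)

  if (!is.null(stack)) {
    stopifnot(inherits(stack, "image_stack"))
    if (!all(stack$dim == d)) stop("mask and stack are not aligned")
    for (ch in names(stack$channels)) {
      bg <- if (length(background) > 1L || !is.null(names(background)))
        background[[ch]] %||% 0 else background
      s <- agg((as.numeric(stack$channels[[ch]]) - bg) * mvec)
      cubes[[paste0("mean_", ch)]] <- ifelse(n_fg > 0, s / n_fg, NA_real_)
    }
  }
  structure(list(cubes = cubes,
                 meta = list(cube_vox = cvox, cube_um = cube_um,
                             grid_dim = ng, pitch = p, side = side,
                             include_occupancy = include_occupancy)),
            class = "cube_grid")
}

#' @export
print.cube_grid <- function(x, ...) {
  cat(sprintf("cube_grid: %d x %d x %d cubes (%.2g x %.2g x %.2g um), %d included\n",
              x$meta$grid_dim[1], x$meta$grid_dim[2], x$meta$grid_dim[3],
              x$meta$cube_um[["x"]], x$meta$cube_um[["y"]],
              x$meta$cube_um[["z"]], sum(x$cubes$included)))
  invisible(x)
}

#' Estimate per-channel background level
#'
#' Median intensity over voxels outside the segmentation mask, per channel.
#' Used to background-correct intensities before ratiometric averaging.
#'
#' @param stack an [image_stack].
#' @param mask a [seg_mask] aligned to the stack.
#' @return named numeric vector, one background level per channel.
#' @export
estimate_background <- function(stack, mask) {
  stopifnot(inherits(stack, "image_stack"), inherits(mask, "seg_mask"))
  if (!all(stack$dim == dim(mask$mask))) stop("mask and stack not aligned")
  bgvox <- !mask$mask
  if (!any(bgvox)) stop("mask covers the whole stack; no background voxels")
  vapply(stack$channels, function(ch) stats::median(ch[bgvox]), numeric(1L))
}

#' Distance of each cube to the biofilm-liquid interface
#'
#' Interface cubes are included cubes that touch the surrounding liquid:
#' cubes with a 6-neighbour (in cube space) that is excluded, looking
#' laterally and upward but not through the substrate-facing face (the glass
#' is not a biofilm-liquid interface). Every included cube is assigned the
#' Euclidean distance (µm, centre to centre) to the nearest interface cube;
#' interface cubes get 0. When the biofilm fills the whole arena there is no
#' interface and all distances are flagged `NA` (`meta$no_interface`).
#'
#' @param grid a [cube_grid].
#' @return the grid with a `distance_um` column added (NA for excluded
#'   cubes).
#' @export
interface_distance <- function(grid) {
  stopifnot(inherits(grid, "cube_grid"))
  ng <- grid$meta$grid_dim
  inc <- array(FALSE, ng)
  inc[cbind(grid$cubes$gy, grid$cubes$gx, grid$cubes$gz)] <-
    grid$cubes$included
  idx <- which(inc, arr.ind = TRUE)
  grid$cubes$distance_um <- NA_real_
  if (nrow(idx) == 0L) return(grid)

  # neighbour directions: lateral and up; not through the substrate face
  dirs <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L),
                c(0L, 1L, 0L), c(0L, -1L, 0L),
                c(0L, 0L, 1L))
  is_iface <- rep(FALSE, nrow(idx))
  for (k in seq_len(nrow(dirs))) {
    nb <- sweep(idx, 2L, dirs[k, ], "+")
    inside <- nb[, 1L] >= 1L & nb[, 1L] <= ng[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= ng[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= ng[3L]
    hit <- inside
    hit[inside] <- !inc[nb[inside, , drop = FALSE]]
    is_iface <- is_iface | hit
  }
  if (!any(is_iface)) {
    grid$meta$no_interface <- TRUE
    return(grid)
  }
  cu <- grid$meta$cube_um                           # (y, x, z)
  pts <- sweep(idx - 0.5, 2L, cu, "*")              # centre coords, um
  ipts <- pts[is_iface, , drop = FALSE]
  dmin <- vapply(seq_len(nrow(pts)), function(i) {
    dv <- sweep(ipts, 2L, pts[i, ], "-")
    sqrt(min(rowSums(dv * dv)))
  }, numeric(1L))
  lin <- idx[, 1L] + (idx[, 2L] - 1L) * ng[1L] +
    (idx[, 3L] - 1L) * ng[1L] * ng[2L]
  pos <- match(lin, grid$cubes$gy + (grid$cubes$gx - 1L) * ng[1L] +
                 (grid$cubes$gz - 1L) * ng[1L] * ng[2L])
  grid$cubes$distance_um[pos] <- dmin
  grid$meta$no_interface <- FALSE
  grid
}

#' Per-cube ratio of two fluorescence channels
#'
#' Ratiometric reporter readout: the per-cube mean intensity of the reporter
#' channel divided by that of a constitutive channel, which cancels biomass
#' density and illumination. Cubes whose denominator mean is at or below a
#' floor (e.g. the background level) are flagged rather than divided.
#'
#' @param grid a [cube_grid] built with intensities.
#' @param numerator,denominator channel names.
#' @param floor denominator floor; cubes at or below it get `NA`.
#' @return the grid with `ratio` and `ratio_flagged` columns.
#' @export
channel_ratio <- function(grid, numerator, denominator, floor = 0) {
  stopifnot(inherits(grid, "cube_grid"))
  nm <- paste0("mean_", numerator); dn <- paste0("mean_", denominator)
  if (is.null(grid$cubes[[nm]])) stop("missing channel: ", numerator)
  if (is.null(grid$cubes[[dn]])) stop("missing channel: ", denominator)
  num <- grid$cubes[[nm]]; den <- grid$cubes[[dn]]
  ok <- grid$cubes$included & is.finite(num) & is.finite(den) & den > floor
  grid$cubes$ratio <- ifelse(ok, num / den, NA_real_)
  grid$cubes$ratio_flagged <- grid$cubes$included & !ok
  grid
}

#' Space-time kymograph of a per-cube observable
#'
#' Averages a per-cube value within distance-to-interface bins for every
#' timepoint: one matrix pixel per (distance bin, timepoint), with the cube
#' count behind each pixel recorded so empty pixels are distinguishable.
#'
#' @param grids list of [cube_grid]s with `distance_um` (and the chosen
#'   value column) computed; all must share cube geometry.
#' @param times numeric timepoints (h), one per grid.
#' @param value name of the cube column to average (default `"ratio"`).
#' @param bin_width distance bin width in µm (default 1).
#' @return object of class `kymograph`: list with `values` (matrix, rows =
#'   distance bins, cols = timepoints; `NA` where no cubes), `counts`,
#'   `bin_edges` (µm), `times`, `value`.
#' @export
build_kymograph <- function(grids, times, value = "ratio", bin_width = 1) {
  if (length(grids) == 0L) stop("empty grid sequence")
  if (length(grids) != length(times)) stop("one time per grid required")
  cu <- grids[[1L]]$meta$cube_um
  for (g in grids) {
    stopifnot(inherits(g, "cube_grid"))
    if (!all(g$meta$cube_um == cu)) stop("grids differ in cube geometry")
    if (is.null(g$cubes$distance_um)) stop("run interface_distance() first")
    if (is.null(g$cubes[[value]])) stop("missing value column: ", value)
  }
  dmax <- suppressWarnings(max(unlist(lapply(grids, function(g)
    g$cubes$distance_um[g$cubes$included])), na.rm = TRUE))
  if (!is.finite(dmax)) dmax <- 0
  nbin <- max(1L, as.integer(ceiling((dmax + 1e-9) / bin_width)))
  edges <- seq(0, nbin * bin_width, by = bin_width)
  vals <- matrix(NA_real_, nbin, length(times))
  cnts <- matrix(0L, nbin, length(times))
  for (j in seq_along(grids)) {
    cb <- grids[[j]]$cubes
    ok <- cb$included & is.finite(cb$distance_um) & is.finite(cb[[value]])
    if (!any(ok)) next
    b <- pmin(nbin, 1L + as.integer(cb$distance_um[ok] %/% bin_width))
    s <- rowsum(cb[[value]][ok], b)
    n <- rowsum(rep(1L, sum(ok)), b)
    rows <- as.integer(rownames(s))
    vals[rows, j] <- s[, 1L] / n[, 1L]
    cnts[rows, j] <- n[, 1L]
  }
  structure(list(values = vals, counts = cnts, bin_edges = edges,
                 times = times, value = value, bin_width = bin_width),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph of '%s': %d distance bins (%.2g um) x %d timepoints\n",
              x$value, nrow(x$values), x$bin_width, length(x$times)))
  invisible(x)
}

#' Fold change of a kymograph relative to the first timepoint
#'
#' Divides every pixel by the value of its distance bin at the first
#' timepoint, so a time-constant scene maps to 1 everywhere. Bins with no
#' cubes at the first timepoint become `NA`.
#'
#' @param kymo a [kymograph].
#' @return a [kymograph] of fold changes.
#' @export
kymo_fold_change <- function(kymo) {
  stopifnot(inherits(kymo, "kymograph"))
  base <- kymo$values[, 1L]
  base[kymo$counts[, 1L] == 0L] <- NA_real_
  kymo$values <- sweep(kymo$values, 1L, base, "/")
  kymo$value <- paste0(kymo$value, "_fold_change")
  kymo
}
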