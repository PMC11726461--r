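#' Generate a synthetic confocal scene with ground truth
#'
#' Places cells according to the [scene_spec], rasterizes them onto the
#' voxel grid, renders every requested fluorescence channel (with Poisson
#' shot noise when enabled) and reports ground truth from both the
#' continuous geometry (analytic spherocylinder volumes) and the rasterized
#' mask (voxel counts), so that downstream segmentation and metrics can be
#' validated exactly.
#'
#' @param spec a [scene_spec].
#' @return an object of class `synthetic_scene`: list with `stack`
#'   ([image_stack]), `mask` (ground-truth [seg_mask], biofilm cells only),
#'   `float_mask` (planktonic cells), `cells` (per-cell table: cell_id, x,
#'   y, z, azimuth, elevation, length_um, diameter_um, floating, infected,
#'   reporter_ratio), `truth` (analytic and voxel-count volumes, the
#'   above-cutoff volume and the true biofilm biovolume fraction; the
#'   fraction is `NA`-flagged when total volume is zero), `spec` and
#'   `seed`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    cells <- place_cells(spec)
    floats <- place_floating(spec, spec$n_floating)
    render_scene(spec, cells, floats, noise_seed = spec$seed + 1L)
  })
}

# shared renderer: rasterization, channels, truth
render_scene <- function(spec, cells, floats, noise_seed) {
  geom <- grid_geom(spec)
  dims <- geom$dims; pitch <- geom$pitch

  # infection flags drawn here so the flag set is part of scene ground truth
  inf_defs <- Filter(function(ch) ch$type == "infection", spec$channels)
  if (length(inf_defs) > 0L && !is.null(cells) && nrow(cells) > 0L) {
    frac <- inf_defs[[1L]]$infected_fraction %||% 0
    n_inf <- round(frac * nrow(cells))
    if (n_inf > 0L)
      cells$infected[sample.int(nrow(cells), n_inf)] <- TRUE
  }

  solid <- spec$mode %in% c("colony", "mixed") && spec$fill == "solid"
  ras <- rasterize_cells(cells, dims, pitch)
  mask <- ras$mask
  if (solid)
    mask <- mask | hemisphere_occupancy(spec$colony_radius_um, dims, pitch,
                                        geom$centre)
  ras_f <- rasterize_cells(floats, dims, pitch)

  # depth below the biofilm-liquid interface (analytic, colony geometry)
  depth <- if (spec$mode %in% c("colony", "mixed")) {
    xs <- (seq_len(dims[2L]) - 0.5) * pitch[["x"]] - geom$centre[1L]
    ys <- (seq_len(dims[1L]) - 0.5) * pitch[["y"]] - geom$centre[2L]
    zs <- (seq_len(dims[3L]) - 0.5) * pitch[["z"]]
    rho <- sqrt(outer(outer(ys^2, xs^2, "+"), zs^2, "+"))
    pmax(spec$colony_radius_um - rho, 0)
  } else array(0, dims)

  if (!is.null(cells) && nrow(cells) > 0L) {
    rho_c <- sqrt((cells$x - geom$centre[1L])^2 +
                    (cells$y - geom$centre[2L])^2 + cells$z^2)
    cells$depth_um <- if (spec$mode %in% c("colony", "mixed"))
      pmax(spec$colony_radius_um - rho_c, 0) else 0
  }

  occ <- mask | ras_f$mask
  channels <- list()
  for (nm in names(spec$channels)) {
    ch <- spec$channels[[nm]]
    A <- ch$amplitude %||% spec$amplitude
    lam <- switch(
      ch$type,
      constitutive = spec$background + A * occ,
      reporter = {
        prof <- ch$profile %||% c(1, 0)
        rfac <- pmax(prof[1L] + prof[2L] * depth, 0)
        if (!is.null(cells) && nrow(cells) > 0L)
          cells$reporter_ratio <- pmax(prof[1L] + prof[2L] * cells$depth_um, 0)
        spec$background + A * rfac * occ
      },
      infection = {
        basel <- ch$baseline %||% 1
        mult <- ch$multiplier %||% 10
        spec$background + A * (basel * occ +
                                 (mult - basel) * ras$infected)
      })
    if (spec$noise) {
      lam_v <- as.numeric(lam)
      lam <- with_seed(noise_seed + match(nm, names(spec$channels)),
                       array(stats::rpois(length(lam_v), lam_v), dims))
    }
    channels[[nm]] <- lam
  }
  if (!is.null(cells) && nrow(cells) > 0L &&
      is.null(cells$reporter_ratio)) cells$reporter_ratio <- NA_real_

  # planktonic cells join the per-cell table, flagged, outside the truth mask
  if (!is.null(floats) && nrow(floats) > 0L) {
    floats$depth_um <- 0
    rep_defs <- Filter(function(ch) ch$type == "reporter", spec$channels)
    floats$reporter_ratio <- if (length(rep_defs) > 0L) {
      prof <- rep_defs[[1L]]$profile %||% c(1, 0)
      max(prof[1L], 0)
    } else NA_real_
    cells <- if (is.null(cells) || nrow(cells) == 0L) floats
    else rbind(cells, floats)
  }

  vox_vol <- prod(pitch)
  nz <- dims[3L]
  heights <- voxel_height(seq_len(nz) - 1L, pitch[["z"]])
  per_slice <- vapply(seq_len(nz), function(k) sum(mask[, , k]), numeric(1L))
  total_vox <- sum(per_slice) * vox_vol
  above_vox <- sum(per_slice[heights > spec$cutoff_um]) * vox_vol
  total_analytic <- if (solid) {
    (2 / 3) * pi * spec$colony_radius_um^3 +
      if (!is.null(cells)) nrow(cells) *
      sphero_volume(spec$cell_length_um, spec$cell_diameter_um) else 0
  } else if (!is.null(cells)) {
    nrow(cells) * sphero_volume(spec$cell_length_um, spec$cell_diameter_um)
  } else 0
  above_analytic <- if (solid && spec$cutoff_um < spec$colony_radius_um) {
    a <- spec$colony_radius_um - spec$cutoff_um
    pi * a^2 * (3 * spec$colony_radius_um - a) / 3
  } else NA_real_

  truth <- list(total_analytic_um3 = total_analytic,
                total_um3 = total_vox, above_um3 = above_vox,
                above_analytic_um3 = above_analytic,
                fraction = if (total_vox > 0) above_vox / total_vox
                else NA_real_,
                undefined = total_vox <= 0,
                cutoff_um = spec$cutoff_um)

  structure(list(stack = image_stack(channels, pitch),
                 mask = seg_mask(mask, pitch,
                                 provenance = list(ground_truth = TRUE)),
                 float_mask = seg_mask(ras_f$mask, pitch),
                 cells = cells, truth = truth, spec = spec,
                 seed = spec$seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene (%s, fill %s): %s cells, %d floating\n",
              x$spec$mode, x$spec$fill,
              if (is.null(x$cells)) "solid-fill" else nrow(x$cells),
              x$spec$n_floating))
  cat(sprintf("  truth: total %.1f um^3 (analytic %.1f), above %.1f, fraction %s\n",
              x$truth$total_um3, x$truth$total_analytic_um3,
              x$truth$above_um3,
              if (x$truth$undefined) "undefined" else
                sprintf("%.3f", x$truth$fraction)))
  invisible(x)
}

#' Time-series specification
#'
#' Dynamics for a sequence of scenes: colony radius growth, phage-induced
#' lysis (a fraction of surviving cells removed at given timepoints) and
#' per-timepoint reporter ratio profiles.
#'
#' @param times strictly increasing timepoints (h).
#' @param growth_rate_um_h colony radius growth rate g in
#'   `R(t) = R0 + g (t - t0)`; lattice or solid colony fill only.
#' @param lysis_fraction fraction of surviving cells removed at each
#'   timepoint (scalar or one value per timepoint, each in \[0, 1\]).
#' @param reporter_profiles optional list of `c(a, b)` reporter profiles,
#'   one per timepoint.
#' @return object of class `time_spec`.
#' @export
time_spec <- function(times, growth_rate_um_h = 0, lysis_fraction = 0,
                      reporter_profiles = NULL) {
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  lysis_fraction <- rep_len(as.numeric(lysis_fraction), length(times))
  if (any(lysis_fraction < 0 | lysis_fraction > 1))
    stop("lysis fractions must be in [0, 1]")
  if (!is.null(reporter_profiles) &&
      length(reporter_profiles) != length(times))
    stop("one reporter profile per timepoint required")
  structure(list(times = times, growth_rate_um_h = growth_rate_um_h,
                 lysis_fraction = lysis_fraction,
                 reporter_profiles = reporter_profiles),
            class = "time_spec")
}

#' Generate a time series of synthetic scenes
#'
#' One [generate_scene]-style scene per timepoint with consistent per-cell
#' identities: colony growth adds lattice cells as the radius grows, lysed
#' cells are removed permanently from geometry and ground truth, and the
#' reporter ratio profile can change per timepoint.
#'
#' @param spec a [scene_spec].
#' @param ts a [time_spec].
#' @return list of `synthetic_scene` objects, one per timepoint.
#' @export
generate_timeseries <- function(spec, ts) {
  stopifnot(inherits(spec, "scene_spec"), inherits(ts, "time_spec"))
  if (ts$growth_rate_um_h != 0 &&
      !(spec$mode %in% c("colony", "mixed") &&
          spec$fill %in% c("lattice", "solid")))
    stop("radius growth requires a lattice- or solid-fill colony")
  if (any(ts$lysis_fraction > 0) && spec$fill == "solid")
    stop("lysis requires resolved cells (lattice or random fill)")

  nt <- length(ts$times)
  radii <- spec$colony_radius_um +
    ts$growth_rate_um_h * (ts$times - ts$times[1L])
  if (any(radii > spec$arena_um[3L]))
    stop("colony outgrows the arena height")
  geom <- grid_geom(spec)

  with_seed(spec$seed, {
    # master cell set at the final radius (stable lattice identities)
    master <- if (spec$mode %in% c("colony", "mixed") &&
                    spec$fill == "lattice") {
      sp_max <- spec; sp_max$colony_radius_um <- max(radii)
      place_cells(sp_max)
    } else place_cells(spec)
    floats <- place_floating(spec, spec$n_floating)

    lysed <- character(0)
    scenes <- vector("list", nt)
    for (i in seq_len(nt)) {
      sp_i <- spec
      sp_i$colony_radius_um <- radii[i]
      if (!is.null(ts$reporter_profiles)) {
        for (nm in names(sp_i$channels))
          if (sp_i$channels[[nm]]$type == "reporter")
            sp_i$channels[[nm]]$profile <- ts$reporter_profiles[[i]]
      }
      cells_i <- master
      if (!is.null(cells_i) && spec$fill == "lattice" &&
            spec$mode %in% c("colony", "mixed")) {
        sg_h <- (spec$cell_length_um - spec$cell_diameter_um) / 2
        dfar <- sqrt((abs(cells_i$x - geom$centre[1L]) + sg_h)^2 +
                       (cells_i$y - geom$centre[2L])^2 + cells_i$z^2) +
          spec$cell_diameter_um / 2
        fits <- dfar <= radii[i] | cells_i$floating
        cells_i <- cells_i[fits, , drop = FALSE]
      }
      if (!is.null(cells_i)) {
        cells_i <- cells_i[!as.character(cells_i$cell_id) %in% lysed, ,
                           drop = FALSE]
        if (ts$lysis_fraction[i] > 0 && nrow(cells_i) > 0L) {
          n_kill <- round(ts$lysis_fraction[i] * nrow(cells_i))
          if (n_kill > 0L) {
            kill <- sample.int(nrow(cells_i), n_kill)
            lysed <- c(lysed, as.character(cells_i$cell_id[kill]))
            cells_i <- cells_i[-kill, , drop = FALSE]
          }
        }
      }
      scenes[[i]] <- render_scene(sp_i, cells_i, floats,
                                  noise_seed = spec$seed + 101L * i)
      scenes[[i]]$time_h <- ts$times[i]
    }
    scenes
  })
}
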