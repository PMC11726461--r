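#' Reporter threshold from a phage-free reference timepoint
#'
#' Otsu threshold (no discount) computed over the infection-reporter
#' intensities of foreground (biomass) voxels, typically at the first
#' phage-free timepoint, to be held fixed over the rest of the series.
#'
#' The threshold is never allowed below `median + guard_k * MAD` of the
#' foreground reporter values: at a phage-free reference the foreground
#' distribution is unimodal (no infected class) and a bare Otsu cut would
#' land inside it, classifying roughly half the uninfected biomass as
#' infected. The guard keeps the threshold above the uninfected
#' distribution while leaving a genuinely bimodal histogram to Otsu.
#'
#' For a reporter with characterized fold induction `F` (known from bulk
#' assays), supplying `fold = F` switches to the midpoint policy instead:
#' threshold = reference median times `(1 + F) / 2`. On normalized
#' (cover-independent) reporter ratios this is the unbiased cut: a voxel
#' mixing infected and uninfected biomass crosses the midpoint exactly when
#' half its biomass is infected, so boundary voxels split evenly.
#'
#' @param mask a [seg_mask] from the constitutive channel.
#' @param reporter 3D array of reporter intensities aligned to the mask.
#' @param bins histogram bins.
#' @param guard_k multiplier on the MAD for the unimodal guard; `-Inf`
#'   disables it.
#' @param fold characterized fold induction of the reporter; when given,
#'   the midpoint policy is used.
#' @return numeric threshold.
#' @export
infection_threshold <- function(mask, reporter, bins = 256L, guard_k = 5,
                                fold = NULL) {
  stopifnot(inherits(mask, "seg_mask"))
  if (!all(dim(reporter) == dim(mask$mask)))
    stop("reporter and mask are not aligned")
  vals <- reporter[mask$mask]
  if (length(vals) == 0L) stop("empty mask: no foreground reporter values")
  if (!is.null(fold)) {
    if (fold <= 1) stop("'fold' must exceed 1")
    return(stats::median(vals) * (1 + fold) / 2)
  }
  otsu <- as.numeric(otsu_threshold(vals, discount = 1, bins = bins))
  max(otsu, stats::median(vals) + guard_k * stats::mad(vals))
}

#' Ratiometric infection-reporter normalization
#'
#' Converts a raw infection-reporter stack into a per-voxel ratio against
#' the constitutive channel: both channels are mean-filtered with the
#' segmentation kernel, background-subtracted, and divided. Because both
#' numerator and denominator scale with the local biomass cover, the ratio
#' is cover-independent: an uninfected voxel sits at the reporter baseline
#' and an infected one at the reporter's fold induction, regardless of how
#' much of the voxel the cell occupies. Voxels whose constitutive excess is
#' at or below `floor` (essentially empty) get ratio 0.
#'
#' @param stack an [image_stack] containing both channels.
#' @param mask a [seg_mask] used to estimate the background levels.
#' @param reporter name of the infection-reporter channel.
#' @param reference name of the constitutive channel.
#' @param kernel mean-filter kernel (use the segmentation kernel).
#' @param floor minimum constitutive excess (photons) for a defined ratio.
#' @return 3D array of per-voxel reporter ratios.
#' @export
normalize_reporter <- function(stack, mask, reporter,
                               reference = "constitutive",
                               kernel = c(5L, 5L, 3L), floor = 5) {
  stopifnot(inherits(stack, "image_stack"))
  bg <- estimate_background(stack, mask)
  num <- mean_filter(stack_channel(stack, reporter), kernel) - bg[[reporter]]
  den <- mean_filter(stack_channel(stack, reference), kernel) - bg[[reference]]
  out <- ifelse(den > floor, num / pmax(den, floor), 0)
  array(out, dim(den))
}

#' Fraction of infected biomass at one timepoint
#'
#' Biovolume-weighted infected fraction: foreground voxels whose
#' infection-reporter intensity exceeds the threshold, divided by all
#' foreground voxels. Per-voxel rather than per-cell, since no single-cell
#' segmentation is performed; the label is carried in the output.
#'
#' @param mask a [seg_mask] from the constitutive channel.
#' @param reporter 3D array of infection-reporter intensities.
#' @param threshold reporter intensity threshold (see
#'   [infection_threshold]).
#' @param time optional timepoint (h).
#' @return one-row `data.frame` (class `infection_record`): `time_h`,
#'   `total_um3`, `infected_um3`, `fraction` (`NA` and `undefined = TRUE`
#'   for an empty mask), `threshold`, `unit = "biovolume"`.
#' @export
infected_fraction <- function(mask, reporter, threshold, time = NA_real_) {
  stopifnot(inherits(mask, "seg_mask"))
  if (!all(dim(reporter) == dim(mask$mask)))
    stop("reporter and mask are not aligned")
  vox_vol <- prod(mask$pitch)
  n_total <- sum(mask$mask)
  n_inf <- sum(mask$mask & reporter > threshold)
  undefined <- n_total == 0L
  structure(data.frame(
    time_h = time,
    total_um3 = n_total * vox_vol,
    infected_um3 = n_inf * vox_vol,
    fraction = if (undefined) NA_real_ else n_inf / n_total,
    threshold = threshold, unit = "biovolume", undefined = undefined),
    class = c("infection_record", "data.frame"))
}

#' Infected-fraction time course
#'
#' Applies [infected_fraction] across a time series with a single threshold
#' held fixed (derived from the first timepoint when not supplied), so the
#' fraction responds only to reporter dynamics, not to per-frame threshold
#' jitter.
#'
#' When `kernel` is given, the reporter stacks are mean-filtered with it
#' before thresholding, so that the per-voxel classification has the same
#' spatial bandwidth as the segmentation mask (whose channel went through
#' the same filter); without this, mask voxels contributed by the smoothing
#' of cell borders carry raw background reporter values and dilute the
#' fraction.
#'
#' @param masks list of [seg_mask]s, one per timepoint.
#' @param reporters list of 3D reporter arrays, one per timepoint.
#' @param times numeric timepoints (h).
#' @param threshold fixed reporter threshold; `NULL` derives it from the
#'   first timepoint via [infection_threshold].
#' @param kernel optional mean-filter kernel applied to the reporters
#'   (typically the segmentation kernel); `NULL` leaves them raw.
#' @return `data.frame` of records ordered by time.
#' @export
infection_timeseries <- function(masks, reporters, times, threshold = NULL,
                                 kernel = NULL) {
  if (length(masks) != length(times) || length(reporters) != length(times))
    stop("masks, reporters and times must have equal length")
  if (length(masks) == 0L) stop("empty series")
  if (!is.null(kernel))
    reporters <- lapply(reporters, mean_filter, kernel = kernel)
  ord <- order(times)
  if (is.null(threshold))
    threshold <- infection_threshold(masks[[ord[1L]]], reporters[[ord[1L]]])
  out <- do.call(rbind, lapply(ord, function(i)
    infected_fraction(masks[[i]], reporters[[i]], threshold,
                      time = times[i])))
  rownames(out) <- NULL
  out
}

#' Peak infection per replicate and group comparison
#'
#' For every replicate time course, the maximum infected fraction over time
#' (ties resolved to the earliest time); then per-group mean, SD and n of
#' the peaks, and -- for exactly two groups -- the two-sided two-sample
#' t-test of the group difference.
#'
#' @param records_by_group named list: group label -> list of replicate
#'   `data.frame`s with columns `time_h` and `fraction`.
#' @param welch use the Welch t-test for the group comparison.
#' @return list of class `peak_infection`: `peaks` (data.frame: group,
#'   replicate, peak, peak_time_h), `groups` (data.frame: group, n, mean,
#'   sd), and for two groups `difference` (mean difference, first minus
#'   second) and `test` (see [ttest_two_sided]).
#' @export
peak_infection <- function(records_by_group, welch = FALSE) {
  if (!is.list(records_by_group) || length(records_by_group) == 0L ||
      is.null(names(records_by_group)))
    stop("'records_by_group' must be a non-empty named list")
  rows <- list()
  for (g in names(records_by_group)) {
    reps <- records_by_group[[g]]
    if (length(reps) == 0L) stop("empty group: ", g)
    for (r in seq_along(reps)) {
      df <- reps[[r]]
      fr <- df$fraction
      if (all(!is.finite(fr))) stop("no finite fractions in group ", g)
      pk <- max(fr, na.rm = TRUE)
      pt <- min(df$time_h[which(fr == pk)])
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, replicate = r, peak = pk, peak_time_h = pt)
    }
  }
  peaks <- do.call(rbind, rows)
  groups <- do.call(rbind, lapply(split(peaks$peak, peaks$group), function(v)
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_)))
  groups <- data.frame(group = rownames(groups), groups, row.names = NULL)
  out <- list(peaks = peaks, groups = groups)
  gl <- names(records_by_group)
  if (length(gl) == 2L) {
    a <- peaks$peak[peaks$group == gl[1L]]
    b <- peaks$peak[peaks$group == gl[2L]]
    out$difference <- mean(a) - mean(b)
    if (length(a) >= 2L && length(b) >= 2L)
      out$test <- tryCatch(ttest_two_sided(a, b, welch = welch),
                           error = function(e)
                             list(statistic = NA_real_, df = NA_real_,
                                  p.value = NA_real_,
                                  method = conditionMessage(e)))
  }
  structure(out, class = "peak_infection")
}

#' @export
print.peak_infection <- function(x, ...) {
  cat("peak infection summary\n")
  print(x$groups)
  if (!is.null(x$difference))
    cat(sprintf("difference of means: %.4g%s\n", x$difference,
                if (!is.null(x$test))
                  sprintf(" (two-sided t-test p = %.3g)", x$test$p.value)
                else ""))
  invisible(x)
}
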