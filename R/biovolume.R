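#' Height of a voxel centre above the substrate
#'
#' The substrate (glass) is the lower face of the first acquired z-slice;
#' voxel heights use the voxel-centre convention, which breaks ties at a
#' height cutoff deterministically.
#'
#' @param z_index 0-based z-slice index (0 = substrate slice).
#' @param pitch_z z voxel pitch in µm.
#' @return height in µm: `(z_index + 0.5) * pitch_z`.
#' @export
voxel_height <- function(z_index, pitch_z) {
  if (any(z_index < 0)) stop("'z_index' must be >= 0")
  if (pitch_z <= 0) stop("'pitch_z' must be > 0")
  (z_index + 0.5) * pitch_z
}

#' Total biovolume of a segmentation mask
#'
#' The volume in µm³ occupied by fluorescent bacterial biomass: the
#' foreground voxel count times the physical voxel volume.
#'
#' @param mask a [seg_mask].
#' @return biovolume in µm³.
#' @export
biovolume <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  sum(mask$mask) * prod(mask$pitch)
}

#' Biofilm biovolume fraction
#'
#' The biovolume at height `H > cutoff` above the substrate divided by the
#' total biovolume. A flat monolayer scores 0; a tall 3D colony approaches
#' 1. The default 3 µm cutoff separates monolayer growth from genuine 3D
#' biofilm architecture. Voxels count as above the cutoff when their centre
#' height strictly exceeds it ([voxel_height]).
#'
#' @param mask a [seg_mask].
#' @param cutoff height cutoff in µm (default 3).
#' @param time optional timepoint in h, echoed into the record.
#' @return a one-row `data.frame` (class `biovolume_record`) with columns
#'   `time_h`, `total_um3`, `above_um3`, `fraction`, `cutoff_um` and
#'   `undefined` (TRUE when total biovolume is zero; `fraction` is then
#'   `NA`, distinguishing "no cells" from "monolayer").
#' @export
biofilm_fraction <- function(mask, cutoff = 3, time = NA_real_) {
  stopifnot(inherits(mask, "seg_mask"))
  vox_vol <- prod(mask$pitch)
  nz <- dim(mask$mask)[3L]
  per_slice <- vapply(seq_len(nz), function(k) sum(mask$mask[, , k]),
                      numeric(1L))
  heights <- voxel_height(seq_len(nz) - 1L, mask$pitch[["z"]])
  total <- sum(per_slice) * vox_vol
  above <- sum(per_slice[heights > cutoff]) * vox_vol
  undefined <- total <= 0
  structure(data.frame(time_h = time, total_um3 = total, above_um3 = above,
                       fraction = if (undefined) NA_real_ else above / total,
                       cutoff_um = cutoff, undefined = undefined),
            class = c("biovolume_record", "data.frame"))
}

#' Biovolume time course
#'
#' One [biofilm_fraction] record per timepoint, ordered by time. All masks
#' must share shape and pitch.
#'
#' @param masks list of [seg_mask] objects.
#' @param times numeric timepoints in h, one per mask.
#' @param cutoff height cutoff in µm.
#' @return `data.frame` of records, one row per timepoint.
#' @export
timeseries_metrics <- function(masks, times, cutoff = 3) {
  if (length(masks) != length(times)) stop("one time per mask required")
  if (length(masks) == 0L) stop("empty mask sequence")
  d1 <- dim(masks[[1L]]$mask); p1 <- masks[[1L]]$pitch
  for (m in masks) {
    stopifnot(inherits(m, "seg_mask"))
    if (!all(dim(m$mask) == d1) || !all(m$pitch == p1))
      stop("masks differ in shape or pitch across timepoints")
  }
  ord <- order(times)
  out <- do.call(rbind, lapply(ord, function(i)
    biofilm_fraction(masks[[i]], cutoff, time = times[i])))
  rownames(out) <- NULL
  out
}

#' Aggregate replicate fractions per condition
#'
#' Per-condition mean, standard deviation (n-1 denominator) and n, for
#' dose-response summaries of independent biological replicates.
#'
#' @param fractions_by_condition named list: condition label -> numeric
#'   vector of replicate values.
#' @param doses optional numeric dose per condition, used for ordering.
#' @return `data.frame` with columns `condition`, `dose`, `n`, `mean`, `sd`
#'   (`NA` for a single replicate), ordered by dose when given.
#' @export
dose_response <- function(fractions_by_condition, doses = NULL) {
  if (!is.list(fractions_by_condition) || length(fractions_by_condition) == 0L)
    stop("'fractions_by_condition' must be a non-empty named list")
  if (is.null(names(fractions_by_condition)))
    stop("conditions must be named")
  for (v in fractions_by_condition)
    if (length(v) < 1L || any(!is.finite(v)))
      stop("every condition needs >= 1 finite replicate value")
  n <- vapply(fractions_by_condition, length, integer(1L))
  out <- data.frame(
    condition = names(fractions_by_condition),
    dose = if (is.null(doses)) NA_real_ else as.numeric(doses),
    n = n,
    mean = vapply(fractions_by_condition, mean, numeric(1L)),
    sd = vapply(fractions_by_condition,
                function(v) if (length(v) > 1L) stats::sd(v) else NA_real_,
                numeric(1L)),
    row.names = NULL)
  if (!is.null(doses)) out <- out[order(out$dose), , drop = FALSE]
  rownames(out) <- NULL
  out
}
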