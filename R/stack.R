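#' Multi-channel 3D image stack
#'
#' Container for one timepoint's voxel grid: one or more channels stored as
#' 3D arrays with dimensions `(y, x, z)` (matching TIFF pages read as z-slices
#' of row-major images), together with the physical voxel pitch in micrometres.
#' The first z-slice is the substrate (glass) plane.
#'
#' @param channels a 3D numeric array, or a named list of 3D arrays of equal
#'   dimension. Unnamed single arrays are stored under channel name
#'   `"constitutive"`.
#' @param pitch numeric length-3 voxel pitch in µm, in order `(x, y, z)`.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(channels, pitch) {
  if (is.array(channels) && length(dim(channels)) == 3L)
    channels <- list(constitutive = channels)
  if (!is.list(channels) || length(channels) == 0L)
    stop("'channels' must be a 3D array or a non-empty named list of 3D arrays")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    names(channels) <- paste0("ch", seq_along(channels))
  d <- dim(channels[[1L]])
  for (ch in channels) {
    if (!is.array(ch) || length(dim(ch)) != 3L || !all(dim(ch) == d))
      stop("all channels must be 3D arrays of identical dimension")
  }
  pitch <- check_pitch(pitch)
  structure(list(channels = channels, pitch = pitch, dim = d),
            class = "image_stack")
}

check_pitch <- function(pitch) {
  pitch <- as.numeric(pitch)
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  if (length(pitch) != 3L || any(!is.finite(pitch)) || any(pitch <= 0))
    stop("voxel pitch must be 3 positive finite values (x, y, z), in um")
  names(pitch) <- c("x", "y", "z")
  pitch
}

#' @export
print.image_stack <- function(x, ...) {
  d <- x$dim
  cat(sprintf("image_stack: %d x %d x %d voxels (y,x,z), %d channel(s)\n",
              d[1], d[2], d[3], length(x$channels)))
  cat(sprintf("  channels: %s\n", paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  pitch:    %.4g x %.4g x %.4g um (x,y,z)\n",
              x$pitch[1], x$pitch[2], x$pitch[3]))
  invisible(x)
}

#' Extract one channel from an image stack
#'
#' @param stack an [image_stack].
#' @param channel channel name or index; `NULL` picks `"constitutive"` when
#'   present, otherwise the first channel.
#' @return a 3D numeric array.
#' @export
stack_channel <- function(stack, channel = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(channel)) {
    channel <- if ("constitutive" %in% names(stack$channels))
      "constitutive" else 1L
  }
  ch <- stack$channels[[channel]]
  if (is.null(ch)) stop("channel not found: ", channel)
  ch
}

#' Binary segmentation mask
#'
#' A logical voxel grid aligned to its source [image_stack], carrying the
#' voxel pitch and the provenance of the parameters that produced it.
#'
#' @param mask logical (or coercible) 3D array; `TRUE` marks biomass.
#' @param pitch voxel pitch in µm `(x, y, z)`.
#' @param params the [seg_params] used, or `NULL`.
#' @param provenance named list of realized values (thresholds etc.).
#' @return an object of class `seg_mask`.
#' @export
seg_mask <- function(mask, pitch, params = NULL, provenance = list()) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("'mask' must be a 3D array")
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, pitch = check_pitch(pitch), params = params,
                 provenance = provenance),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  d <- dim(x$mask)
  nf <- sum(x$mask)
  cat(sprintf("seg_mask: %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], nf, 100 * nf / length(x$mask)))
  cat(sprintf("  biovolume: %.2f um^3\n", biovolume(x)))
  if (!is.null(x$provenance$threshold_used))
    cat(sprintf("  threshold: %.4g (otsu x discount %.4g, floor %.4g)\n",
                x$provenance$threshold_used,
                x$provenance$threshold_otsu %||% NA_real_,
                x$provenance$threshold_floor %||% NA_real_))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
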