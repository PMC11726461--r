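#' Segmentation parameters
#'
#' Bundles every tunable of the biomass segmentation chain with the defaults
#' used for flow-chamber biofilm stacks: a 5x5x3 voxel mean filter, a 5.5 µm
#' top-hat disk applied per xy-slice, an Otsu threshold discounted by 0.2,
#' and suppression of detached components below one cell volume.
#'
#' @param kernel mean-filter kernel in voxels `(y, x, z)`; odd, >= 1.
#' @param tophat_radius_um top-hat disk radius in µm; the voxel radius is
#'   derived from the in-plane pitch at run time.
#' @param discount Otsu discount factor in (0, 1].
#' @param bins histogram bins for the Otsu threshold.
#' @param suppress enable floating-cell suppression.
#' @param min_volume_um3 minimum volume for detached components (µm³).
#' @param connectivity component connectivity, 6 or 26.
#' @param noise_floor enable the robust noise-floor guard: the threshold is
#'   never allowed below `median + floor_k * MAD` of the enhanced image, so
#'   a stack containing no signal (only shot noise) yields an empty mask
#'   instead of thresholding inside the noise.
#' @param floor_k multiplier on the MAD for the noise floor.
#' @return an object of class `seg_params`.
#' @export
seg_params <- function(kernel = c(5L, 5L, 3L), tophat_radius_um = 5.5,
                       discount = 0.2, bins = 256L, suppress = TRUE,
                       min_volume_um3 = 1.3, connectivity = 26L,
                       noise_floor = TRUE, floor_k = 5) {
  kernel <- as.integer(kernel)
  if (length(kernel) != 3L || any(kernel < 1L) || any(kernel %% 2L == 0L))
    stop("'kernel' must be 3 odd integers >= 1")
  if (tophat_radius_um <= 0) stop("'tophat_radius_um' must be > 0")
  if (discount <= 0 || discount > 1) stop("'discount' must be in (0, 1]")
  structure(list(kernel = kernel, tophat_radius_um = tophat_radius_um,
                 discount = discount, bins = as.integer(bins),
                 suppress = isTRUE(suppress),
                 min_volume_um3 = min_volume_um3,
                 connectivity = as.integer(connectivity),
                 noise_floor = isTRUE(noise_floor), floor_k = floor_k),
            class = "seg_params")
}

#' Segment biomass in a fluorescence z-stack
#'
#' Full segmentation chain for the constitutive (or stain) channel:
#' mean filter, per-slice white top-hat enhancement, discounted Otsu
#' threshold, then floating-cell suppression on the resulting objects. All
#' realized values (the Otsu threshold found, the noise floor, the voxel
#' disk radius) are echoed into the mask's provenance.
#'
#' A stack with no intensity variation is treated as signal-free: the result
#' is an empty mask with a warning, since absence of signal should not
#' produce biomass.
#'
#' @param stack an [image_stack] (or 3D array, with `pitch` supplied).
#' @param params a [seg_params].
#' @param channel channel to segment; defaults to `"constitutive"` or the
#'   first channel.
#' @param pitch voxel pitch, only when `stack` is a bare array.
#' @return a [seg_mask].
#' @export
segment_stack <- function(stack, params = seg_params(), channel = NULL,
                          pitch = NULL) {
  if (is.array(stack) && length(dim(stack)) == 3L) {
    if (is.null(pitch)) stop("supply 'pitch' when 'stack' is a bare array")
    stack <- image_stack(stack, pitch)
  }
  stopifnot(inherits(stack, "image_stack"), inherits(params, "seg_params"))
  x <- stack_channel(stack, channel)

  if (diff(range(x)) == 0) {
    warning("stack has no intensity variation; returning an empty mask")
    return(seg_mask(array(FALSE, dim(x)), stack$pitch, params,
                    list(empty_input = TRUE)))
  }

  xm <- mean_filter(x, params$kernel)
  r_vox <- tophat_radius_vox(params$tophat_radius_um, stack$pitch)
  # a field of view narrower than the physical disk still gets the largest
  # disk that fits; recorded in provenance
  r_max <- (min(dim(x)[1:2]) - 1L) %/% 2L
  r_vox <- min(r_vox, r_max)
  xt <- tophat_enhance(xm, r_vox)

  thr_otsu <- otsu_threshold(xt, discount = params$discount,
                             bins = params$bins)
  floor_thr <- if (params$noise_floor)
    stats::median(xt) + params$floor_k * stats::mad(xt) else -Inf
  thr <- max(as.numeric(thr_otsu), floor_thr)

  m <- seg_mask(xt > thr, stack$pitch, params,
                list(threshold_otsu = attr(thr_otsu, "otsu"),
                     threshold_discounted = as.numeric(thr_otsu),
                     threshold_floor = floor_thr,
                     threshold_used = thr,
                     tophat_radius_vox = r_vox,
                     kernel = params$kernel))
  if (params$suppress)
    m <- suppress_floating_cells(m, params$min_volume_um3,
                                 params$connectivity)
  m
}
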