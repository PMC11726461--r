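#' Write a synthetic scene to disk
#'
#' Writes one multi-page TIFF per channel (pages = z-slices, row-major y,x;
#' 32-bit float, photon counts divided by a power-of-two scale recorded in
#' the sidecar so the round trip is exact), the ground-truth mask as an
#' 8-bit TIFF, the per-cell table as CSV and a JSON sidecar with the voxel
#' pitch, seed, intensity scales, axis declaration and ground-truth
#' volumes.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @param name file stem (default `"scene"`).
#' @return invisibly, the named list of files written.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- list()
  scales <- list()
  for (nm in names(scene$stack$channels)) {
    f <- file.path(dir, paste0(name, "_", nm, ".tif"))
    sc <- write_stack_tiff(scene$stack$channels[[nm]], f)
    files[[paste0("channel_", nm)]] <- f
    scales[[nm]] <- sc
  }
  fmask <- file.path(dir, paste0(name, "_mask.tif"))
  write_mask_tiff(scene$mask$mask, fmask)
  files$mask <- fmask

  fcsv <- file.path(dir, paste0(name, "_cells.csv"))
  cells <- scene$cells
  if (is.null(cells))
    cells <- data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                        z = numeric(0), azimuth = numeric(0),
                        elevation = numeric(0), length_um = numeric(0),
                        diameter_um = numeric(0), floating = logical(0),
                        infected = logical(0), reporter_ratio = numeric(0))
  utils::write.csv(cells, fcsv, row.names = FALSE)
  files$cells <- fcsv

  fjson <- file.path(dir, paste0(name, "_scene.json"))
  spec_echo <- scene$spec
  class(spec_echo) <- NULL
  sidecar <- list(pitch_um = as.list(scene$stack$pitch),
                  axes = "pages are z-slices from the substrate up; each page row-major (y, x)",
                  seed = scene$seed,
                  intensity_scale = scales,
                  truth = scene$truth,
                  spec = spec_echo)
  jsonlite::write_json(sidecar, fjson, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files$sidecar <- fjson
  invisible(files)
}

# photon-count TIFF writer; returns the intensity scale used.
# Integer counts up to 65535 are stored as 16-bit samples (exact round
# trip); anything else falls back to 32-bit samples, quantized by the
# writer to 1/2^32 of the scale.
write_stack_tiff <- function(arr, path) {
  mx <- max(arr, 1)
  if (all(arr == round(arr)) && mx <= 65535) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- 2^ceiling(log2(mx))
    bits <- 32L
  }
  pages <- lapply(seq_len(dim(arr)[3L]), function(k) arr[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  scale
}

write_mask_tiff <- function(mask, path) {
  pages <- lapply(seq_len(dim(mask)[3L]), function(k) mask[, , k] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}

read_tiff_array <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1L]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr * scale
}

#' Read an image stack from TIFF files
#'
#' Reads one or more single-channel multi-page TIFFs (pages = z) into an
#' [image_stack]. The voxel pitch comes from the JSON sidecar when present;
#' an explicit `pitch` argument always wins (a conflict is reported with a
#' warning).
#'
#' @param paths character vector of TIFF paths, optionally named by channel
#'   role (names default to file stems).
#' @param pitch optional voxel pitch override (µm, `(x, y, z)`).
#' @param sidecar optional path to a scene JSON sidecar; defaults to a
#'   `*_scene.json` next to the first TIFF when one exists.
#' @return an [image_stack].
#' @export
read_stack <- function(paths, pitch = NULL, sidecar = NULL) {
  if (length(paths) == 0L) stop("no input files")
  for (p in paths) if (!file.exists(p)) stop("unreadable file: ", p)
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    names(paths) <- sub("^.*_", "", tools::file_path_sans_ext(basename(paths)))
  if (is.null(sidecar)) {
    guess <- file.path(dirname(paths[[1L]]),
                       paste0(sub("_[^_]+$", "",
                                  tools::file_path_sans_ext(basename(paths[[1L]]))),
                              "_scene.json"))
    if (file.exists(guess)) sidecar <- guess
  }
  meta <- if (!is.null(sidecar) && file.exists(sidecar))
    jsonlite::read_json(sidecar) else NULL
  meta_pitch <- if (!is.null(meta$pitch_um))
    unlist(meta$pitch_um)[c("x", "y", "z")] else NULL
  if (is.null(pitch)) {
    if (is.null(meta_pitch))
      stop("voxel pitch unavailable: no sidecar and no 'pitch' override")
    pitch <- meta_pitch
  } else if (!is.null(meta_pitch) &&
               !isTRUE(all.equal(unname(check_pitch(pitch)),
                                 unname(as.numeric(meta_pitch))))) {
    warning("pitch override differs from sidecar metadata; using the override")
  }
  channels <- lapply(seq_along(paths), function(i) {
    sc <- meta$intensity_scale[[names(paths)[i]]] %||% 1
    read_tiff_array(paths[[i]], as.numeric(sc))
  })
  names(channels) <- names(paths)
  image_stack(channels, pitch)
}

#' Re-read a written synthetic scene
#'
#' Reconstructs the stack, ground-truth mask, per-cell table and truth
#' volumes from the files written by [write_scene].
#'
#' @param dir directory containing the files.
#' @param name file stem used at write time.
#' @return list with `stack`, `mask`, `cells`, `truth`, `sidecar`.
#' @export
read_scene <- function(dir, name = "scene") {
  fjson <- file.path(dir, paste0(name, "_scene.json"))
  if (!file.exists(fjson)) stop("missing sidecar: ", fjson)
  meta <- jsonlite::read_json(fjson)
  pitch <- unlist(meta$pitch_um)[c("x", "y", "z")]
  chfiles <- list.files(dir, paste0("^", name, "_.*\\.tif$"),
                        full.names = TRUE)
  chfiles <- chfiles[!grepl("_mask\\.tif$", chfiles)]
  names(chfiles) <- sub(paste0("^", name, "_"), "",
                        tools::file_path_sans_ext(basename(chfiles)))
  stack <- read_stack(chfiles, pitch = pitch, sidecar = fjson)
  mask_arr <- read_tiff_array(file.path(dir, paste0(name, "_mask.tif"))) > 0.5
  cells <- utils::read.csv(file.path(dir, paste0(name, "_cells.csv")))
  list(stack = stack,
       mask = seg_mask(mask_arr, pitch,
                       provenance = list(ground_truth = TRUE)),
       cells = cells,
       truth = meta$truth, sidecar = meta)
}
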