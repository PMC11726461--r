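#' Label 3D connected components
#'
#' Connected-component labelling of a binary voxel grid under 6- or
#' 26-connectivity, via run-length encoding along the first array dimension
#' and union-find over runs in adjacent columns.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (face neighbours) or 26 (face, edge and corner).
#' @return list with `labels` (integer array, 0 = background, components
#'   numbered from 1 in first-voxel order), `n` (component count) and
#'   `sizes` (voxel count per component).
#' @export
label_components <- function(mask, connectivity = 26L) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("'mask' must be a 3D logical array")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  d <- dim(mask)
  labels <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0L)
    return(list(labels = labels, n = 0L, sizes = integer(0)))

  # runs of consecutive foreground voxels along dim 1 within one (x,z) column
  col_of <- (idx - 1L) %/% d[1L]          # 0-based combined (x,z) column id
  y_of <- (idx - 1L) %% d[1L]             # 0-based y
  new_run <- c(TRUE, diff(idx) != 1L | diff(col_of) != 0L)
  run_id <- cumsum(new_run)
  nrun <- run_id[length(run_id)]
  rs <- y_of[new_run]                      # run start y (0-based)
  re <- y_of[c(new_run[-1L], TRUE)]        # run end y
  rcol <- col_of[new_run]
  rx <- rcol %% d[2L]                      # 0-based x
  rz <- rcol %/% d[2L]                     # 0-based z

  parent <- seq_len(nrun)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # runs grouped by column for neighbour lookup
  runs_by_col <- split(seq_len(nrun), rcol)
  ext <- if (connectivity == 26L) 1L else 0L
  offs <- if (connectivity == 26L)
    list(c(-1L, 0L), c(0L, -1L), c(-1L, -1L), c(1L, -1L))
  else
    list(c(-1L, 0L), c(0L, -1L))

  for (r in seq_len(nrun)) {
    for (o in offs) {
      nx <- rx[r] + o[1L]; nz <- rz[r] + o[2L]
      if (nx < 0L || nx >= d[2L] || nz < 0L) next
      nb <- runs_by_col[[as.character(nx + nz * d[2L])]]
      if (is.null(nb)) next
      for (q in nb) {
        if (rs[q] <= re[r] + ext && re[q] >= rs[r] - ext) {
          a <- find(r); b <- find(q)
          if (a != b) parent[max(a, b)] <- min(a, b)
        }
      }
    }
  }
  root <- vapply(seq_len(nrun), find, integer(1L))
  lab <- match(root, sort(unique(root)))
  # relabel so components are numbered by first appearance
  first <- !duplicated(lab)
  remap <- integer(max(lab))
  remap[lab[first]] <- seq_len(sum(first))
  lab <- remap[lab]
  labels[idx] <- rep(lab, re - rs + 1L)
  list(labels = labels, n = max(lab), sizes = tabulate(lab[rep.int(seq_len(nrun), re - rs + 1L)]))
}

#' Suppress free-floating cells from a segmentation mask
#'
#' Planktonic cells drifting past the biofilm segment as small detached
#' objects and inflate biovolume estimates. This filter removes foreground
#' components that both (a) fail substrate attachment -- no voxel within one
#' z-slice of the bottom plane -- and (b) are smaller than a minimum volume
#' (default one cell volume, 1.3 µm³). Components touching the substrate, or
#' large detached aggregates, are kept. The surviving mask is always a
#' subset of the input.
#'
#' @param mask a [seg_mask].
#' @param min_volume_um3 minimum volume for detached components, µm³.
#' @param connectivity component connectivity, 6 or 26.
#' @return a [seg_mask] with suppressed components removed; provenance gains
#'   `n_removed` and `removed_um3`.
#' @export
suppress_floating_cells <- function(mask, min_volume_um3 = 1.3,
                                    connectivity = 26L) {
  stopifnot(inherits(mask, "seg_mask"))
  cc <- label_components(mask$mask, connectivity)
  if (cc$n == 0L) return(mask)
  vox_vol <- prod(mask$pitch)
  # attachment: any voxel of the component in z-slice 1 or 2
  nz <- dim(mask$mask)[3L]
  bottom <- cc$labels[, , seq_len(min(2L, nz)), drop = FALSE]
  attached_ids <- unique(bottom[bottom > 0L])
  small <- which(cc$sizes * vox_vol < min_volume_um3)
  drop_ids <- setdiff(small, attached_ids)
  if (length(drop_ids) > 0L) {
    out <- mask$mask & !(cc$labels %in% drop_ids)
    dim(out) <- dim(mask$mask)
  } else out <- mask$mask
  prov <- mask$provenance
  prov$n_removed <- length(drop_ids)
  prov$removed_um3 <- sum(cc$sizes[drop_ids]) * vox_vol
  seg_mask(out, mask$pitch, mask$params, prov)
}
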