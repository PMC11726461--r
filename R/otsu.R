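#' Otsu threshold with a discount factor
#'
#' Computes the intensity threshold maximizing the between-class variance of
#' the intensity histogram (Otsu's criterion) and multiplies it by a discount
#' factor. A discount below 1 deliberately lowers the cut so that dim
#' fluorescent objects are still captured; 0.2 is the value used throughout
#' for biofilm segmentation, held constant across all stacks.
#'
#' The histogram uses `bins` equal-width bins over the observed min-max
#' range. Candidate thresholds are the `bins - 1` inner bin boundaries; ties
#' in the criterion are broken towards the lowest qualifying threshold. The
#' returned value is on the intensity scale of the input; apply it as
#' `x > threshold`.
#'
#' @param x numeric array or vector of intensities, at least two distinct
#'   values.
#' @param discount multiplier in (0, 1] applied to the Otsu threshold.
#' @param bins number of histogram bins (default 256).
#' @return a single numeric threshold, with attributes `otsu` (the
#'   undiscounted threshold) and `bin` (the selected boundary index).
#' @export
otsu_threshold <- function(x, discount = 0.2, bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite intensities")
  if (!is.numeric(discount) || length(discount) != 1L ||
      discount <= 0 || discount > 1)
    stop("'discount' must be in (0, 1]")
  rng <- range(x)
  if (rng[1L] >= rng[2L])
    stop("degenerate histogram: input has no intensity variation")
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  bin <- .bincode(x, breaks, right = TRUE, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = bins)
  k <- otsu_from_counts(counts)
  thr <- breaks[k + 1L]
  structure(discount * thr, otsu = thr, bin = k)
}

#' Otsu criterion on histogram counts
#'
#' Vectorized maximization of the between-class variance
#' \eqn{\sigma_b^2(k) = \omega_1\omega_2(\mu_1-\mu_2)^2} over all split
#' points of a histogram. Exposed separately so the selection rule can be
#' checked against exhaustive search.
#'
#' @param counts non-negative integer histogram counts, one per bin.
#' @param mids optional numeric bin centres (defaults to bin indices); only
#'   their ordering/spacing affects the criterion through the class means.
#' @return the selected split index `k` in `1 .. length(counts) - 1`: bins
#'   `1..k` form the lower class. First (lowest) maximizer on ties.
#' @export
otsu_from_counts <- function(counts, mids = seq_along(counts)) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L || any(counts < 0) || sum(counts) <= 0)
    stop("'counts' must be >= 2 non-negative bin counts with positive total")
  p <- counts / sum(counts)
  w <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  k <- seq_len(length(counts) - 1L)
  w1 <- w[k]
  num <- (mu_t * w1 - mu[k])^2
  den <- w1 * (1 - w1)
  sb2 <- ifelse(den > 0, num / den, -Inf)
  which.max(sb2)
}
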