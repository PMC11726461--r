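#' Two-sided two-sample Student's t-test
#'
#' Classical two-sample comparison of replicate means. Equal-variance
#' (pooled) by default, Welch behind a flag. When both groups have zero
#' variance and equal means the test is degenerate and `p = 1`, `t = 0` by
#' convention.
#'
#' @param a,b numeric replicate values, at least 2 per group.
#' @param welch use the Welch (unequal variance) form.
#' @return list: `statistic` (t), `df`, `p.value`, `method`.
#' @export
ttest_two_sided <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("at least 2 replicates per group are required")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("replicate values must be finite")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, df = length(a) + length(b) - 2L,
                  p.value = 1,
                  method = "two-sample t-test (degenerate: zero variance)"))
    stop("zero variance in both groups with unequal means: t is infinite")
  }
  tt <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, method = tt$method)
}

#' One-way ANOVA with Bonferroni-corrected comparisons against a control
#'
#' One-way analysis of variance across all groups, then pairwise pooled
#' two-sample t-tests of every non-control group against the control, with
#' Bonferroni correction (raw p times the number of comparisons, capped at
#' 1).
#'
#' If all values are identical the decomposition is degenerate and `F = 0`,
#' `p = 1` by convention; zero within-group variance with differing means is
#' flagged.
#'
#' @param values numeric vector of all replicate values.
#' @param groups factor/character of group labels, same length.
#' @param control label of the control (reference) group.
#' @param welch use Welch t-tests for the pairwise comparisons.
#' @return list of class `anova_bonferroni`: `F`, `df` (c(between,
#'   within)), `p.value`, `degenerate` flag, `m` (number of comparisons) and
#'   `comparisons` (data.frame: group, diff (group mean - control mean), t,
#'   p_raw, p_adj).
#' @export
anova_bonferroni <- function(values, groups, control, welch = FALSE) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  lv <- unique(groups)
  if (length(lv) < 2L) stop("at least 2 groups are required")
  if (!control %in% lv) stop("control group not found: ", control)
  ns <- table(groups)
  if (any(ns < 2L)) stop("every group needs n >= 2")

  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ss_between <- sum(ns[names(means)] * (means - grand)^2)
  ss_within <- sum((values - means[groups])^2)
  df1 <- length(lv) - 1L
  df2 <- length(values) - length(lv)
  degenerate <- FALSE
  if (ss_between == 0) {
    Fv <- 0; p <- 1
  } else if (ss_within == 0) {
    Fv <- Inf; p <- 0; degenerate <- TRUE
  } else {
    Fv <- (ss_between / df1) / (ss_within / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }

  others <- setdiff(lv, control)
  m <- length(others)
  cmp <- do.call(rbind, lapply(others, function(g) {
    tt <- ttest_two_sided(values[groups == g], values[groups == control],
                          welch = welch)
    data.frame(group = g, diff = means[[g]] - means[[control]],
               t = tt$statistic, p_raw = tt$p.value,
               p_adj = min(1, m * tt$p.value))
  }))
  rownames(cmp) <- NULL
  structure(list(F = Fv, df = c(between = df1, within = df2), p.value = p,
                 degenerate = degenerate, m = m, control = control,
                 comparisons = cmp),
            class = "anova_bonferroni")
}

#' @export
print.anova_bonferroni <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df[1], x$df[2], x$F, x$p.value,
              if (x$degenerate) " (degenerate within-group variance)" else ""))
  cat(sprintf("Bonferroni-adjusted comparisons vs '%s' (m = %d):\n",
              x$control, x$m))
  print(x$comparisons)
  invisible(x)
}
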