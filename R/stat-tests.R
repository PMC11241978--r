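## Two-group test selection shared by the editing, expression and validation
## stages: each group is screened for normality with a Kolmogorov-Smirnov
## test against a normal with sample-estimated mean/SD (estimated-parameter
## bias documented in the vignette; Lilliefors correction available); if
## either group rejects at `alpha`, a Mann-Whitney test is used (exact when
## min(n) <= 8 without ties), otherwise a Welch two-sample t-test.

ks_normal_reject <- function(v, alpha = 0.05, lilliefors = FALSE) {
  if (length(v) < 3) return(TRUE)          # too small to defend normality
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(TRUE)
  if (lilliefors) {
    if (requireNamespace("nortest", quietly = TRUE))
      return(nortest::lillie.test(v)$p.value < alpha)
    warnf("nortest not available; falling back to plain KS")
  }
  p <- suppressWarnings(stats::ks.test(v, "pnorm", mean(v), s)$p.value)
  p < alpha
}

#' Kolmogorov-Smirnov-gated two-group test
#'
#' @param x,y numeric samples (case, control).
#' @param alpha normality-screen level (default 0.05).
#' @param force NULL, "t" or "mann_whitney" to bypass the gate.
#' @param lilliefors use the Lilliefors-corrected normality screen.
#' @return list with `test_used` ("t" or "mann_whitney"), `p_value`,
#'   `statistic`, `degenerate` (TRUE when both groups are constant and
#'   equal, in which case p = 1).
#' @export
ks_gated_test <- function(x, y, alpha = 0.05, force = NULL, lilliefors = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  v <- stats::var(c(x, y))
  if (is.na(v) || v == 0) {
    return(list(test_used = force %||% "t", p_value = 1, statistic = NA_real_,
                degenerate = TRUE))
  }
  use_mw <- if (!is.null(force)) force == "mann_whitney"
  else ks_normal_reject(x, alpha, lilliefors) || ks_normal_reject(y, alpha, lilliefors)
  if (use_mw) {
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- min(length(x), length(y)) <= 8 && !ties
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE))
    list(test_used = "mann_whitney", p_value = ht$p.value,
         statistic = unname(ht$statistic), degenerate = FALSE)
  } else {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    list(test_used = "t", p_value = ht$p.value,
         statistic = unname(ht$statistic), degenerate = FALSE)
  }
}

#' Pearson correlation with the closed-form t-transform p-value
#'
#' p is two-sided from t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom;
#' the significance flag applies the r > `r_cutoff` AND p < `p_cutoff` rule.
#'
#' @param x,y numeric vectors (pairwise-complete).
#' @param r_cutoff correlation threshold for the significance flag
#'   (default 0.5).
#' @param p_cutoff p-value threshold (default 0.05).
#' @return list with `r`, `p_value`, `n`, `significant`, `small_n` flag
#'   (n < 5), `flagged` (TRUE when undefined: n < 3 or zero variance).
#' @export
pearson_significance <- function(x, y, r_cutoff = 0.5, p_cutoff = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = n, significant = FALSE,
                small_n = n < 5, flagged = TRUE))
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  list(r = r, p_value = p, n = n,
       significant = isTRUE(r > r_cutoff && p < p_cutoff),
       small_n = n < 5, flagged = FALSE)
}
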