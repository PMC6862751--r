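# Comparison statistics on frequency tables: fold changes, transformed paired
# t-tests, Fisher's exact test and exact binomial confidence intervals. These
# are the field's standard tests, called through base R behind a thin surface;
# tests cross-check them against independent enumerations.

#' Fold change of selected over mock frequency
#'
#' @param freq_sel,freq_mock percentages (or any same-scale frequencies).
#' @param pseudo optional pseudo-count added to both terms when the mock
#'   frequency is zero (default none: the ratio is reported as `NA` and
#'   flagged by a warning).
#' @return ratio `freq_sel / freq_mock`.
#' @export
fold_change <- function(freq_sel, freq_mock, pseudo = 0) {
  if (any(freq_mock + pseudo == 0)) {
    warning("zero mock frequency: fold change undefined")
    return(ifelse(freq_mock + pseudo == 0, NA_real_,
                  (freq_sel + pseudo) / (freq_mock + pseudo)))
  }
  (freq_sel + pseudo) / (freq_mock + pseudo)
}

#' Paired t-test with optional transform
#'
#' Applies the transform element-wise, then a standard paired t-test on the
#' differences (two-sided, `n - 1` df). `log` is the natural log (values must
#' be positive); `arcsine_sqrt` is `asin(sqrt(p))` on proportions in \[0, 1\]
#' (divide percentages by 100 first).
#'
#' @param a,b paired samples (same length, n >= 2).
#' @param transform one of `"none"`, `"log"`, `"arcsine_sqrt"`.
#' @return list with `statistic`, `p.value`, `df`, `transform`, `n`,
#'   `degenerate` (TRUE when the differences have zero variance; if moreover
#'   all differences are zero, `statistic = 0` and `p.value = 1`).
#' @export
paired_t <- function(a, b, transform = c("none", "log", "arcsine_sqrt")) {
  transform <- match.arg(transform)
  stopifnot(length(a) == length(b), length(a) >= 2)
  f <- switch(transform,
              none = identity,
              log = function(x) {
                if (any(x <= 0)) stop("log transform requires positive values")
                log(x)
              },
              arcsine_sqrt = function(x) {
                if (any(x < 0 | x > 1))
                  stop("arcsine_sqrt requires proportions in [0, 1]")
                asin(sqrt(x))
              })
  d <- f(a) - f(b)
  n <- length(d)
  if (stats::var(d) == 0) {
    if (all(d == 0))
      return(list(statistic = 0, p.value = 1, df = n - 1,
                  transform = transform, n = n, degenerate = TRUE))
    return(list(statistic = sign(mean(d)) * Inf, p.value = NA_real_,
                df = n - 1, transform = transform, n = n, degenerate = TRUE))
  }
  tt <- t.test(f(a), f(b), paired = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), transform = transform, n = n,
       degenerate = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p by summation of hypergeometric probabilities no larger than
#' the observed table's. Degenerate margins give p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (all(rowSums(tab) == 0) || all(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n >= 1`.
#' @param level confidence level.
#' @return numeric `c(lower, upper)`.
#' @export
binomial_ci <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  as.numeric(stats::binom.test(k, n, conf.level = level)$conf.int)
}
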