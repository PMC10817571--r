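#' Spearman rank correlation with interpretation bands
#'
#' Ranks use midranks for ties; the coefficient is the Pearson correlation
#' of the ranks. The two-sided p-value uses the t approximation
#' `t = rs * sqrt((n - 2) / (1 - rs^2))` with n - 2 degrees of freedom
#' (appropriate at the study's n = 100; an exact permutation reference is
#' practical only for tiny n). The magnitude is banded as weak
#' (0.2 <= |rs| <= 0.39), moderate (0.4-0.59) or strong (0.6-0.79);
#' anything else (including the gaps at the published band edges) is
#' `"other"`.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return An object of class `correlation_result` with `rs`, `p`, `n`,
#'   `band`.
#' @export
spearman_corr <- function(x, y) {
  n <- length(x)
  if (n != length(y)) nt_stop("x and y differ in length", "nervetrace_size_error")
  if (n < 3) nt_stop("need n >= 3", "nervetrace_size_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    nt_stop("correlation undefined for a constant input", "nervetrace_undefined_correlation")
  }
  rs <- stats::cor(rank(x), rank(y))
  p <- if (abs(rs) >= 1) 0 else {
    tt <- rs * sqrt((n - 2) / (1 - rs^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(rs = rs, p = p, n = n, band = correlation_band(rs)),
            class = "correlation_result")
}

correlation_band <- function(rs) {
  a <- abs(rs)
  if (a >= 0.2 && a <= 0.39) "weak"
  else if (a >= 0.4 && a <= 0.59) "moderate"
  else if (a >= 0.6 && a <= 0.79) "strong"
  else "other"
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rs(%d) = %.3f, p = %.3g (%s)\n",
              x$n - 2L, x$rs, x$p, x$band))
  invisible(x)
}

#' Student's t-test between two metric samples
#'
#' Pooled-variance two-sample Student's t by default, or a paired t-test.
#' Zero pooled variance is handled deterministically: equal means give
#' `t = 0, p = 1`; unequal means give `p = 0`.
#'
#' @param a,b numeric samples (each n >= 2; equal lengths when paired).
#' @param paired logical.
#' @return A list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, paired = FALSE) {
  if (length(a) < 2 || length(b) < 2) nt_stop("need n >= 2 per sample", "nervetrace_size_error")
  if (paired && length(a) != length(b)) {
    nt_stop("paired samples must have equal length", "nervetrace_size_error")
  }
  degenerate <- if (paired) stats::sd(a - b) == 0 else
    stats::var(a) == 0 && stats::var(b) == 0
  if (degenerate) {
    df <- if (paired) length(a) - 1 else length(a) + length(b) - 2
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(t = 0, df = df, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0))
  }
  ht <- stats::t.test(a, b, paired = paired, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Bland-Altman agreement between a reference and a test method
#'
#' Differences are taken as reference minus test, so a positive mean
#' difference means the test method underestimates. Limits of agreement are
#' the mean difference +/- 1.96 times the sample SD of the differences;
#' `coverage` is the fraction of pairs falling inside them.
#'
#' @param reference,test numeric vectors of equal length, n >= 3 (the
#'   reference is the manual/ground-truth arm).
#' @return An object of class `bland_altman` with `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `coverage`, `n`, plus per-pair `means` and
#'   `diffs` for plotting.
#' @export
bland_altman <- function(reference, test) {
  n <- length(reference)
  if (n != length(test)) nt_stop("lengths differ", "nervetrace_size_error")
  if (n < 3) nt_stop("need n >= 3", "nervetrace_size_error")
  d <- reference - test
  md <- mean(d)
  sdd <- stats::sd(d)
  lo <- md - 1.96 * sdd
  hi <- md + 1.96 * sdd
  structure(list(mean_diff = md, sd_diff = sdd, loa_low = lo, loa_high = hi,
                 coverage = mean(d >= lo & d <= hi), n = n,
                 means = (reference + test) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean diff %.3f +/- %.3f SD, LoA [%.3f, %.3f], coverage %.1f%%\n",
              x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high,
              100 * x$coverage))
  invisible(x)
}

#' Bland-Altman plot: pairwise differences against pairwise means
#' @param x a `bland_altman` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "mean of methods",
                 ylab = "reference - test", ...)
  graphics::abline(h = c(x$loa_low, x$mean_diff, x$loa_high),
                   lty = c(2, 1, 2), col = c("firebrick", "black", "firebrick"))
  invisible(x)
}
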