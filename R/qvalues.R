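#' Estimate the proportion of true null hypotheses by a sliding linear model
#'
#' The empirical CDF of a p-value vector is piecewise linear with slope close
#' to pi0 (the proportion of true nulls) in regions free of signal, because
#' null p-values are uniform while alternative p-values concentrate near
#' zero. The estimator evaluates the empirical CDF at knots spaced
#' \code{alpha} apart and fits an ordinary least-squares line within a
#' window sliding across the unit interval. Because alternative p-values
#' concentrate near zero, the slope sequence decreases from left to right
#' and flattens once windows are free of signal: the estimate is the slope
#' at the left end of the longest stable run of windows ending at the right
#' edge (successive slopes differing by less than \code{tol}); when no run
#' is stable the right-most window is used. Estimates outside (0, 1\] fall
#' back to pi0 = 1, which reduces \code{\link{compute_qvalues}} to plain
#' Benjamini-Hochberg adjustment — the conservative regime that exact-test
#' p-value distributions (discrete, sub-uniform under the null) trigger by
#' design.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs dropped).
#' @param alpha knot spacing of the sliding windows (default 0.05).
#' @param window_frac fraction of the unit interval each window spans
#'   (default 0.5).
#' @param tol slope-stabilisation tolerance (default 0.01).
#' @return scalar pi0 estimate in (0, 1\].
#' @export
estimate_pi0_slim <- function(p, alpha = 0.05, window_frac = 0.5, tol = 0.01) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) {
    return(1)
  }
  if (any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  # a uniform null component puts mass near p = 1; if the distribution never
  # reaches the right region (as gated or bounded-support exact tests can
  # arrange), the sliding fit has no null support and the estimate is
  # meaningless -- fall back to the conservative pi0 = 1
  if (max(p) < 1 - 2 * alpha) {
    return(1)
  }
  knots <- seq(0, 1, by = alpha)
  ecdf_vals <- vapply(knots, function(t) mean(p <= t), numeric(1))
  w <- max(2L, round(window_frac / alpha))      # knots per window
  n_windows <- length(knots) - w
  if (n_windows < 1L) {
    return(1)
  }
  slopes <- vapply(seq_len(n_windows), function(i) {
    idx <- i:(i + w)
    x <- knots[idx]
    y <- ecdf_vals[idx]
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }, numeric(1))
  # walk left from the right-most window while the slope stays stable
  i <- length(slopes)
  while (i > 1L && abs(slopes[i - 1L] - slopes[i]) < tol) {
    i <- i - 1L
  }
  pi0 <- slopes[i]
  # a line fitted through a window where the ECDF moves at a single knot
  # (e.g. all mass at p = 1) carries no slope information
  if (sum(diff(ecdf_vals[i:(i + w)]) > 0) <= 1L) {
    return(1)
  }
  if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) {
    return(1)
  }
  pi0
}

#' FDR q-values with a sliding-linear-model pi0 estimate
#'
#' q-values are \code{pi0} times the Benjamini-Hochberg step-up adjusted
#' p-values, capped at 1. With \code{pi0 = 1} this is exactly BH. NAs in the
#' input (e.g. rules whose significance test was not evaluated) are carried
#' through as NA and excluded from both the pi0 estimate and the adjustment.
#'
#' @param p numeric vector of p-values (may contain NA).
#' @param pi0 optional fixed pi0; estimated by \code{\link{estimate_pi0_slim}}
#'   when NULL.
#' @param alpha knot spacing passed to the pi0 estimator.
#' @return numeric vector of q-values, same length and NA pattern as \code{p}.
#' @export
compute_qvalues <- function(p, pi0 = NULL, alpha = 0.05) {
  if (length(p) == 0L) {
    return(numeric(0))
  }
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (is.null(pi0)) {
    pi0 <- estimate_pi0_slim(p[ok], alpha = alpha)
  }
  q <- rep(NA_real_, length(p))
  q[ok] <- pmin(1, pi0 * p.adjust(p[ok], method = "BH"))
  q
}
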