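#' Exact p-value for a 2x2 contingency table
#'
#' Computes the Fisher exact p-value for the table
#' \code{rbind(c(a, b), c(c, d))} conditional on both margins, via the
#' hypergeometric distribution. The two-sided p-value is the sum of the
#' probabilities of all tables (with the same margins) whose probability does
#' not exceed that of the observed table, up to a small relative tolerance —
#' the convention used by \code{stats::fisher.test}. The pipeline evaluates
#' this on the order of 1e5 tables per mining pass, so the computation is
#' done directly on the table support rather than through
#' \code{stats::fisher.test}.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise.
#' @param alternative \code{"two.sided"} (default), \code{"greater"}
#'   (enrichment of cell \code{a}) or \code{"less"}.
#' @return p-value in \[0, 1\]. Degenerate tables (a zero margin) have p = 1.
#' @examples
#' fisher_exact_2x2(2, 0, 0, 8)           # 1/45
#' fisher_exact_2x2(5, 5, 5, 5)           # 1
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  if (r1 == 0L || r2 == 0L || c1 == 0L || c1 == n) {
    return(1)
  }
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  k <- lo:hi
  pk <- dhyper(k, r1, r2, c1)
  p_obs <- pk[k == a]
  p <- switch(alternative,
    two.sided = sum(pk[pk <= p_obs * (1 + 1e-7)]),
    greater   = sum(pk[k >= a]),
    less      = sum(pk[k <= a])
  )
  min(1, p)
}

# Vectorised two-sided Fisher over parallel count vectors; returns NA where
# any count is NA.
fisher_p_two_sided_vec <- function(a, b, c, d) {
  n <- length(a)
  out <- rep(NA_real_, n)
  ok <- !(is.na(a) | is.na(b) | is.na(c) | is.na(d))
  idx <- which(ok)
  for (i in idx) {
    out[i] <- fisher_exact_2x2(a[i], b[i], c[i], d[i])
  }
  out
}
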