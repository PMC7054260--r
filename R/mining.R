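#' Enumerate all ordered phenotype pairs
#'
#' All ordered (lhs, rhs) combinations including self-pairs; a catalogue of
#' n phenotypes yields n^2 patterns. Self-pairs are flagged so downstream
#' stages exclude them from rules.
#'
#' @param phenotypes either a count or a character vector of phenotype ids.
#' @return data.frame with columns \code{lhs}, \code{rhs}, \code{self}.
#' @examples
#' nrow(enumerate_pairs(532))  # 283024
#' @export
enumerate_pairs <- function(phenotypes) {
  ids <- if (is.numeric(phenotypes) && length(phenotypes) == 1L) {
    stopifnot(phenotypes >= 1)
    sprintf("phenotype_%d", seq_len(phenotypes))
  } else {
    as.character(phenotypes)
  }
  out <- expand.grid(rhs = ids, lhs = ids, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)[, c("lhs", "rhs")]
  out$self <- out$lhs == out$rhs
  rownames(out) <- NULL
  out
}

#' Complete-case 2x2 counts for a phenotype pair
#'
#' Tabulates strains over complete cases only: any strain not tested in
#' either phenotype is removed before counting.
#'
#' @param calls a \code{\link{call_matrix}}.
#' @param X,Y distinct phenotype ids present in \code{calls}.
#' @return list of class \code{pairwise_counts}: \code{n11} (both abnormal),
#'   \code{n10} (X abnormal, Y normal), \code{n01}, \code{n00}, \code{N}.
#' @export
pairwise_counts <- function(calls, X, Y) {
  if (!all(c(X, Y) %in% rownames(calls))) {
    stop("unknown phenotype id: ",
         paste(setdiff(c(X, Y), rownames(calls)), collapse = ", "))
  }
  if (X == Y) {
    stop("pairwise counts require two distinct phenotypes")
  }
  x <- calls[X, ]
  y <- calls[Y, ]
  keep <- x != "NT" & y != "NT"
  x <- x[keep] == "A"
  y <- y[keep] == "A"
  structure(list(n11 = sum(x & y), n10 = sum(x & !y),
                 n01 = sum(!x & y), n00 = sum(!x & !y),
                 N = sum(keep)),
            class = "pairwise_counts")
}

#' Support: co-abnormality frequency
#'
#' Fraction of complete-case strains abnormal in both phenotypes,
#' \code{n11 / N}.
#'
#' @param c a \code{pairwise_counts}.
#' @return proportion in \[0, 1\], or NA when N = 0.
#' @export
rule_support <- function(c) {
  if (c$N == 0L) return(NA_real_)
  c$n11 / c$N
}

#' Confidence: conditional abnormal probability
#'
#' Forward: P(Y abnormal | X abnormal) = n11 / (n11 + n10); reverse
#' conditions on Y instead.
#'
#' @param c a \code{pairwise_counts}.
#' @param direction \code{"fwd"} or \code{"rev"}.
#' @return proportion, or NA when the conditioning margin is empty.
#' @export
rule_confidence <- function(c, direction = c("fwd", "rev")) {
  direction <- match.arg(direction)
  den <- if (direction == "fwd") c$n11 + c$n10 else c$n11 + c$n01
  if (den == 0L) return(NA_real_)
  c$n11 / den
}

#' Lift: confidence relative to the marginal abnormality of the conclusion
#'
#' \code{lift = n11 N / ((n11 + n10)(n11 + n01))}; 1 represents
#' independence, and the value is symmetric in rule direction.
#'
#' @param c a \code{pairwise_counts}.
#' @return ratio >= 0, or NA when either abnormal margin is empty.
#' @export
rule_lift <- function(c) {
  mx <- c$n11 + c$n10
  my <- c$n11 + c$n01
  if (mx == 0L || my == 0L) return(NA_real_)
  c$n11 * c$N / (mx * my)
}

#' Rule polarity: deviation between the two directed confidences
#'
#' Two-tailed Fisher exact p on the 2x2 table \code{rbind(c(n11, n10),
#' c(n11, n01))} — the two conditional-probability numerators share n11 —
#' returned as -log10 p. Large values mean the premise has far fewer
#' abnormal cases than the conclusion.
#'
#' @param c a \code{pairwise_counts}.
#' @return -log10 p >= 0, or NA when either confidence is undefined.
#' @export
rule_polarity <- function(c) {
  if (c$n11 + c$n10 == 0L || c$n11 + c$n01 == 0L) return(NA_real_)
  -log10(fisher_exact_2x2(c$n11, c$n10, c$n11, c$n01))
}

#' Rule significance: exact test of the lift
#'
#' Two-tailed Fisher exact p on the complete-case cross table
#' \code{rbind(c(n11, n10), c(n01, n00))}, evaluated only when the number of
#' abnormal co-expressions n11 >= 2; symmetric in rule direction.
#'
#' @param c a \code{pairwise_counts}.
#' @return p-value, or NA when n11 < 2 (not evaluated).
#' @export
rule_significance <- function(c) {
  if (c$n11 < 2L) return(NA_real_)
  fisher_exact_2x2(c$n11, c$n10, c$n01, c$n00)
}

#' Mine all pairwise rule measures from a call matrix
#'
#' Computes, for every unordered phenotype pair over complete cases, the
#' 2x2 counts and the six measures (co-abnormal count, support, both
#' directed confidences, lift, rule polarity, rule significance), plus
#' q-values over all evaluated significance p-values
#' (\code{\link{compute_qvalues}}). Counts are accumulated with three
#' matrix products, so the pass scales to hundreds of phenotypes by
#' thousands of strains.
#'
#' @param calls a \code{\link{call_matrix}}.
#' @param pi0 optional fixed pi0 for the q-value computation.
#' @param qvalues compute q-values over this matrix's own p-values (set
#'   FALSE when the caller adjusts over a larger family, as the selection
#'   sweep does).
#' @return data.frame with one row per unordered pair (lhs precedes rhs in
#'   matrix row order): \code{lhs}, \code{rhs}, \code{n11}, \code{n10},
#'   \code{n01}, \code{n00}, \code{N}, \code{support},
#'   \code{confidence_fwd}, \code{confidence_rev}, \code{lift},
#'   \code{polarity}, \code{significance_p}, \code{q}.
#' @export
mine_all <- function(calls, pi0 = NULL, qvalues = TRUE) {
  phen <- rownames(calls)
  n <- length(phen)
  A <- matrix((calls == "A") + 0, nrow = n)
  T_ <- matrix((calls != "NT") + 0, nrow = n)
  n11m <- tcrossprod(A)            # A %*% t(A)
  Nm <- tcrossprod(T_)
  ATm <- tcrossprod(A, T_)         # abnormal in row phenotype among co-tested
  ut <- which(upper.tri(n11m), arr.ind = TRUE)
  i <- ut[, 1L]
  j <- ut[, 2L]
  n11 <- n11m[ut]
  N <- Nm[ut]
  n10 <- ATm[ut] - n11
  n01 <- ATm[cbind(j, i)] - n11
  n00 <- N - n11 - n10 - n01

  support <- ifelse(N > 0, n11 / N, NA_real_)
  mfwd <- n11 + n10
  mrev <- n11 + n01
  confidence_fwd <- ifelse(mfwd > 0, n11 / mfwd, NA_real_)
  confidence_rev <- ifelse(mrev > 0, n11 / mrev, NA_real_)
  lift <- ifelse(mfwd > 0 & mrev > 0, n11 * N / (mfwd * mrev), NA_real_)

  polarity <- rep(NA_real_, length(n11))
  pol_ok <- mfwd > 0 & mrev > 0
  polarity[pol_ok] <- -log10(fisher_p_two_sided_vec(
    n11[pol_ok], n10[pol_ok], n11[pol_ok], n01[pol_ok]))

  significance_p <- rep(NA_real_, length(n11))
  sig_ok <- n11 >= 2L
  significance_p[sig_ok] <- fisher_p_two_sided_vec(
    n11[sig_ok], n10[sig_ok], n01[sig_ok], n00[sig_ok])

  data.frame(lhs = phen[i], rhs = phen[j],
             n11 = n11, n10 = n10, n01 = n01, n00 = n00, N = N,
             support = support,
             confidence_fwd = confidence_fwd,
             confidence_rev = confidence_rev,
             lift = lift, polarity = polarity,
             significance_p = significance_p,
             q = if (qvalues) compute_qvalues(significance_p, pi0 = pi0)
                 else NA_real_,
             stringsAsFactors = FALSE)
}
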