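#' Fisher exact enrichment of a 2x2 table
#'
#' Exact hypergeometric test of the table with fold-enrichment
#' \code{observed / expected}, where expected is the margin product
#' \code{r1 c1 / N}. One-tailed p-values are only evaluated when fold >= 1
#' (over-representation); degenerate margins yield p = 1 with a flag.
#'
#' @param tab 2x2 matrix of non-negative integer counts; cell \[1,1\] is
#'   the observed count of interest.
#' @param tail \code{"two"} or \code{"one"}.
#' @return list of class \code{enrichment_record}: \code{observed},
#'   \code{expected}, \code{fold}, \code{p}, \code{direction}
#'   (positive/negative), \code{degenerate}.
#' @export
fisher_enrichment <- function(tab, tail = c("two", "one")) {
  tail <- match.arg(tail)
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  a <- tab[1, 1]
  N <- sum(tab)
  expected <- if (N > 0) sum(tab[1, ]) * sum(tab[, 1]) / N else NA_real_
  fold <- if (!is.na(expected) && expected > 0) a / expected else NA_real_
  degenerate <- N == 0 || sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0 ||
    sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0
  p <- if (degenerate) {
    1
  } else if (tail == "two") {
    fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  } else if (!is.na(fold) && fold >= 1) {
    fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                     alternative = "greater")
  } else {
    NA_real_
  }
  structure(list(observed = a, expected = expected, fold = fold, p = p,
                 direction = if (!is.na(fold) && fold >= 1) "positive"
                             else "negative",
                 degenerate = degenerate),
            class = "enrichment_record")
}

stage_of <- function(ids, annotation) {
  annotation$stage_type[match(ids, annotation$phenotype_id)]
}

systems_of <- function(ids, annotation) {
  hit <- match(ids, annotation$phenotype_id)
  strsplit(annotation$biological_systems[hit], ";", fixed = TRUE)
}

#' Enrichment of atlas rules by stage/type category pair
#'
#' For each of the 16 ordered stage/type category pairs, contrasts the
#' observed number of atlas rules in the pair against the category
#' composition of all possible ordered phenotype pairs in the annotation
#' (two-tailed Fisher exact test, Holm-corrected across the 16 tests).
#'
#' @param atlas a \code{significant_rule_set} (or its rules data.frame).
#' @param annotation annotation map covering the atlas phenotypes.
#' @return data.frame: \code{lhs_category}, \code{rhs_category},
#'   \code{observed}, \code{possible}, \code{expected}, \code{fold},
#'   \code{p}, \code{p_holm}, \code{direction}.
#' @export
stage_type_rule_enrichment <- function(atlas, annotation) {
  rules <- if (inherits(atlas, "significant_rule_set")) atlas$rules else atlas
  stages <- c("adult_trait", "adult_gene", "embryo_trait", "embryo_gene")
  n_cat <- table(factor(unique(annotation[, c("phenotype_id", "stage_type")])
                        $stage_type, levels = stages))
  rl <- factor(stage_of(rules$lhs, annotation), levels = stages)
  rr <- factor(stage_of(rules$rhs, annotation), levels = stages)
  obs_tab <- table(rl, rr)
  R <- nrow(rules)
  P <- sum(n_cat) * (sum(n_cat) - 1)
  grid <- expand.grid(lhs_category = stages, rhs_category = stages,
                      stringsAsFactors = FALSE)
  recs <- lapply(seq_len(nrow(grid)), function(k) {
    a <- grid$lhs_category[k]
    b <- grid$rhs_category[k]
    poss <- n_cat[[a]] * n_cat[[b]] - (a == b) * n_cat[[a]]
    obs <- obs_tab[a, b]
    tab <- matrix(c(obs, R - obs, poss - obs, (P - poss) - (R - obs)),
                  2, 2, byrow = TRUE)
    er <- fisher_enrichment(tab, tail = "two")
    data.frame(lhs_category = a, rhs_category = b,
               observed = obs, possible = as.integer(poss),
               expected = er$expected, fold = er$fold, p = er$p,
               direction = er$direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$p_holm <- p.adjust(out$p, method = "holm")
  out[, c("lhs_category", "rhs_category", "observed", "possible",
          "expected", "fold", "p", "p_holm", "direction")]
}

# Number of unordered phenotype pairs spanning systems s and t crosswise:
# |A||B| - |A∩B| - C(|A∩B|, 2), with A, B the annotated phenotype sets.
cross_pair_count <- function(a, b) {
  i <- sum(a & b)
  sum(a) * sum(b) - i - i * (i - 1) / 2
}

#' Enrichment of atlas rules by between-biological-systems pair
#'
#' For every pair of distinct biological systems with at least one atlas
#' rule, contrasts the observed rule count in the pair against the possible
#' phenotype pairs spanning the two systems (two-tailed Fisher exact test)
#' and computes q-values across the realized pairs.
#'
#' @param atlas a \code{significant_rule_set} (or its rules data.frame).
#' @param annotation annotation map with \code{biological_systems}.
#' @param fdr significance threshold recorded in \code{significant}
#'   (default 0.01).
#' @return data.frame: \code{system_a}, \code{system_b}, \code{observed},
#'   \code{possible}, \code{fold}, \code{p}, \code{q}, \code{direction},
#'   \code{significant}.
#' @export
system_pair_enrichment <- function(atlas, annotation, fdr = 0.01) {
  rules <- if (inherits(atlas, "significant_rule_set")) atlas$rules else atlas
  phen <- unique(annotation$phenotype_id)
  sys_list <- systems_of(phen, annotation)
  all_sys <- sort(unique(unlist(sys_list)))
  S <- vapply(all_sys, function(s)
    vapply(sys_list, function(x) s %in% x, logical(1)),
    logical(length(phen)))
  lhs_sys <- systems_of(rules$lhs, annotation)
  rhs_sys <- systems_of(rules$rhs, annotation)
  rule_cats <- mapply(function(ls, rs) {
    cats <- unique(c(
      outer(ls, rs, function(x, y) paste(pmin(x, y), pmax(x, y),
                                         sep = "\r"))))
    cats[vapply(strsplit(cats, "\r"), function(z) z[1] != z[2], logical(1))]
  }, lhs_sys, rhs_sys, SIMPLIFY = FALSE)
  realized <- sort(unique(unlist(rule_cats)))
  if (length(realized) == 0L) {
    return(data.frame(system_a = character(0), system_b = character(0),
                      observed = integer(0), possible = integer(0),
                      fold = numeric(0), p = numeric(0), q = numeric(0),
                      direction = character(0), significant = logical(0)))
  }
  obs <- table(factor(unlist(rule_cats), levels = realized))
  R <- nrow(rules)
  P <- length(phen) * (length(phen) - 1) / 2
  recs <- lapply(realized, function(cat) {
    st <- strsplit(cat, "\r", fixed = TRUE)[[1L]]
    poss <- cross_pair_count(S[, st[1L]], S[, st[2L]])
    o <- obs[[cat]]
    tab <- matrix(c(o, R - o, poss - o, (P - poss) - (R - o)),
                  2, 2, byrow = TRUE)
    er <- fisher_enrichment(tab, tail = "two")
    data.frame(system_a = st[1L], system_b = st[2L],
               observed = o, possible = as.integer(poss),
               fold = er$fold, p = er$p, direction = er$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$q <- compute_qvalues(out$p)
  out$significant <- out$q < fdr
  rownames(out) <- NULL
  out
}

#' Categories of between-system pairs realizable in an annotation
#'
#' For every unordered phenotype pair, lists the between-biological-systems
#' categories it spans (empty for within-system pairs). Feed to
#' \code{\link{bootstrap_expected_system_pairs}}.
#'
#' @param annotation annotation map.
#' @return list with \code{pairs} (data.frame \code{lhs}, \code{rhs}) and
#'   \code{categories} (list of character vectors, parallel to pairs).
#' @export
possible_pair_categories <- function(annotation) {
  phen <- unique(annotation$phenotype_id)
  sys_list <- systems_of(phen, annotation)
  n <- length(phen)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cats <- lapply(seq_len(nrow(idx)), function(k) {
    s1 <- sys_list[[idx[k, 1L]]]
    s2 <- sys_list[[idx[k, 2L]]]
    cc <- unique(c(outer(s1, s2, function(x, y)
      paste(pmin(x, y), pmax(x, y), sep = "|"))))
    cc[vapply(strsplit(cc, "|", fixed = TRUE),
              function(z) z[1] != z[2], logical(1))]
  })
  list(pairs = data.frame(lhs = phen[idx[, 1L]], rhs = phen[idx[, 2L]],
                          stringsAsFactors = FALSE),
       categories = cats)
}

#' Bootstrap null for the number of distinct between-system pair categories
#'
#' Draws \code{n_rules} phenotype pairs uniformly without replacement from
#' the universe of possible pairs, \code{B} times, and counts the distinct
#' between-system categories realized in each replicate. The expected count
#' is the replicate mean; the lower-tail bootstrap p is the fraction of
#' replicates with a count less than or equal to \code{observed}.
#'
#' @param possible_pairs output of \code{\link{possible_pair_categories}}
#'   (or any list with a \code{categories} element).
#' @param n_rules number of pairs drawn per replicate.
#' @param observed observed distinct between-system category count.
#' @param B bootstrap replicates (>= 1000).
#' @param seed RNG seed.
#' @return list: \code{expected}, \code{p}, \code{counts} (the B replicate
#'   counts).
#' @export
bootstrap_expected_system_pairs <- function(possible_pairs, n_rules,
                                            observed, B = 10000,
                                            seed = 1L) {
  cats <- possible_pairs$categories
  stopifnot(n_rules <= length(cats), B >= 1000)
  set.seed(seed)
  counts <- vapply(seq_len(B), function(b) {
    idx <- sample.int(length(cats), n_rules)
    length(unique(unlist(cats[idx])))
  }, integer(1))
  list(expected = mean(counts), p = mean(counts <= observed),
       counts = counts)
}

#' Enrichment of rule categories among measure extremes
#'
#' Splits the atlas rules at the upper and lower \code{quantile} of one of
#' the four measures and tests, per stage/type rule category, one-tailed
#' over-representation in each extreme (Fisher exact, evaluated only for
#' fold >= 1, Bonferroni-corrected over the tests performed).
#'
#' @param atlas a \code{significant_rule_set} (or its rules data.frame).
#' @param measure one of \code{"support"}, \code{"confidence"},
#'   \code{"polarity"}, \code{"significance"}.
#' @param annotation annotation map (for the stage/type categories).
#' @param quantile extreme cut (default 0.25, quartiles).
#' @return data.frame: \code{category}, \code{extreme} (upper/lower),
#'   \code{observed}, \code{expected}, \code{fold}, \code{p},
#'   \code{p_bonferroni}; empty when the measure is constant.
#' @export
measure_extreme_enrichment <- function(atlas, measure, annotation,
                                       quantile = 0.25) {
  rules <- if (inherits(atlas, "significant_rule_set")) atlas$rules else atlas
  values <- switch(measure,
    support = rules$support,
    confidence = rules$confidence_fwd,
    polarity = rules$polarity,
    significance = -log10(rules$significance_p),
    stop("parameter error: unknown measure '", measure, "'"))
  lo <- stats::quantile(values, quantile, na.rm = TRUE, names = FALSE)
  hi <- stats::quantile(values, 1 - quantile, na.rm = TRUE, names = FALSE)
  empty <- data.frame(category = character(0), extreme = character(0),
                      observed = integer(0), expected = numeric(0),
                      fold = numeric(0), p = numeric(0),
                      p_bonferroni = numeric(0))
  if (!is.finite(lo) || !is.finite(hi) || lo == hi) {
    return(empty)
  }
  category <- paste(stage_of(rules$lhs, annotation),
                    stage_of(rules$rhs, annotation), sep = "=>")
  in_extreme <- list(upper = values >= hi, lower = values <= lo)
  recs <- list()
  for (cat in sort(unique(category))) {
    for (e in names(in_extreme)) {
      x <- in_extreme[[e]]
      tab <- matrix(c(sum(category == cat & x), sum(category == cat & !x),
                      sum(category != cat & x), sum(category != cat & !x)),
                    2, 2, byrow = TRUE)
      er <- fisher_enrichment(tab, tail = "one")
      recs[[length(recs) + 1L]] <- data.frame(
        category = cat, extreme = e, observed = tab[1, 1],
        expected = er$expected, fold = er$fold, p = er$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  evaluated <- !is.na(out$p)
  out$p_bonferroni <- NA_real_
  out$p_bonferroni[evaluated] <- pmin(1, out$p[evaluated] * sum(evaluated))
  rownames(out) <- NULL
  out
}

#' Spearman correlations among the four rule-selection measures
#'
#' All six pairwise Spearman correlations (with p-values) among support,
#' confidence (stored direction), rule polarity and rule significance
#' (-log10 p) over the atlas rules.
#'
#' @param atlas a \code{significant_rule_set} (or its rules data.frame).
#' @return data.frame: \code{measure_a}, \code{measure_b}, \code{rho},
#'   \code{p}.
#' @export
measure_correlations <- function(atlas) {
  rules <- if (inherits(atlas, "significant_rule_set")) atlas$rules else atlas
  if (nrow(rules) < 3L) {
    stop("need at least 3 rules for correlations")
  }
  m <- data.frame(support = rules$support,
                  confidence = rules$confidence_fwd,
                  polarity = rules$polarity,
                  significance = -log10(rules$significance_p))
  combos <- utils::combn(names(m), 2)
  recs <- lapply(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]
    b <- combos[2, k]
    ct <- suppressWarnings(cor.test(m[[a]], m[[b]], method = "spearman",
                                    exact = FALSE))
    data.frame(measure_a = a, measure_b = b,
               rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}
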