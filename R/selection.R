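#' Filter mined rules by the three selection criteria
#'
#' Keeps records with number of abnormal co-expressions >= \code{min_co},
#' lift strictly greater than \code{min_lift}, and q-value below
#' \code{max_q}.
#'
#' @param measures rule-measures data.frame from \code{\link{mine_all}}.
#' @param min_co minimum co-abnormal count (default 2).
#' @param min_lift lift must exceed this (strict; default 2).
#' @param max_q q-value must be below this (default 0.1).
#' @return filtered data.frame (bidirectional rules).
#' @export
filter_rules <- function(measures, min_co = 2, min_lift = 2, max_q = 0.1) {
  keep <- !is.na(measures$n11) & measures$n11 >= min_co &
    !is.na(measures$lift) & measures$lift > min_lift &
    !is.na(measures$q) & measures$q < max_q
  out <- measures[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Optimal |ES| call threshold per phenotype
#'
#' For each phenotype, the optimal threshold maximises the number of
#' filtered rules incident to it across the sweep; ties are broken toward
#' the larger (more stringent) threshold. Phenotypes with zero rules at
#' every threshold are absent from the map and drop out of the atlas.
#'
#' @param sweep_tables named list of filtered rule tables, one per grid
#'   value (names are the formatted thresholds, in grid order).
#' @param grid the threshold grid (same length/order as
#'   \code{sweep_tables}).
#' @return named numeric vector: phenotype id -> optimal threshold.
#' @export
optimal_threshold_per_phenotype <- function(sweep_tables, grid) {
  stopifnot(length(sweep_tables) == length(grid))
  phen <- sort(unique(unlist(lapply(sweep_tables,
                                    function(t) c(t$lhs, t$rhs)))))
  if (length(phen) == 0L) {
    return(setNames(numeric(0), character(0)))
  }
  counts <- vapply(sweep_tables, function(t) {
    tab <- table(factor(c(t$lhs, t$rhs), levels = phen))
    as.integer(tab)
  }, integer(length(phen)))
  counts <- matrix(counts, nrow = length(phen),
                   dimnames = list(phen, NULL))
  best <- apply(counts, 1L, function(x) {
    m <- max(x)
    if (m == 0L) return(NA_integer_)
    max(which(x == m))                      # tie -> larger threshold
  })
  keep <- !is.na(best)
  setNames(grid[best[keep]], phen[keep])
}

#' Accumulate rules at per-phenotype optima and remove duplicates
#'
#' Takes, for each phenotype p with an optimal threshold t*(p), the filtered
#' rules incident to p in the sweep table at t*(p); the union is then
#' deduplicated per unordered pair, keeping the occurrence with the larger
#' lift (ties: larger n11, then smaller threshold index).
#'
#' @param sweep_tables named list of filtered rule tables (grid order).
#' @param optimal map from \code{\link{optimal_threshold_per_phenotype}}.
#' @param grid the threshold grid.
#' @return bidirectional rule data.frame with a \code{selected_threshold}
#'   column.
#' @export
accumulate_and_dedupe <- function(sweep_tables, optimal, grid) {
  pieces <- lapply(names(optimal), function(p) {
    k <- which(abs(grid - optimal[[p]]) < 1e-9)[1L]
    t <- sweep_tables[[k]]
    t <- t[t$lhs == p | t$rhs == p, , drop = FALSE]
    if (nrow(t) > 0L) t$selected_threshold <- grid[k]
    t
  })
  acc <- do.call(rbind, pieces[vapply(pieces, nrow, integer(1)) > 0L])
  if (is.null(acc) || nrow(acc) == 0L) {
    return(acc %||% data.frame())
  }
  key <- paste(pmin(acc$lhs, acc$rhs), pmax(acc$lhs, acc$rhs), sep = "\r")
  ord <- order(key, -acc$lift, -acc$n11, acc$selected_threshold)
  acc <- acc[ord, , drop = FALSE]
  acc <- acc[!duplicated(key[ord]), , drop = FALSE]
  rownames(acc) <- NULL
  acc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve bidirectional rules into directed rules
#'
#' Each unordered pair keeps the direction with the larger confidence, so
#' rules point from the phenotype with fewer complete-case abnormal strains
#' toward the one with more. Exact confidence ties are broken toward the
#' lexicographically smaller lhs and flagged in \code{direction_tie}.
#'
#' @param rules bidirectional rule data.frame (\code{mine_all} columns).
#' @return directed rule data.frame: counts and confidences re-expressed in
#'   the stored direction, with \code{confidence_fwd >= confidence_rev}.
#' @export
resolve_direction <- function(rules) {
  if (nrow(rules) == 0L) {
    rules$direction_tie <- logical(0)
    return(rules)
  }
  cf <- rules$confidence_fwd
  cr <- rules$confidence_rev
  tie <- !is.na(cf) & !is.na(cr) & cf == cr
  swap <- (!is.na(cf) & !is.na(cr) & cr > cf) |
    (tie & rules$rhs < rules$lhs)
  out <- rules
  out[swap, c("lhs", "rhs")] <- rules[swap, c("rhs", "lhs")]
  out[swap, c("n10", "n01")] <- rules[swap, c("n01", "n10")]
  out[swap, c("confidence_fwd", "confidence_rev")] <-
    rules[swap, c("confidence_rev", "confidence_fwd")]
  out$direction_tie <- tie
  rownames(out) <- NULL
  out
}

#' End-to-end selection of significant directed rules
#'
#' Composes the full selection workflow: threshold sweep -> per-threshold
#' mining with q-values adjusted over the sweep-wide family of evaluated
#' p-values -> three-criteria filtering -> per-phenotype optimal
#' thresholds -> accumulation and deduplication -> direction resolution.
#'
#' @param x either a \code{call_sweep} (from
#'   \code{\link{sweep_call_matrices}}), a named list of
#'   \code{\link{call_matrix}} objects (one per threshold), or a long-format
#'   measurement data.frame (then \code{annotation} is required).
#' @param annotation annotation map, required when \code{x} is a
#'   measurement table.
#' @param grid threshold grid (used when sweeping measurements, and as the
#'   labels of a pre-swept list).
#' @param min_co,min_lift,max_q selection criteria (see
#'   \code{\link{filter_rules}}).
#' @param pi0 optional fixed pi0 for q-values (per sweep step).
#' @param ... passed to \code{\link{sweep_call_matrices}}.
#' @return object of class \code{significant_rule_set}: list with
#'   \code{rules} (directed, deduplicated data.frame), \code{phenotypes}
#'   (roster), \code{optimal_thresholds}, \code{grid} and the selection
#'   \code{criteria}.
#' @export
select_significant_rules <- function(x, annotation = NULL,
                                     grid = threshold_grid(),
                                     min_co = 2, min_lift = 2, max_q = 0.1,
                                     pi0 = NULL, ...) {
  if (is.data.frame(x)) {
    if (is.null(annotation)) {
      stop("annotation map required when mining from measurements")
    }
    x <- sweep_call_matrices(x, annotation, grid = grid, ...)
  }
  matrices <- if (inherits(x, "call_sweep")) {
    grid <- x$grid
    x$matrices
  } else {
    x
  }
  stopifnot(length(matrices) == length(grid))
  # mine every sweep step, then adjust all rule-significance p-values as a
  # single family: the q-value correction covers the whole mining pass, so
  # gate-sparse steps (few evaluated pairs) cannot locally deflate q
  mined <- lapply(matrices, mine_all, qvalues = FALSE)
  pooled_p <- unlist(lapply(mined, `[[`, "significance_p"))
  pooled_q <- compute_qvalues(pooled_p, pi0 = pi0)
  offset <- 0L
  filtered <- lapply(mined, function(m) {
    m$q <- pooled_q[offset + seq_len(nrow(m))]
    offset <<- offset + nrow(m)
    filter_rules(m, min_co = min_co, min_lift = min_lift, max_q = max_q)
  })
  optimal <- optimal_threshold_per_phenotype(filtered, grid)
  acc <- accumulate_and_dedupe(filtered, optimal, grid)
  rules <- if (is.null(acc) || nrow(acc) == 0L) {
    empty <- filter_rules(mine_all(matrices[[1L]], pi0 = 1))[0, ]
    empty$selected_threshold <- numeric(0)
    resolve_direction(empty)
  } else {
    resolve_direction(acc)
  }
  structure(list(rules = rules,
                 phenotypes = sort(unique(c(rules$lhs, rules$rhs))),
                 optimal_thresholds = optimal,
                 grid = grid,
                 criteria = list(min_co = min_co, min_lift = min_lift,
                                 max_q = max_q)),
            class = "significant_rule_set")
}

#' @export
print.significant_rule_set <- function(x, ...) {
  cat(sprintf(paste0("significant_rule_set: %d directed rules over %d ",
                     "phenotypes\n  criteria: n11 >= %g, lift > %g, q < %g; ",
                     "grid %g..%g\n"),
              nrow(x$rules), length(x$phenotypes),
              x$criteria$min_co, x$criteria$min_lift, x$criteria$max_q,
              min(x$grid), max(x$grid)))
  invisible(x)
}
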