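#' Simpson (overlap) distance between two id sets
#'
#' \code{1 - |A intersect B| / min(|A|, |B|)}: 0 when one set contains the
#' other, 1 when disjoint.
#'
#' @param setA,setB non-empty character vectors (treated as sets).
#' @return distance in \[0, 1\].
#' @export
simpson_distance <- function(setA, setB) {
  a <- unique(setA)
  b <- unique(setB)
  if (length(a) == 0L || length(b) == 0L) {
    stop("Simpson distance undefined for empty sets")
  }
  1 - length(intersect(a, b)) / min(length(a), length(b))
}

simpson_distance_matrix <- function(sets) {
  n <- length(sets)
  d <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- simpson_distance(sets[[i]], sets[[j]])
    }
  }
  d
}

#' Cluster PPAPs by Ward linkage on Simpson distances
#'
#' Pairwise Simpson distances over the PPAPs' phenotype node sets are
#' agglomerated with Ward linkage (\code{hclust}, \code{ward.D2}) and the
#' tree is cut into \code{k} communities. Items are canonicalised to query
#' order before clustering, so the result is invariant to input order.
#'
#' @param ppaps list of \code{ppap} objects (or a named list of character
#'   sets).
#' @param k number of communities to cut (default 7, the phenotype-level
#'   community count).
#' @return object of class \code{cluster_result}: \code{labels} (named
#'   integer vector in 1..k), \code{tree} (hclust), \code{k}.
#' @export
cluster_ppaps <- function(ppaps, k = 7) {
  sets <- if (length(ppaps) > 0L && inherits(ppaps[[1L]], "ppap")) {
    setNames(lapply(ppaps, `[[`, "nodes"),
             vapply(ppaps, `[[`, character(1), "query"))
  } else {
    ppaps
  }
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("PPAP sets must have unique names")
  }
  if (k > length(sets)) {
    stop("parameter error: k exceeds the number of items")
  }
  sets <- sets[order(names(sets))]
  d <- simpson_distance_matrix(sets)
  tree <- hclust(as.dist(d), method = "ward.D2")
  labels <- cutree(tree, k = k)
  structure(list(labels = labels, tree = tree, k = k),
            class = "cluster_result")
}

#' Cluster biological systems by their PPAP occupancy
#'
#' Each biological system is represented by the set of PPAPs containing at
#' least one phenotype annotated to it; systems are then clustered with
#' Ward linkage on Simpson distances (default cut k = 4, matching the four
#' stage/type categories).
#'
#' @param ppaps list of \code{ppap} objects.
#' @param annotation annotation map with \code{phenotype_id},
#'   \code{biological_systems}.
#' @param k number of clusters (default 4).
#' @return a \code{cluster_result} over systems.
#' @export
cluster_biological_systems <- function(ppaps, annotation, k = 4) {
  sys_of <- strsplit(annotation$biological_systems, ";", fixed = TRUE)
  names(sys_of) <- annotation$phenotype_id
  occupancy <- list()
  for (p in ppaps) {
    systems <- unique(unlist(sys_of[p$nodes]))
    for (s in systems) {
      occupancy[[s]] <- c(occupancy[[s]], p$query)
    }
  }
  cluster_ppaps(occupancy, k = k)
}

#' Three-valued PPAP membership matrix
#'
#' Rows are PPAPs (by query), columns are query phenotypes. A cell is
#' \code{member} when the column phenotype belongs to the row PPAP,
#' \code{never_co_tested} when the query/phenotype pair has zero complete
#' cases in the call matrix, and \code{non_member} otherwise.
#'
#' @param ppaps list of \code{ppap} objects.
#' @param calls a \code{\link{call_matrix}} (used for the co-tested check).
#' @return character matrix (queries x queries).
#' @export
build_membership_matrix <- function(ppaps, calls) {
  queries <- sort(vapply(ppaps, `[[`, character(1), "query"))
  ppaps <- ppaps[order(vapply(ppaps, `[[`, character(1), "query"))]
  tested <- (calls[queries, , drop = FALSE] != "NT") + 0
  co <- tcrossprod(tested)
  m <- matrix("non_member", length(queries), length(queries),
              dimnames = list(queries, queries))
  m[co == 0] <- "never_co_tested"
  for (p in ppaps) {
    m[p$query, intersect(p$nodes, queries)] <- "member"
  }
  m
}

#' Adjusted Rand index between two partitions
#'
#' Closed-form ARI on the contingency table of the two label vectors;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) {
    return(1)
  }
  (sum_ij - expected) / (maxi - expected)
}
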