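#' Build the directed rule graph from a significant rule set
#'
#' One node per phenotype appearing in at least one rule; one directed edge
#' per rule, carrying the rule measures as edge attributes.
#'
#' @param atlas a \code{significant_rule_set} or a directed-rule data.frame
#'   with \code{lhs}, \code{rhs} columns.
#' @return an \code{igraph} directed graph.
#' @export
build_rule_graph <- function(atlas) {
  rules <- if (inherits(atlas, "significant_rule_set")) atlas$rules else atlas
  if (is.null(rules) || nrow(rules) == 0L) {
    return(igraph::make_empty_graph(directed = TRUE))
  }
  igraph::graph_from_data_frame(
    rules[, c("lhs", "rhs",
              setdiff(names(rules), c("lhs", "rhs"))), drop = FALSE],
    directed = TRUE)
}

#' Extract the PPAP (ego-module) of a query phenotype
#'
#' The phenotype-phenotype association pair set of a query is its closed
#' one-hop neighborhood in the rule graph (the query plus all direct
#' in/out neighbors) together with every atlas rule among those nodes —
#' edges between neighbors carry the indirectly related relationships.
#'
#' @param graph rule graph from \code{\link{build_rule_graph}}.
#' @param query phenotype id present in the graph.
#' @param annotation optional annotation map (with \code{phenotype_id} and
#'   \code{biological_systems}) used to fill the biological-system stats.
#' @return object of class \code{ppap}: list with \code{query},
#'   \code{nodes}, \code{edges} (data.frame), \code{graph} (induced
#'   subgraph) and \code{stats} (\code{n_phenotypes} excluding the query,
#'   \code{indegree}/\code{outdegree} of the query, and when annotated,
#'   \code{n_distinct_biological_systems},
#'   \code{n_same_system_as_query}).
#' @export
extract_ppap <- function(graph, query, annotation = NULL) {
  if (!query %in% igraph::V(graph)$name) {
    stop("query phenotype not present in rule graph: ", query)
  }
  nb <- igraph::ego(graph, order = 1, nodes = query, mode = "all")[[1L]]
  sub <- igraph::induced_subgraph(graph, nb)
  nodes <- sort(igraph::V(sub)$name)
  edges <- igraph::as_data_frame(sub, what = "edges")
  names(edges)[1:2] <- c("lhs", "rhs")
  stats <- list(
    n_phenotypes = length(nodes) - 1L,
    indegree = unname(igraph::degree(graph, query, mode = "in")),
    outdegree = unname(igraph::degree(graph, query, mode = "out")))
  if (!is.null(annotation)) {
    sys_of <- function(ids) {
      hit <- match(ids, annotation$phenotype_id)
      strsplit(annotation$biological_systems[hit], ";", fixed = TRUE)
    }
    node_sys <- sys_of(nodes)
    qsys <- unlist(sys_of(query))
    others <- setdiff(nodes, query)
    stats$n_distinct_biological_systems <-
      length(unique(unlist(node_sys)))
    stats$n_same_system_as_query <- sum(vapply(
      sys_of(others), function(s) any(s %in% qsys), logical(1)))
  }
  structure(list(query = query, nodes = nodes, edges = edges,
                 graph = sub, stats = stats),
            class = "ppap")
}

#' @export
print.ppap <- function(x, ...) {
  cat(sprintf("ppap: query '%s', %d related phenotypes, %d rules\n",
              x$query, x$stats$n_phenotypes, nrow(x$edges)))
  invisible(x)
}

#' In/out-degree deviation of query phenotypes
#'
#' For each query, a two-tailed Fisher exact test contrasts the indegree
#' and outdegree against their transposition,
#' \code{rbind(c(in, out), c(out, in))}. The signed score is -log10 p,
#' negative when outdegree exceeds indegree (relatively rare phenotype) and
#' positive otherwise (relatively common). q-values are computed over all
#' queries and classes assigned at FDR < \code{fdr}.
#'
#' @param graph rule graph.
#' @param queries phenotype ids (default: all nodes with degree >= 1).
#' @param fdr class-assignment threshold (default 0.05).
#' @return data.frame: \code{query}, \code{indegree}, \code{outdegree},
#'   \code{p}, \code{score}, \code{q}, \code{class} (rare/common/neutral).
#' @export
degree_deviation <- function(graph, queries = NULL, fdr = 0.05) {
  if (is.null(queries)) {
    queries <- igraph::V(graph)$name[igraph::degree(graph) >= 1]
  }
  ind <- igraph::degree(graph, queries, mode = "in")
  outd <- igraph::degree(graph, queries, mode = "out")
  if (any(ind + outd == 0L)) {
    stop("degree deviation undefined for zero-degree queries")
  }
  p <- fisher_p_two_sided_vec(ind, outd, outd, ind)
  score <- ifelse(outd - ind > 0, -1, 1) * (-log10(p))
  q <- compute_qvalues(p)
  class <- ifelse(q < fdr & score < 0, "rare",
                  ifelse(q < fdr & score >= 0, "common", "neutral"))
  data.frame(query = queries, indegree = as.integer(ind),
             outdegree = as.integer(outd), p = p, score = score, q = q,
             class = class, stringsAsFactors = FALSE, row.names = NULL)
}

# Depth-first enumeration of simple paths from `from` to `to` over an
# adjacency list; keeps the longest (most edges), breaking ties by
# lexicographically smallest node sequence. Raises a
# `phenorules_too_complex` condition when more than max_paths complete
# paths are enumerated.
longest_simple_path <- function(adj, from, to, max_paths) {
  best <- NULL
  n_found <- 0L
  visit <- function(node, path) {
    if (node == to) {
      n_found <<- n_found + 1L
      if (n_found > max_paths) {
        stop(errorCondition(
          sprintf("too-complex: more than %g simple paths %s -> %s",
                  max_paths, from, to),
          class = c("phenorules_too_complex", "error")))
      }
      if (is.null(best) || length(path) > length(best) ||
          (length(path) == length(best) &&
           paste(path, collapse = "\r") < paste(best, collapse = "\r"))) {
        best <<- path
      }
      return(invisible())
    }
    for (nxt in sort(adj[[node]])) {
      if (!nxt %in% path) {
        visit(nxt, c(path, nxt))
      }
    }
    invisible()
  }
  visit(from, from)
  best
}

adjacency_list <- function(edges, nodes) {
  adj <- split(edges$rhs, factor(edges$lhs, levels = nodes))
  lapply(adj, as.character)
}

reachable_from <- function(adj, start) {
  seen <- start
  frontier <- start
  while (length(frontier) > 0L) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Convert a PPAP into a pathway-like configuration
#'
#' For each outgoing phenotype of the query (any phenotype reachable from it
#' within the PPAP edge set — in a PPAP every node is also a direct
#' neighbor), all simple directed paths from the query to it are enumerated
#' and the longest (most edges) is kept; likewise from each incoming
#' phenotype to the query. The union of all kept paths' edges, with duplicates removed, is
#' the pathway-like configuration. Ties in path length keep the
#' lexicographically smallest node sequence. PPAPs whose path enumeration
#' exceeds \code{max_paths} for some endpoint raise a too-complex error
#' (condition class \code{phenorules_too_complex}) rather than truncating.
#'
#' @param ppap a \code{ppap}.
#' @param max_paths cap on enumerated simple paths per endpoint
#'   (default 1e5).
#' @return object of class \code{pathway_graph}: list with \code{edges}
#'   (data.frame \code{lhs}, \code{rhs}), \code{nodes}, \code{provenance}
#'   (contributing query) and \code{paths} (the kept longest path per
#'   endpoint, named \code{"query->o"} / \code{"i->query"}).
#' @export
convert_to_pathway <- function(ppap, max_paths = 1e5) {
  stopifnot(inherits(ppap, "ppap"))
  adj <- adjacency_list(ppap$edges, ppap$nodes)
  radj <- adjacency_list(data.frame(lhs = ppap$edges$rhs,
                                    rhs = ppap$edges$lhs), ppap$nodes)
  q <- ppap$query
  out_nb <- sort(setdiff(reachable_from(adj, q), q))
  in_nb <- sort(setdiff(reachable_from(radj, q), q))
  paths <- c(
    lapply(out_nb, function(o) longest_simple_path(adj, q, o, max_paths)),
    lapply(in_nb, function(i) longest_simple_path(adj, i, q, max_paths)))
  names(paths) <- c(if (length(out_nb)) paste0(q, "->", out_nb),
                    if (length(in_nb)) paste0(in_nb, "->", q))
  edges <- unique(do.call(rbind, lapply(paths, function(p) {
    if (is.null(p) || length(p) < 2L) return(NULL)
    data.frame(lhs = p[-length(p)], rhs = p[-1L], stringsAsFactors = FALSE)
  })))
  if (is.null(edges)) {
    edges <- data.frame(lhs = character(0), rhs = character(0),
                        stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$lhs, edges$rhs))),
                 provenance = q,
                 paths = paths),
            class = "pathway_graph")
}

#' Union pathway-like configurations into a phenome-wide pathway
#'
#' Edge union without duplicates; per-edge provenance lists the
#' contributing PPAP queries.
#'
#' @param pathways list of \code{pathway_graph} objects.
#' @return a \code{pathway_graph} whose \code{edges} carry a
#'   \code{provenance} column (comma-separated contributing queries).
#' @export
build_phenome_pathway <- function(pathways) {
  pieces <- do.call(rbind, lapply(pathways, function(p) {
    if (nrow(p$edges) == 0L) return(NULL)
    data.frame(lhs = p$edges$lhs, rhs = p$edges$rhs,
               src = p$provenance, stringsAsFactors = FALSE)
  }))
  if (is.null(pieces)) {
    return(structure(list(edges = data.frame(lhs = character(0),
                                             rhs = character(0),
                                             provenance = character(0)),
                          nodes = character(0),
                          provenance = character(0)),
                     class = "pathway_graph"))
  }
  key <- paste(pieces$lhs, pieces$rhs, sep = "\r")
  prov <- vapply(split(pieces$src, key),
                 function(s) paste(sort(unique(s)), collapse = ","),
                 character(1))
  uniq <- pieces[!duplicated(key), c("lhs", "rhs"), drop = FALSE]
  uniq$provenance <- prov[paste(uniq$lhs, uniq$rhs, sep = "\r")]
  rownames(uniq) <- NULL
  structure(list(edges = uniq,
                 nodes = sort(unique(c(uniq$lhs, uniq$rhs))),
                 provenance = sort(unique(pieces$src))),
            class = "pathway_graph")
}

#' Brute-force longest simple path (test oracle)
#'
#' Enumerates every simple directed path from \code{source} to
#' \code{target} via \code{igraph::all_simple_paths} and returns the
#' longest, breaking length ties by lexicographically smallest node
#' sequence. Intended as an independent cross-check of
#' \code{\link{convert_to_pathway}} on small graphs (<= 12 nodes).
#'
#' @param edges data.frame with \code{lhs}, \code{rhs}.
#' @param source,target node ids.
#' @return character vector of nodes along the path, or NULL if none.
#' @export
longest_path_oracle <- function(edges, source, target) {
  nodes <- sort(unique(c(edges$lhs, edges$rhs, source, target)))
  if (length(nodes) > 12L) {
    stop("oracle restricted to graphs with <= 12 nodes")
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  paths <- igraph::all_simple_paths(g, from = source, to = target,
                                    mode = "out")
  if (length(paths) == 0L) {
    return(NULL)
  }
  seqs <- lapply(paths, function(p) igraph::V(g)$name[p])
  lens <- lengths(seqs)
  cand <- seqs[lens == max(lens)]
  keys <- vapply(cand, paste, character(1), collapse = "\r")
  cand[[order(keys)[1L]]]
}

#' Rank mutant strains by overlap with a PPAP
#'
#' Lists the strains called abnormal for the query phenotype, scoring each
#' by the count and proportion of PPAP-constituting phenotypes (query
#' included) abnormal in that strain, sorted in descending order of count
#' with ties broken by strain id.
#'
#' @param ppap a \code{ppap}.
#' @param calls a \code{\link{call_matrix}} covering the PPAP phenotypes.
#' @return data.frame: \code{strain}, \code{n_overlap},
#'   \code{prop_overlap}.
#' @export
rank_genes <- function(ppap, calls) {
  miss <- setdiff(ppap$nodes, rownames(calls))
  if (length(miss) > 0L) {
    stop("call matrix does not cover PPAP phenotypes: ",
         paste(miss, collapse = ", "))
  }
  eligible <- colnames(calls)[calls[ppap$query, ] == "A"]
  sub <- calls[ppap$nodes, eligible, drop = FALSE] == "A"
  counts <- colSums(sub)
  out <- data.frame(strain = eligible,
                    n_overlap = as.integer(counts),
                    prop_overlap = counts / length(ppap$nodes),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_overlap, out$strain), , drop = FALSE]
}
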