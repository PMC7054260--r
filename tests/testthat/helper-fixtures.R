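# Shared fixtures and independent oracles for the test suite.

# Build a call matrix from per-phenotype call strings, e.g.
# cm(X = "A A N N", Y = "A N A N").
cm <- function(...) {
  rows <- list(...)
  vals <- lapply(rows, function(s) strsplit(trimws(s), "\\s+")[[1]])
  m <- do.call(rbind, vals)
  rownames(m) <- names(rows)
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  call_matrix(m)
}

# Independent two-sided Fisher oracle: enumerates the conditional table
# support and accumulates probabilities via choose() arithmetic (no dhyper).
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) {
    return(1)
  }
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  prob <- function(k) choose(r1, k) * choose(r2, c1 - k) / choose(n, c1)
  pk <- vapply(lo:hi, prob, numeric(1))
  min(1, sum(pk[pk <= prob(a) * (1 + 1e-7)]))
}

# All 2x2 tables with total N in n_range as a matrix of (a, b, c, d) rows.
all_tables <- function(n_range) {
  do.call(rbind, lapply(n_range, function(n) {
    out <- list()
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      out[[length(out) + 1L]] <- c(a, b, cc, n - a - b - cc)
    }
    do.call(rbind, out)
  }))
}

# Random DAG edge list on nodes n01..nXX (edges only from lower to higher
# index, so the graph is acyclic by construction).
random_dag <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  idx <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < p_edge
  data.frame(lhs = nodes[idx[keep, 1]], rhs = nodes[idx[keep, 2]],
             stringsAsFactors = FALSE)
}

# Wrap an edge list as a minimal ppap object for conversion tests.
as_test_ppap <- function(edges, query) {
  nodes <- sort(unique(c(edges$lhs, edges$rhs, query)))
  structure(list(query = query, nodes = nodes, edges = edges,
                 graph = NULL, stats = list()),
            class = "ppap")
}

# Small planted-corpus helper used across selection/ppap tests.
planted_corpus <- function(n_phenotypes = 30, n_strains = 800,
                           cliques = c(3, 3), lift = 8, seed = 1,
                           missing_rate = 0.2) {
  cfg <- sim_config(n_phenotypes = n_phenotypes, n_strains = n_strains,
                    n_controls_per_parameter = 40,
                    planted_pairs = planted_clique_pairs(cliques, lift),
                    missing_rate = missing_rate, seed = seed)
  catalog <- generate_catalog(cfg)
  gen <- generate_measurements(cfg, catalog)
  list(config = cfg, catalog = catalog, measurements = gen$measurements,
       truth = gen$truth)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
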