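toy_atlas <- function() {
  data.frame(lhs = c("A", "B", "A"), rhs = c("B", "C", "C"),
             lift = c(3, 4, 5), confidence_fwd = c(0.5, 0.6, 0.7),
             stringsAsFactors = FALSE)
}

test_that("the rule graph mirrors the atlas and satisfies the handshake", {
  g <- build_rule_graph(toy_atlas())
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
  expect_equal(sum(igraph::degree(g, mode = "in")), igraph::ecount(g))
  expect_equal(sum(igraph::degree(g, mode = "out")), igraph::ecount(g))
  empty <- build_rule_graph(toy_atlas()[0, ])
  expect_equal(igraph::vcount(empty), 0)
})

test_that("a PPAP is the closed neighborhood with induced edges", {
  star <- data.frame(lhs = c("A", "A"), rhs = c("B", "C"))
  p <- extract_ppap(build_rule_graph(star), "A")
  expect_setequal(p$nodes, c("A", "B", "C"))
  expect_equal(nrow(p$edges), 2)
  expect_equal(p$stats$n_phenotypes, 2)
  # neighbor-neighbor edges (indirect relationships) are retained
  tri <- extract_ppap(build_rule_graph(toy_atlas()), "A")
  expect_true(any(tri$edges$lhs == "B" & tri$edges$rhs == "C"))
  # cross-check against the igraph induced-subgraph oracle
  g <- build_rule_graph(toy_atlas())
  ind <- igraph::induced_subgraph(
    g, igraph::ego(g, 1, "A", mode = "all")[[1]])
  expect_equal(nrow(tri$edges), igraph::ecount(ind))
  expect_error(extract_ppap(g, "nope"), "not present")
})

test_that("PPAP stats count distinct and query-shared biological systems", {
  ann <- data.frame(
    parameter_id = paste0("p", 1:3),
    phenotype_id = c("A", "B", "C"),
    stage_type = "adult_trait",
    biological_systems = c("s1", "s1;s2", "s3"))
  p <- extract_ppap(build_rule_graph(toy_atlas()), "A", annotation = ann)
  expect_equal(p$stats$n_distinct_biological_systems, 3)
  expect_equal(p$stats$n_same_system_as_query, 1)
  expect_equal(p$stats$indegree + p$stats$outdegree, 2)
})

test_that("degree deviation matches the hypergeometric oracle and sign rule", {
  chain <- data.frame(lhs = c(paste0("x", 1:10)), rhs = "hub")
  g <- build_rule_graph(chain)
  dd <- degree_deviation(g, "hub")
  expect_equal(dd$indegree, 10)
  expect_equal(dd$outdegree, 0)
  expect_equal(dd$p, oracle_fisher_two_sided(10, 0, 0, 10), tolerance = 1e-9)
  expect_gt(dd$score, 0)                      # indegree excess -> positive
  rev <- build_rule_graph(data.frame(lhs = "hub", rhs = paste0("x", 1:10)))
  dr <- degree_deviation(rev, "hub")
  expect_equal(dr$p, 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(dr$score, log10(2 / choose(20, 10)), tolerance = 1e-6)
  expect_lt(dr$score, 0)                      # outdegree excess -> negative
  bal <- degree_deviation(build_rule_graph(
    data.frame(lhs = c("hub", "a"), rhs = c("b", "hub"))), "hub")
  expect_equal(bal$p, 1)
  expect_equal(bal$score, 0)
  expect_equal(bal$class, "neutral")
})

test_that("degree-deviation classes respect the score sign", {
  set.seed(6)
  edges <- random_dag(12, 0.5, seed = 61)
  g <- build_rule_graph(edges)
  dd <- degree_deviation(g)
  expect_true(all(dd$class[dd$score < 0 & dd$q < 0.05] == "rare"))
  expect_true(all(dd$class[dd$q >= 0.05] == "neutral"))
  expect_true(all(dd$p > 0 & dd$p <= 1))
})

test_that("pathway conversion keeps longest paths and absorbs shortcuts", {
  ppap <- as_test_ppap(toy_atlas()[, c("lhs", "rhs")], "A")
  pw <- convert_to_pathway(ppap)
  expect_setequal(paste(pw$edges$lhs, pw$edges$rhs),
                  c("A B", "B C"))            # A->C absorbed into A->B->C
  single <- convert_to_pathway(
    as_test_ppap(data.frame(lhs = "A", rhs = "B"), "A"))
  expect_equal(nrow(single$edges), 1)
  # idempotence on DAG input: converting the conversion changes nothing
  again <- convert_to_pathway(as_test_ppap(pw$edges, "A"))
  expect_equal(again$edges, pw$edges)
})

test_that("path enumeration beyond the cap raises a too-complex error", {
  n <- 10
  nodes <- sprintf("n%02d", 1:n)
  idx <- which(outer(1:n, 1:n, "!="), arr.ind = TRUE)
  complete <- data.frame(lhs = nodes[idx[, 1]], rhs = nodes[idx[, 2]])
  expect_error(convert_to_pathway(as_test_ppap(complete, "n01"),
                                  max_paths = 1000),
               class = "phenorules_too_complex")
})

test_that("kept paths equal the brute-force oracle on random DAGs", {
  for (s in 1:40) {
    edges <- random_dag(sample(4:10, 1), runif(1, 0.25, 0.6), seed = 1000 + s)
    if (nrow(edges) == 0) next
    nodes <- unique(c(edges$lhs, edges$rhs))
    query <- sample(nodes, 1)
    ppap <- as_test_ppap(edges, query)
    pw <- convert_to_pathway(ppap)
    for (nm in names(pw$paths)) {
      ends <- strsplit(nm, "->", fixed = TRUE)[[1]]
      expect_equal(pw$paths[[nm]],
                   longest_path_oracle(edges, ends[1], ends[2]),
                   label = paste("seed", s, nm))
    }
  }
})

test_that("the oracle itself honours length and lexicographic tie rules", {
  chain <- data.frame(lhs = c("a", "b", "c", "d"), rhs = c("b", "c", "d", "e"))
  expect_equal(longest_path_oracle(chain, "a", "e"),
               c("a", "b", "c", "d", "e"))
  # two equal-length routes a->b->d and a->c->d: lexicographically smaller
  tie <- data.frame(lhs = c("a", "a", "b", "c"), rhs = c("b", "c", "d", "d"))
  expect_equal(longest_path_oracle(tie, "a", "d"), c("a", "b", "d"))
  expect_null(longest_path_oracle(chain, "e", "a"))
  big <- data.frame(lhs = sprintf("m%02d", 1:13), rhs = sprintf("m%02d", 2:14))
  expect_error(longest_path_oracle(big, "m01", "m14"), "12 nodes")
})

test_that("the phenome pathway is a provenance-tracked edge union", {
  p1 <- convert_to_pathway(as_test_ppap(
    data.frame(lhs = c("A", "B", "A"), rhs = c("B", "C", "C")), "A"))
  p2 <- convert_to_pathway(as_test_ppap(
    data.frame(lhs = c("B", "D"), rhs = c("C", "C")), "C"))
  u <- build_phenome_pathway(list(p1, p2))
  expect_equal(anyDuplicated(paste(u$edges$lhs, u$edges$rhs)), 0)
  shared <- u$edges$provenance[u$edges$lhs == "B" & u$edges$rhs == "C"]
  expect_equal(shared, "A,C")
  expect_setequal(u$nodes, unique(c(u$edges$lhs, u$edges$rhs)))
  expect_setequal(u$nodes, union(p1$nodes, p2$nodes))
})

test_that("gene ranking lists query-abnormal strains by PPAP overlap", {
  calls <- cm(Q = "A A N NT",
              B = "A N A A",
              C = "A N A N",
              Z = "N N A A")
  ppap <- extract_ppap(build_rule_graph(
    data.frame(lhs = c("Q", "Q"), rhs = c("B", "C"))), "Q")
  ranked <- rank_genes(ppap, calls)
  # s03 is normal for the query, s04 not tested: both excluded
  expect_equal(ranked$strain, c("s01", "s02"))
  expect_equal(ranked$n_overlap, c(3, 1))
  expect_equal(ranked$prop_overlap, c(1, 1 / 3))
  expect_error(rank_genes(ppap, calls[c("Q", "B"), ]), "cover")
})
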