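test_that("fisher enrichment reports fold, direction and exact p", {
  flat <- fisher_enrichment(matrix(c(5, 5, 5, 5), 2), tail = "two")
  expect_equal(flat$fold, 1)
  expect_equal(flat$p, 1)
  er <- fisher_enrichment(matrix(c(2, 0, 0, 8), 2, byrow = TRUE),
                          tail = "two")
  expect_equal(er$p, 1 / 45, tolerance = 1e-9)
  expect_equal(er$direction, "positive")
  one <- fisher_enrichment(matrix(c(8, 2, 2, 8), 2, byrow = TRUE),
                           tail = "one")
  two <- fisher_enrichment(matrix(c(8, 2, 2, 8), 2, byrow = TRUE),
                           tail = "two")
  expect_lte(one$p, two$p)
  dep <- fisher_enrichment(matrix(c(1, 2, 3, 4), 2, byrow = TRUE),
                           tail = "one")
  expect_true(is.na(dep$p))                    # fold < 1: one-tailed skipped
  deg <- fisher_enrichment(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

stage_ann <- function() {
  data.frame(parameter_id = paste0("par", 1:8),
             phenotype_id = paste0("p", 1:8),
             stage_type = rep(c("adult_trait", "adult_gene"), each = 4),
             biological_systems = rep(c("s1", "s2", "s1;s2", "s3"), 2))
}

test_that("stage/type enrichment contrasts rules against possible pairs", {
  ann <- stage_ann()
  rules <- data.frame(lhs = c("p1", "p2", "p3"), rhs = c("p2", "p3", "p4"))
  out <- stage_type_rule_enrichment(rules, ann)
  expect_equal(nrow(out), 16)
  at <- out[out$lhs_category == "adult_trait" &
              out$rhs_category == "adult_trait", ]
  expect_equal(at$observed, 3)
  expect_equal(at$possible, 4 * 3)
  expect_true(all(out$p_holm >= out$p - 1e-12, na.rm = TRUE))
  expect_equal(at$direction, "positive")
  # a same-category-only atlas puts all mass on one diagonal cell
  expect_equal(sum(out$observed), 3)
})

test_that("system-pair enrichment counts cross pairs and conserves totals", {
  ann <- data.frame(parameter_id = paste0("par", 1:6),
                    phenotype_id = paste0("p", 1:6),
                    stage_type = "adult_trait",
                    biological_systems = rep(c("s1", "s2", "s3"), each = 2))
  rules <- data.frame(lhs = c("p1", "p3", "p1"), rhs = c("p3", "p5", "p2"))
  out <- system_pair_enrichment(rules, ann)
  # p1->p2 is within-system; two between-system rules in two categories
  expect_equal(sum(out$observed), 2)
  expect_setequal(paste(out$system_a, out$system_b), c("s1 s2", "s2 s3"))
  expect_equal(out$possible[paste(out$system_a, out$system_b) == "s1 s2"],
               4)
  single <- system_pair_enrichment(
    data.frame(lhs = "p1", rhs = "p2"),
    data.frame(parameter_id = c("a", "b"), phenotype_id = c("p1", "p2"),
               stage_type = "adult_trait", biological_systems = "s1"))
  expect_equal(nrow(single), 0)
})

test_that("cross-pair counting handles shared membership exactly", {
  # A = {1,2,3}, B = {2,3,4}: |A||B| - |I| - C(|I|,2) = 9 - 2 - 1 = 6
  a <- c(TRUE, TRUE, TRUE, FALSE)
  b <- c(FALSE, TRUE, TRUE, TRUE)
  expect_equal(phenorules:::cross_pair_count(a, b), 6)
  # exhaustive check against direct enumeration
  set.seed(2)
  for (i in 1:20) {
    n <- 8
    x <- runif(n) < 0.5
    y <- runif(n) < 0.5
    direct <- 0
    for (p in 1:(n - 1)) for (q in (p + 1):n) {
      if ((x[p] && y[q]) || (x[q] && y[p])) direct <- direct + 1
    }
    expect_equal(phenorules:::cross_pair_count(x, y), direct)
  }
})

test_that("bootstrap expectation is zero for one system and grows with draws", {
  ann1 <- data.frame(parameter_id = paste0("a", 1:10),
                     phenotype_id = paste0("p", 1:10),
                     stage_type = "adult_trait", biological_systems = "s1")
  u1 <- possible_pair_categories(ann1)
  b1 <- bootstrap_expected_system_pairs(u1, n_rules = 10, observed = 0,
                                        B = 1000, seed = 1)
  expect_equal(b1$expected, 0)
  ann2 <- data.frame(parameter_id = paste0("a", 1:12),
                     phenotype_id = paste0("p", 1:12),
                     stage_type = "adult_trait",
                     biological_systems = rep(paste0("s", 1:4), each = 3))
  u2 <- possible_pair_categories(ann2)
  e <- vapply(c(5, 20, 50), function(k) {
    bootstrap_expected_system_pairs(u2, k, observed = 0, B = 1000,
                                    seed = 2)$expected
  }, numeric(1))
  expect_true(all(diff(e) > 0))
  expect_lte(max(e), choose(4, 2))
})

test_that("measure extremes are empty for constant measures, found otherwise", {
  ann <- stage_ann()
  rules <- data.frame(
    lhs = c("p1", "p2", "p3", "p5", "p6", "p7"),
    rhs = c("p2", "p3", "p4", "p6", "p7", "p8"),
    support = c(0.5, 0.6, 0.55, 0.01, 0.02, 0.015),
    confidence_fwd = 0.5, polarity = 1, significance_p = 0.01)
  out <- measure_extreme_enrichment(rules, "support", ann)
  up <- out[out$category == "adult_trait=>adult_trait" &
              out$extreme == "upper", ]
  expect_equal(up$observed, 2)                 # the two top-quartile rules
  expect_gt(up$fold, 1)
  expect_true(all(out$p_bonferroni >= out$p, na.rm = TRUE))
  const <- rules
  const$support <- 0.3
  expect_equal(nrow(measure_extreme_enrichment(const, "support", ann)), 0)
  expect_error(measure_extreme_enrichment(rules, "oddity", ann),
               "parameter error")
})

test_that("measure correlations match a rank-transform Pearson oracle", {
  set.seed(5)
  n <- 40
  rules <- data.frame(
    lhs = paste0("x", 1:n), rhs = paste0("y", 1:n),
    support = runif(n), confidence_fwd = runif(n),
    polarity = runif(n), significance_p = runif(n))
  out <- measure_correlations(rules)
  expect_equal(nrow(out), 6)
  sc <- out[out$measure_a == "support" & out$measure_b == "confidence", ]
  expect_equal(sc$rho,
               cor(rank(rules$support), rank(rules$confidence_fwd)),
               tolerance = 1e-12)
  # anti-monotone columns give rho = -1
  anti <- rules
  anti$confidence_fwd <- -anti$support
  out2 <- measure_correlations(anti)
  expect_equal(out2$rho[out2$measure_a == "support" &
                          out2$measure_b == "confidence"], -1)
  expect_error(measure_correlations(rules[1:2, ]), "at least 3")
})
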