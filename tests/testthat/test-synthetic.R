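test_that("config validation rejects bad probabilities, counts and coupling", {
  expect_error(sim_config(abnormality_rate = 1.2), "probabilities")
  expect_error(sim_config(n_phenotypes = 0), "counts")
  expect_error(sim_config(stage_type_mix = c(a = 1)), "stage_type_mix")
  pp <- data.frame(phenotype_i = 1, phenotype_j = 2, lift = 30)
  expect_error(sim_config(abnormality_rate = 0.04, planted_pairs = pp),
               "infeasible")
  expect_error(sim_config(planted_pairs =
                            data.frame(phenotype_i = 1, phenotype_j = 1,
                                       lift = 2)),
               "self")
  # overlapping pairs must complete a clique with one lift value
  tri_open <- data.frame(phenotype_i = c(1, 2), phenotype_j = c(2, 3),
                         lift = 2)
  expect_error(sim_config(planted_pairs = tri_open), "cliques")
  tri_mixed <- data.frame(phenotype_i = c(1, 1, 2), phenotype_j = c(2, 3, 3),
                          lift = c(2, 2, 3))
  expect_error(sim_config(planted_pairs = tri_mixed), "single lift")
  tri_ok <- data.frame(phenotype_i = c(1, 1, 2), phenotype_j = c(2, 3, 3),
                       lift = 2)
  expect_s3_class(sim_config(planted_pairs = tri_ok), "sim_config")
})

test_that("catalog respects a degenerate stage mix and is deterministic", {
  cfg <- sim_config(n_phenotypes = 4, seed = 2,
                    stage_type_mix = c(adult_trait = 1, adult_gene = 0,
                                       embryo_trait = 0, embryo_gene = 0))
  cat1 <- generate_catalog(cfg)
  expect_equal(nrow(cat1), 4)
  expect_true(all(cat1$stage_type == "adult_trait"))
  expect_true(all(startsWith(cat1$phenotype_id, "adult_trait:")))
  expect_identical(cat1, generate_catalog(cfg))
})

test_that("catalog stage proportions track the configured mix", {
  mix <- c(adult_trait = 0.55, adult_gene = 0.3, embryo_trait = 0.1,
           embryo_gene = 0.05)
  cfg <- sim_config(n_phenotypes = 500, seed = 1, stage_type_mix = mix)
  tab <- table(generate_catalog(cfg)$stage_type) / 500
  expect_true(all(abs(tab[names(mix)] - mix) < 0.05))
})

test_that("generator output is byte-identical under the same config and seed", {
  cfg <- sim_config(n_phenotypes = 12, n_strains = 60,
                    n_controls_per_parameter = 10, missing_rate = 0.2,
                    seed = 9)
  g1 <- generate_measurements(cfg, generate_catalog(cfg))
  g2 <- generate_measurements(cfg, generate_catalog(cfg))
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))
  c1 <- generate_call_matrix(cfg)
  c2 <- generate_call_matrix(cfg)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
})

test_that("without planting or masking, statuses are complete and independent", {
  cfg <- sim_config(n_phenotypes = 40, n_strains = 250, missing_rate = 0,
                    abnormality_rate = 0.1, seed = 4)
  res <- generate_call_matrix(cfg)
  expect_true(all(res$calls %in% c("A", "N")))
  # chi-square independence across 100 random pairs, none rejected at 0.01
  # after accounting for multiplicity (Bonferroni)
  set.seed(99)
  pairs <- replicate(100, sample(rownames(res$calls), 2), simplify = FALSE)
  pvals <- vapply(pairs, function(pr) {
    tab <- table(res$calls[pr[1], ], res$calls[pr[2], ])
    if (any(dim(tab) < 2)) return(1)
    suppressWarnings(chisq.test(tab)$p.value)
  }, numeric(1))
  expect_gt(min(pvals) * 100, 0.01)
})

test_that("planted co-abnormal counts match the binomial moment oracle", {
  pp <- data.frame(phenotype_i = 1, phenotype_j = 2, lift = 5)
  cfg <- sim_config(n_phenotypes = 10, n_strains = 3000,
                    abnormality_rate = 0.04, planted_pairs = pp,
                    missing_rate = 0, seed = 7)
  res <- generate_call_matrix(cfg)
  both <- sum(res$calls[1, ] == "A" & res$calls[2, ] == "A")
  expected <- 3000 * 5 * 0.04^2                     # 24
  sd3 <- 3 * sqrt(3000 * (5 * 0.04^2) * (1 - 5 * 0.04^2))
  expect_lt(abs(both - expected), sd3)
  # marginals stay calibrated despite the coupling
  for (i in 1:2) {
    rate <- mean(res$calls[i, ] == "A")
    expect_lt(abs(rate - 0.04), 3 * sqrt(0.04 * 0.96 / 3000))
  }
})

test_that("clique planting gives every within-clique pair the configured lift", {
  pp <- planted_clique_pairs(c(4), lift = 6)
  expect_equal(nrow(pp), 6)
  cfg <- sim_config(n_phenotypes = 6, n_strains = 40000,
                    abnormality_rate = 0.05, planted_pairs = pp,
                    missing_rate = 0, seed = 13)
  res <- generate_call_matrix(cfg)
  A <- res$calls == "A"
  for (r in seq_len(nrow(pp))) {
    joint <- mean(A[pp$phenotype_i[r], ] & A[pp$phenotype_j[r], ])
    target <- 6 * 0.05^2
    expect_lt(abs(joint - target), 3 * sqrt(target * (1 - target) / 40000))
  }
})

test_that("masking and rate extremes behave as documented", {
  cfg <- sim_config(n_phenotypes = 5, n_strains = 30, missing_rate = 1,
                    seed = 1)
  expect_true(all(generate_call_matrix(cfg)$calls == "NT"))
  cfg0 <- sim_config(n_phenotypes = 5, n_strains = 30,
                     abnormality_rate = 0, missing_rate = 0.2, seed = 1)
  expect_false(any(generate_call_matrix(cfg0)$calls == "A"))
})

test_that("abnormal fraction of tested cells is calibrated at scale", {
  cfg <- sim_config(n_phenotypes = 500, n_strains = 3000,
                    abnormality_rate = 0.04, seed = 3)
  res <- generate_call_matrix(cfg)
  tested <- res$calls != "NT"
  frac <- sum(res$calls == "A") / sum(tested)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.05)
  n <- sum(tested)
  expect_lt(abs(frac - 0.04), 3 * sqrt(0.04 * 0.96 / n))
})

test_that("measurement tables carry the latent shift and the truth set", {
  corp <- planted_corpus(n_phenotypes = 8, n_strains = 60, cliques = c(2),
                         seed = 5)
  meas <- corp$measurements
  expect_setequal(unique(meas$cohort), c("mutant", "control"))
  expect_equal(sum(meas$cohort == "control"),
               8 * corp$config$n_controls_per_parameter)
  # latently abnormal cells should average near delta, normal cells near 0
  truth <- corp$truth
  key <- paste(meas$parameter_id, meas$strain_id)
  abn_phen <- rownames(truth$latent_status)[1]
  abn_param <- corp$catalog$parameter_id[
    match(abn_phen, corp$catalog$phenotype_id)]
  mut <- meas[meas$cohort == "mutant" & meas$parameter_id == abn_param, ]
  status <- truth$latent_status[abn_phen, mut$strain_id]
  if (sum(status == 1) > 0 && sum(status == 0) > 0) {
    expect_gt(mean(mut$value[status == 1]), mean(mut$value[status == 0]))
  }
})
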