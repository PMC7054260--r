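# phenorules

Phenome-wide phenotype–phenotype association rule mining for
mutant-strain phenotyping screens.

Large knockout screens measure hundreds of quantitative parameters over
thousands of single-gene mutant strains. When abnormality of one phenotype
predicts abnormality of another across strains, that co-abnormality is
direct, measurement-based evidence of a relationship between the two
phenotypes — pleiotropy, shared pathways, secondary effects. phenorules
derives such relationships as weighted, directed association rules and
organises them into per-phenotype modules, pathway-like configurations and
communities. It is aimed at researchers analysing systematic phenotyping
corpora (or any strain × trait screen with normal/abnormal calls) who want
a tested, reproducible implementation of the whole workflow, plus a
synthetic-corpus generator with known ground truth for validating it.

## The method in brief

1. **Calls.** Each (parameter, strain) cell is scored by unbiased Hedges'
   g = J·(x̄ₘ − x̄꜀)/sₚ with J = 1 − 3/(4·df − 1). A cell is *abnormal* at
   threshold t iff |g| ≥ t, the effect is significant at the 95% level
   (p for g < 0.05), and an accompanying exact test (Welch by default) has
   p < 0.05; otherwise *normal*, or *not-tested* when not computable.
   Thresholds sweep |ES| = 0.8 … 3.0 in bins of 0.1.
2. **Mining.** For every phenotype pair, over strains tested in both
   ("complete cases"), the 2×2 table (n₁₁, n₁₀, n₀₁, n₀₀) yields six
   measures: co-abnormal count, support n₁₁/N, the two directed confidences
   n₁₁/(n₁₁+n₁₀) and n₁₁/(n₁₁+n₀₁), lift n₁₁N/((n₁₁+n₁₀)(n₁₁+n₀₁)),
   rule polarity (−log₁₀ p, exact test contrasting the two confidences),
   and rule significance (two-tailed Fisher exact p of the cross table,
   evaluated when n₁₁ ≥ 2). q-values multiply Benjamini–Hochberg
   adjustment by a sliding-linear-model π₀ estimate.
3. **Selection.** Keep rules with n₁₁ ≥ 2, lift > 2 and q < 0.1; choose
   each phenotype's optimal |ES| threshold (maximising its rule count),
   accumulate rules at the optima, dedupe, and store each pair in its
   higher-confidence direction — from fewer abnormal cases toward more.
4. **Modules.** The PPAP of a query phenotype is its closed one-hop
   neighborhood in the rule graph with all induced edges; conversion to a
   pathway-like configuration unions the longest simple paths between the
   query and each related phenotype. The phenome-wide pathway is the
   deduplicated union over all convertible PPAPs.
5. **Communities.** Ward clustering on Simpson distances
   (1 − |A∩B|/min(|A|,|B|)) between PPAP phenotype sets; Fisher-exact
   enrichment suites over stage/type categories and biological systems.

See the methods vignette (`vignettes/phenorules-methods.Rmd`) for the full
model description, parameter defaults, design decisions and limitations —
including an important caveat on the empirical FDR of the accumulated
atlas.

## Worked example

Simulate a 40-phenotype × 1,500-strain corpus with two planted
co-abnormality modules (cliques of 4, pairwise lift 8), then run selection:

```r
library(phenorules)

cfg <- sim_config(
  n_phenotypes = 40, n_strains = 1500, n_controls_per_parameter = 50,
  planted_pairs = planted_clique_pairs(c(4, 4), lift = 8),
  missing_rate = 0.2, seed = 42)
catalog <- generate_catalog(cfg)
gen     <- generate_measurements(cfg, catalog)

atlas <- select_significant_rules(gen$measurements, annotation = catalog,
                                  grid = threshold_grid(0.8, 3.0, 0.2))
atlas
#> significant_rule_set: 19 directed rules over 18 phenotypes
#>   criteria: n11 >= 2, lift > 2, q < 0.1; grid 0.8..3

head(atlas$rules[, c("lhs", "rhs", "n11", "N", "lift", "q")], 3)
#>                           lhs                         rhs n11   N      lift            q
#> 1   adult_gene:phenotype_0004  adult_trait:phenotype_0003  13 974  9.018519 1.382046e-08
#> 2 embryo_trait:phenotype_0001   adult_gene:phenotype_0004   3 981 10.819853 5.381831e-02
#> 3   adult_gene:phenotype_0004 embryo_trait:phenotype_0002   9 950  7.031250 6.818011e-05
```

The atlas recovers the planted modules: rule 1 links two members of a
planted clique that were co-abnormal in 13 of 974 co-tested strains — a
lift of 9 over independence (support 0.013, so the association is strong
but rare, which is exactly what the exact-test machinery is there to
detect). The rule points from the phenotype with fewer abnormal strains to
the one with more. Downstream:

```r
g  <- build_rule_graph(atlas)
pp <- extract_ppap(g, atlas$phenotypes[1], annotation = catalog)
pp
#> ppap: query 'adult_gene:phenotype_0004', 3 related phenotypes, 6 rules

pw <- convert_to_pathway(pp)         # longest-path configuration, 3 edges
dd <- degree_deviation(g)            # rare/common phenotype classification
cl <- cluster_ppaps(lapply(atlas$phenotypes, extract_ppap, graph = g), k = 2)
```

`run_pipeline(pipeline_config(...))` chains every stage (simulate/ingest →
call → mine → select → PPAP → pathway → cluster → enrich), writes TSV/CSV/
GraphML artifacts and a JSON manifest, and is fully determined by its seed.
A thin command-line wrapper with per-stage subcommands is installed at
`inst/cli/phenorules.R`.

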