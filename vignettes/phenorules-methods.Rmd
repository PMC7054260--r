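---
title: "Mining phenotype-phenotype association rules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining phenotype-phenotype association rules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorules)
```

# The problem

Large knockout-mouse phenotyping screens measure hundreds of quantitative
parameters across thousands of single-gene mutant strains. When two
phenotypes are abnormal in the same strains more often than chance predicts,
that co-abnormality is evidence of a biological relationship — pleiotropy,
a shared pathway, or a causal cascade. phenorules turns a strain-by-phenotype
screen into a weighted, directed atlas of such relationships, then organises
the atlas into per-phenotype modules (PPAPs), pathway-like configurations,
and communities.

The pipeline has five stages, each exposed as ordinary R functions:

1. **Phenotypic calls** — quantitative measurements become a three-valued
   matrix (abnormal `A` / normal `N` / not-tested `NT`) via unbiased
   Hedges' g.
2. **Rule mining** — every phenotype pair is cross-tabulated over complete
   cases and scored with six association measures.
3. **Rule selection** — three criteria plus a per-phenotype optimal
   effect-size threshold yield the directed rule atlas.
4. **Modules and pathways** — per-phenotype ego-modules are converted to
   pathway-like configurations by longest-simple-path accumulation.
5. **Communities and enrichment** — Ward clustering on Simpson distances,
   and Fisher-exact enrichment suites.

# Phenotypic calls

For a parameter measured in $n_m$ mutant and $n_c$ control animals, the
standardized mean difference is $d = (\bar x_m - \bar x_c)/s_p$ with the
pooled SD $s_p$, corrected for small-sample bias by
$J = 1 - 3/(4\,\mathrm{df} - 1)$, $\mathrm{df} = n_m + n_c - 2$, giving
unbiased Hedges' $g = J\,d$. The standard error uses the Hedges–Olkin
large-sample form
$\widehat{\mathrm{se}}(g)^2 = \frac{n_m + n_c}{n_m n_c} + \frac{g^2}{2(n_m+n_c)}$,
with normal-quantile 95% confidence limits — the standard Hedges–Olkin
approximation.

A cell is called **abnormal** at threshold $t$ iff all three hold:

* $|g| \ge t$;
* the effect is significant at the 95% level ($p_g < 0.05$, normal
  approximation);
* the accompanying exact significance test has $p < 0.05$.

The accompanying exact test is configurable: the package defaults to a two-sided Welch t-test (appropriate for continuous
screen parameters with unequal variances) and offers an exact Wilcoxon
rank-sum alternative (`exact_test = "wilcoxon"`). Cells with fewer than two
finite values per group, or zero pooled variance, are not computable and
become `NT`.

Calls are swept over a grid of thresholds, $|ES| \in \{0.8, 0.9, \dots,
3.0\}$ (23 values). Effect sizes are computed once per (parameter, strain)
cell; thresholding is applied per grid value, so the abnormal set at a
larger threshold is always nested inside the abnormal set at a smaller one.
Multiple parameters annotating one ontology phenotype collapse by OR:
abnormal if any parameter is abnormal, normal if tested and never abnormal,
not-tested otherwise — OR is the sensitive choice and matches the "any
evidence of abnormality" reading of a screen.

# Rule measures

For an ordered pair (X, Y), strains not tested in either phenotype are
removed; the remaining complete cases form the 2×2 table
$(n_{11}, n_{10}, n_{01}, n_{00})$ with $N$ their sum. The six measures:

* **co-abnormal count** $n_{11}$;
* **support** $n_{11}/N$;
* **confidence** $n_{11}/(n_{11}+n_{10})$ forward,
  $n_{11}/(n_{11}+n_{01})$ reverse;
* **lift** $n_{11} N / ((n_{11}+n_{10})(n_{11}+n_{01}))$ — 1 is
  independence, direction-symmetric;
* **rule polarity** $-\log_{10} p$ of the two-tailed Fisher exact test on
  $\bigl[\begin{smallmatrix} n_{11} & n_{10} \\ n_{11} & n_{01}
  \end{smallmatrix}\bigr]$, contrasting the two directed confidences — the
  two conditional probabilities share the numerator $n_{11}$, so the rows
  are the forward and reverse success/failure splits; large values mean the
  premise has far fewer abnormal cases than the conclusion;
* **rule significance** — the two-tailed Fisher exact p of the cross table
  itself, evaluated only when $n_{11} \ge 2$.

Two-tailed exact p-values follow the standard convention: the sum of the
probabilities of all tables with the same margins whose probability does not
exceed the observed table's (with the usual $1+10^{-7}$ relative tolerance,
matching `stats::fisher.test`). Because a mining pass evaluates on the order
of $10^5$ tables, the p-value is computed directly from the hypergeometric
density over the table support; the test suite verifies agreement with both
`stats::fisher.test` and an independent `choose()`-arithmetic enumeration
oracle to $10^{-9}$.

# Multiplicity: q-values with a sliding-linear-model pi0

q-values are $\hat\pi_0$ times the Benjamini–Hochberg adjusted p-values.
$\hat\pi_0$ comes from an in-package sliding linear model: the empirical CDF
of the p-values is evaluated at knots $\alpha$ apart (default 0.05), an OLS
line is fitted within a window sliding across the unit interval, and the
estimate is the slope at the left end of the longest stable run of windows
ending at the right edge. Two guards matter in practice:

* **Bounded support.** Conditioning the significance test on
  $n_{11} \ge 2$ bounds its null p-values away from 1 whenever the expected
  co-abnormal count is well below 2 (sparse margins): the distribution then
  looks globally left-shifted and *any* right-tail $\pi_0$ estimator reads
  gated nulls as signal. If no p-value reaches beyond $1 - 2\alpha$, the fit
  has no null support and the estimator falls back to $\pi_0 = 1$ (pure BH).
* **Degenerate windows.** A window whose ECDF moves at a single knot (e.g.
  all p-values exactly 1) carries no slope information and also falls back
  to 1.

During rule selection the q-value family is the *whole sweep*: all evaluated
p-values across the 23 thresholds are adjusted together. Adjusting each
threshold separately lets gate-sparse sweep ends (few evaluated pairs, all
with conditionally small p) locally deflate q and select spurious rules at
exactly the most stringent calls; a single family removes that failure mode
and treats the multiplicity correction as what it is: one correction for
one mining analysis.

# Rule selection

A bidirectional rule is retained when $n_{11} \ge 2$, lift $> 2$ (strict),
and $q < 0.1$. The sweep applies one global threshold at a time; for each
phenotype the **optimal threshold** maximises the number of retained rules
incident to it, with ties broken toward the larger (more stringent)
threshold. Rules incident to each phenotype at its optimum are accumulated,
duplicates collapse to the occurrence with the larger lift (then larger
$n_{11}$), and each unordered pair keeps the direction with the larger
confidence — so rules point from the phenotype with fewer complete-case
abnormal strains toward the one with more. Exact confidence ties break
toward the lexicographically smaller id and are flagged (`direction_tie`).

**A calibration caveat that users should know.** The $q<0.1$ criterion
controls the false discovery rate *within one sweep step*. The accumulation
step unions 23 such families: planted/true rules recur at nearly every
threshold and collapse to one record, while chance rules recur at only a few
adjacent thresholds — and a chance rule between two otherwise rule-less
phenotypes always defines those phenotypes' optima, so it is always
accumulated. In the package's validation simulations (120 phenotypes × 3,000
strains, 50 module-planted pairs, the conditions of the recovery test in the
suite) this asymmetry inflates the empirical false-discovery proportion of
the final atlas to roughly 0.3 — about three times the per-step nominal
level — while recovery of planted pairs is 90–94%. This is a property of the
accumulate-over-optima procedure itself, not of the q-value machinery, and
it would apply equally to any atlas produced this way. Interpret the atlas's
nominal FDR accordingly, or select at a single global threshold when strict
FDR control matters.

# The synthetic corpus

`sim_config()` describes the generator whose defaults emulate the
statistical shape of a large phenotyping corpus:

* `n_phenotypes = 500`, `n_strains = 3000` — corpus dimensions;
* `abnormality_rate = 0.04` — the ~4% marginal abnormality frequency
  observed at a stringent call threshold;
* `effect_size_abnormal = 3` — latently abnormal cells shift by 3 control
  SDs, so calls at $|ES| = 2$ recover them with high sensitivity at typical
  cohort sizes (`n_mutants_per_strain = 7` replicate animals,
  `n_controls_per_parameter = 100`);
* `missing_rate = 0.3` — not-tested masking, missing completely at random.
  Real screens miss cells in structured panels, so their *pairwise*
  complete-case counts stay high even when many cells are untested; under
  MCAR the complete-case fraction is $(1-q)^2$, and $q = 0.3$ reproduces the
  effective co-testing regime (expected chance co-abnormal counts of a few
  per pair at full scale) rather than the raw cell-missingness fraction;
* `stage_type_mix` — four stage/type categories (adult/embryo ×
  trait/gene) with an adult-trait-dominated mix;
* `planted_pairs` — co-abnormality structure with known truth. Pairs couple
  through a shared Bernoulli component ($A_i = C \lor U_i$), which gives the
  joint probability $c + (1-c)u^2$ in closed form and solves exactly for the
  configured pairwise lift (feasible for lift $\le 1/\text{rate}$). Pairs
  may overlap provided they decompose into disjoint *cliques* with one lift
  value each — one shared component per clique gives every within-clique
  pair exactly the configured pairwise lift. Module-structured planting is
  the realistic shape: in real atlases a phenotype participates in many
  relationships at once.

What the generator does **not** emulate: center/zygosity/sex structure,
batch effects, covariate-adjusted calling, categorical parameters (emulate
those by supplying call matrices directly), structured missingness, and
directional (signed) abnormality ontologies. Passing tests therefore
demonstrate correctness of the machinery under a clean MCAR Gaussian
corpus, not robustness to those real-data complications.

# PPAPs, pathways, degree deviation, gene ranking

The **rule graph** has one node per atlas phenotype and one directed edge
per rule. The **PPAP** of a query is its closed one-hop neighborhood with
all induced edges; neighbor–neighbor edges carry the indirectly related
phenotypes and make multi-edge paths possible. (Full reachability closure
was rejected: it would blur module boundaries and contradict the ego-layout
reading of the construct.) Module statistics count phenotypes excluding the
query; biological-system counts use the annotation map.

**Pathway conversion** keeps, for each phenotype reachable from the query,
the longest simple directed path from the query (and symmetrically into the
query from each phenotype that reaches it), then unions the kept paths'
edges. Length ties keep the lexicographically smallest node sequence — an
arbitrary but deterministic rule. Enumeration is capped (`max_paths`,
default $10^5$ per endpoint); exceeding the cap raises a `too-complex`
error rather than silently truncating, so unconvertible modules are
reported instead of approximated. On acyclic inputs conversion
is idempotent, and kept paths equal a brute-force enumeration oracle
(`longest_path_oracle`, verified on random DAGs in the suite). The
phenome-wide pathway is the provenance-tracked union of all convertible
PPAPs' configurations.

**Degree deviation** scores each query by the two-tailed Fisher exact test
of $\bigl[\begin{smallmatrix} \mathrm{in} & \mathrm{out} \\ \mathrm{out} &
\mathrm{in} \end{smallmatrix}\bigr]$, signed $-\log_{10} p$ (negative when
outdegree exceeds indegree), with q-values across queries and classes
rare/common at FDR < 0.05. Of the defensible 2×2 constructions, the
transposed-margins form is used because it is symmetric and needs no
external totals.

**Gene ranking** lists strains abnormal for the query phenotype, scored by
the count (and proportion) of PPAP phenotypes abnormal in that strain.
Eligibility requires abnormality *for the query* (the stricter of the two
possible eligibility rules), so a strain abnormal for many module
members but normal for the query is excluded.

# Communities and enrichment

PPAP similarity uses the **Simpson distance**
$1 - |A \cap B| / \min(|A|, |B|)$ on phenotype node sets, agglomerated by
Ward linkage. "Ward linkage" is ambiguous between the two historical `hclust` variants;
`stats::hclust(method = "ward.D2")` is used because it implements the Ward
criterion on the distances directly. Items are sorted by
query id before clustering so the result is order-invariant. The tree cut
is a fixed `k` (defaults: 7 at phenotype level, 4 at biological-system
level); no automatic `k` selection is attempted. System-level clustering represents each biological system by the
set of PPAPs containing it. Approximately-unbiased bootstrap p-values on
dendrogram edges are out of scope.

Enrichment suites all reduce to `fisher_enrichment()`: stage/type rule
composition (16 ordered category pairs vs the possible-pair composition,
Holm-corrected), between-biological-system pairs (vs possible cross pairs,
q-values at FDR 0.01, counting a multi-system phenotype's pair once per
realized category), measure extremes (quartile cut by default, configurable; one-tailed and
Bonferroni-corrected, evaluated only at fold ≥ 1), and the bootstrap null for the number of distinct
between-system categories realized by a random rule set (uniform draws
without replacement, lower-tail p).

# Numerical and engineering choices

* Pairwise counts for all pairs come from three matrix cross-products on
  the A/tested indicator matrices; mining 500 × 3,000 matrices is
  seconds-fast.
* Exact p-values are computed from `dhyper` over the table support,
  vectorised over tables; identical (to $10^{-9}$) to `fisher.test`.
* All randomness flows from explicit seeds; identical config + seed gives
  byte-identical generator output and pipeline results.
* Problem sizes in the validation suite (e.g. 120 × 3,000 for recovery,
  200 × 500 × 20 seeds for null calibration, 200 random DAGs for the
  pathway oracle) were chosen as the smallest corpora in which the planted
  effects operate in the intended statistical regime (expected co-abnormal
  counts of a few per planted pair).
* Call symbols are `A`/`N`/`NT` rather than 1/0/NA so that missingness can
  never be confused with a numeric zero across file round trips.

# Known limitations

* The accumulated atlas's empirical FDR exceeds the per-step nominal level
  (see the selection caveat above).
* MCAR missingness compounds quadratically in pairs; heavily structured
  missingness in real screens changes complete-case counts in ways the
  generator does not model.
* The Welch default for the exact-test prerequisite is a modelling
  choice; rank-based calling can flip borderline cells.
* Polarity's 2×2 construction and the degree-deviation table each admit
  alternative constructions; the ones implemented are exact-test based,
  symmetric and documented above.
* Pathway conversion on cyclic modules can be exponential; the cap turns
  pathological modules into explicit errors, and such modules are reported,
  not converted.
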