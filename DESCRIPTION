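Package: phenorules
Title: Phenome-Wide Phenotype-Phenotype Association Rule Mining
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Mines directed phenotype-phenotype association rules from
    mutant-strain phenotyping screens. Converts quantitative measurements
    into three-valued abnormal/normal/not-tested calls using unbiased
    Hedges' g with significance prerequisites, computes support,
    confidence, lift, rule polarity and rule significance for every
    phenotype pair on complete cases, selects significant rules with
    per-phenotype optimal effect-size thresholds and FDR control via a
    sliding-linear-model pi0 estimate, builds phenotype ego-modules
    (PPAPs), converts them into pathway-like configurations by
    longest-simple-path accumulation, and detects communities by Ward
    clustering on Simpson distances. Includes a synthetic-data generator
    with planted co-abnormality structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
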