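Package: milkqtl
Title: Candidate-Gene Association Analysis of Milk Fatty-Acid Traits in
    Pedigreed Dairy Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-SNP candidate-gene association studies of milk
    fatty-acid composition in pedigreed dairy cattle populations. Derives
    saturated/unsaturated aggregates and desaturation indices from gas-
    chromatography fatty-acid profiles, builds the pedigree numerator
    relationship matrix (tabular method) with inbreeding, fits a mixed animal
    model (fixed genotype, herd and lactation-stage effects, age-at-calving
    covariate, random polygenic effect) by EM-REML and Henderson's mixed-model
    equations, reports genotype least-squares means with letter groupings, and
    estimates additive, dominance and allele-substitution effects with
    significance. Includes relative-quantification (2^-ddCt) helpers for qPCR
    follow-up experiments and a seed-deterministic simulator of half-sib sire
    family populations with gene-dropped genotypes and pedigree-correlated
    polygenic values for validating every stage against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
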