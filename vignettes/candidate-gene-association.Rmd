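---
title: "Candidate-gene association analysis of milk fatty acids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene association analysis of milk fatty acids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkqtl)
```

## The problem

Milk fat is a composite of saturated and unsaturated fatty acids (FAs) whose
proportions are moderately heritable (published estimates for individual milk
FAs in Holstein cows span roughly 0.07–0.42). A candidate-gene study asks
whether the genotype at a single SNP is associated with FA composition in a
pedigreed cow population, while accounting for the systematic environment
(herd, lactation stage, age at calving) and for the fact that related cows
resemble each other genetically. `milkqtl` implements that full analysis
chain and a matching population simulator, so every stage can be validated
against known truth even when the original study data are not available.

## Trait derivation

Sixteen FAs measured by gas chromatography (each as % of total FA) are the
primary traits. Eight derived traits complete the analysed set of 24:

* `sfa`, `ufa`: sums of the saturated (`:0`) and cis-9 unsaturated members
  present in a profile, and their ratio `sfa_ufa`;
* four desaturation indices, `100 * product / (product + substrate)` for the
  delta-9 desaturase pairs C14:1/C14:0, C16:1/C16:0, C17:1/C17:0 and
  C18:1cis-9/C18:0, and a `total_index` pooling all four pairs.

A missing measured FA propagates to any derived trait that needs it rather
than raising an error, because in practice per-trait record counts differ
(each trait is analysed on its own complete-case subset). A zero denominator
yields a missing value with a warning. The saturated/unsaturated membership
is exposed via `fatty_acid_sets()` and can be overridden in
`aggregate_saturation()`, since published studies do not always state the
membership of their SFA/UFA sums.

## Pedigree and kinship

Pedigrees are validated (acyclic, unique ids, phantom founder records for
parents without rows; unknown parents coded `0`, empty, `.` or `NA`) and
topologically sorted. `truncate_to_generations()` restricts the ancestry to
`g` parent steps from the focal animals — the conventional "three-generation
pedigree" corresponds to `g = 3` — recoding parents beyond the horizon as
unknown.

The numerator relationship matrix A is built by the tabular method:
`A[i,i] = 1 + 0.5 * A[sire,dam]` and `A[i,j] = 0.5 * (A[j,sire] + A[j,dam])`.
Inbreeding is accumulated on the diagonal by default; a flag disables it for
comparison with software that assumes non-inbred pedigrees. At the scale of
interest (a few thousand animals) dense storage and Cholesky inversion are
unproblematic, so the sparse inverse rules (Henderson/Meuwissen–Luo) are a
deliberate non-goal. The tabular implementation is tested against an exact,
independent oracle: exhaustive enumeration of every meiosis outcome on toy
pedigrees, which reproduces Wright's relationship coefficients without
sharing any code with the recursion.

## The animal model

For one trait the model is

y = mu + genotype + farm + stage + b * age + u + e,

with genotype (3 classes), farm and lactation stage as fixed factors, age at
calving as a continuous covariate (a switch fits it as a class factor
instead, since field studies describe it both ways), a random polygenic
animal effect `u ~ (0, A * sigma2_a)` over the full pedigree, and residual
`e ~ (0, I * sigma2_e)`. Records with any missing field are dropped and
counted; the design matrix uses treatment coding with single-level factors
dropped, and rank deficiency is a hard error that names the aliased columns.

### Variance components

The estimation method in the original SAS-based analyses of this design is
typically unstated; we chose EM-REML for its robustness (guaranteed
non-negative estimates, monotone REML log-likelihood). Implementation: the
model is reduced to the phenotyped animals, `H = Z A Z'` is eigen-decomposed
once, and the EM recurrences for Henderson's equations run in the rotated
basis where the covariance is diagonal — algebraically the same REML
objective, but each iteration costs O(n p^2) instead of a dense solve. Two
practical safeguards address EM's known slow tail behaviour without
sacrificing its guarantees:

* a monotone step-lengthening acceleration (log-scale extrapolation of the
  EM step, accepted only when the REML log-likelihood does not decrease);
* a final 1-D profiled-likelihood polish of interior solutions, again
  accepted only if the objective does not decrease, because the EM
  fixed-point residual can undersell the remaining distance to the
  maximiser.

Defaults: relative tolerance `1e-6`, at most 500 iterations. A polygenic
variance below `1e-8` of the total is declared a boundary (zero
heritability) solution, and downstream solving falls back to ordinary least
squares. `method = "fixed_h2"` instead profiles the residual variance at a
user-fixed heritability, which is useful for fast simulation studies.

### Solutions, LSMs and tests

`solve_mme()` implements the literal Henderson mixed-model equations
(dense), and the test suite verifies on random instances that its
fixed-effect solutions coincide with dense-V GLS and with the eigen-space
path used by `fit_animal_model()` — a genuine dual-route check.

Genotype least-squares means are the classical estimable functions:
intercept + genotype effect + the unweighted mean over farm and stage
levels, covariate at its mean. Standard errors are `sqrt(k' vcov(beta) k)`;
pairwise genotype differences use t-tests on `n - rank(X)` degrees of
freedom, summarised as compact letter displays (lowercase at 0.05, uppercase
at 0.01, ties in the letter sweep broken by ascending LSM). The overall
genotype test is a 2-df Wald F with the same denominator df. No
multiple-testing correction is applied across the 24 traits (matching field
practice of reporting raw per-trait p-values); Bonferroni adjustment is a
one-liner on the reported p-values if desired.

## Gene effects

With genotype LSMs AA, AB, BB (allele A = first allele of the SNP name) and
allele frequencies p, q:

* additive: a = (AA − BB) / 2
* dominance: d = AB − (AA + BB) / 2
* allele substitution: alpha = a + d (q − p)

These are computed as estimable contrasts over the LSM vector with variance
`k' vcov(LSM) k`, giving t-tests and significance stars. Swapping the allele
labels negates a and alpha and leaves d unchanged, which is tested as an
invariant. Reported tables are rounded half-away-from-zero to 4 decimals
(`round_half_away()`), the convention used in published tables — note that
base R's `round()` is round-half-to-even and reproduces some printed values
incorrectly (e.g. an allele frequency of 0.33125 prints as 0.3313, not
0.3312).

## qPCR relative expression

`relative_expression()` implements 2^-ddCt with replicates averaged first;
`multi_reference_expression()` normalises against several reference genes
and combines per-reference fold changes as their geometric mean. The
amplification efficiency is fixed at 2 by default (plain 2^-ddCt), with the
efficiency-corrected variant available through the `efficiency` argument.
Replicate dispersion is summarised as the SD of per-replicate ddCt when
replicate counts align; no error model beyond that is imposed, since
published knockdown experiments rarely state one.

## The simulator

`simulate_population()` generates the study conditions end to end, and its
defaults are fixed at the population the pipeline targets: 44 paternal
half-sib sire families of 24 daughters (1056 cows) on 23 farms with 4
lactation stages; three-generation pedigrees (founder grandsires/granddams
above the sires, a founder maternal-grandsire pool above the dams; dams are
otherwise unrelated, since field studies rarely report dam-side structure,
with an optional dam-reuse rate); founder allele frequency 0.6688;
heritability 0.30 for every trait (inside the published 0.07–0.42 range);
genotype effects at the published association scale for the short/medium
chain FAs and zero elsewhere; farm and stage effect SDs of 0.25 and 0.15
phenotypic SDs; an age-at-calving covariate uniform on 22–40 months with a
regression of 0.01 phenotypic SDs per month; and 8% missing phenotypes per
trait, mirroring the varying per-genotype record counts of real data.
Per-FA means and variances are field-typical values (coefficient of
variation 0.22) fixed once in `default_trait_params()`.

Genotypes are gene-dropped: founders draw alleles at the configured
frequency and each offspring inherits one uniformly chosen allele per
parent, so allele frequency is preserved in expectation. Polygenic values
use the exact Mendelian-sampling recursion
`u_i = (u_s + u_d)/2 + m_i`, with `Var(m_i)` adjusted for unknown parents
and parental inbreeding, which reproduces `Var(u) = A * sigma2_a` without
factorising A; the test suite checks the empirical covariance of replicate
draws against `A * sigma2_a` entrywise, including on an inbred pedigree.
All generators are seed-deterministic (identical seed and configuration
give identical outputs, byte for byte once written).

What the simulator does **not** emulate: linkage disequilibrium with other
loci, selection, maternal or permanent-environment effects, heterogeneous
residual variances across farms, and non-Gaussian trait distributions.
Passing tests therefore demonstrate correctness of the estimation machinery
under the stated model, not robustness to violations of it.

## Verification problem sizes

The package's statistical checks run at sizes chosen to balance power
against convenience: oracle equivalences (MME vs GLS, tabular A vs
enumeration) use instances of up to 50 records or 10 animals where the
oracles are exact; heritability/effect recovery uses 10 replicate
populations of 2000 cows in 40 sire families at h2 = 0.30; the null
calibration of the genotype test uses 2000 replicate populations of 500
cows (20 sire families, 10 farms, no missingness) drawn over a fixed
pedigree with genotypes and phenotypes redrawn each replicate. The
simulator's defaults themselves are never adjusted to make a check pass.

## Known limitations

* Single-trait analyses only; no genetic correlations between FAs, no
  repeated records, no genomic (marker-based) relationships.
* The letter display uses the sorted-means sweep, which is exact for the
  three-class genotype factor it serves but is not a general graph-colouring
  letter algorithm.
* Denominator degrees of freedom for LSM and contrast tests are the
  residual `n - rank(X)`; no Kenward–Roger/Satterthwaite adjustment, so
  p-values are mildly liberal in very small samples.
* The pipeline analyses one SNP at a time; VCF/PLINK ingestion is out of
  scope.
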