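---
title: "Haplotype-based discovery of trait-associated variation in landrace-derived DH panels"
author: "landhap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{landhap methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landhap)
```

## The problem

Maize landraces are open-pollinated populations that hold allelic variation
lost from elite breeding pools through bottlenecks and decades of selection.
For quantitative traits such as early plant development or cold tolerance,
that variation is hard to access: species-wide diversity panels suffer from
population structure and locally common alleles stay invisible. An
alternative strategy samples a few preselected landraces comprehensively —
hundreds of doubled-haploid (DH) lines per landrace — so that within-population
variation can be mapped at high resolution, and then asks which of the
discovered haplotypes are absent or rare in the breeding pool one wants to
improve.

`landhap` implements this strategy end to end: window-based haplotype
construction, diversity and linkage-disequilibrium (LD) statistics,
kinship-corrected mixed-model association scans per environment and across
environments, multi-environment backward elimination with effect-stability
classification, bivariate models for effects on secondary traits, and the
genotypic/phenotypic comparison of landrace and breeding panels. A seeded
synthetic-data generator emulates the study design and carries
machine-readable truth, so every stage can be validated by recovery tests.

## Data model

All lines are fully homozygous (DH or inbred), so genotypes take only two
states per biallelic SNP, coded 0/2. A `GenotypePanel` couples the
lines x markers matrix with a marker map (chromosome, bp, optionally cM)
and a population label per line. Haplotypes are the allele strings within
nonoverlapping windows of ten consecutive SNPs; each window haplotype
becomes a presence/absence marker with scores 0/2, so per line and window
exactly one haplotype scores 2 (`HaplotypeSet` enforces this invariant).
Haplotype identifiers are assigned by (window, lexicographic allele string)
and are therefore stable across panels and runs — the basis for comparing
landrace and breeding catalogs. Trailing windows with fewer than ten SNPs
are kept but flagged `partial` and excluded by default from cross-panel
frequency comparisons, because sub-length windows are not comparable.

Phenotypes are best linear unbiased estimates (BLUEs) per line, per
environment and across environments (token `ACROSS`), supplied as a long
table. Computing BLUEs from raw field designs is outside the package's
scope; they are inputs.

## Association model

The single-marker scan fits, for each haplotype marker x,

y = W a + x b + u + e,  u ~ N(0, K sg2),  e ~ N(0, I se2),

with W an intercept plus population indicators and K the Astle–Balding
genomic relationship matrix from the SNPs (`computeKinship`; denominator
2p(1-p), so the DH diagonal is near 2; a 4p(1-p) variant is available).
The REML engine (`remlFit`) profiles the variance ratio through a single
eigendecomposition of K, reused for all markers of a scan: a 61-point grid
over log-ratio in [-6, 6] log10-units followed by Brent refinement at
tolerance 1e-8, with explicit boundary comparison. Per scan, variance
components are estimated once under the null model and reused for every
marker; each marker then gets a generalized-least-squares effect, standard
error, and a one-degree chi-square likelihood-ratio p computed from the
weighted residual sum-of-squares difference at fixed variance components.
An exact per-marker refit is available behind `refit_per_marker = TRUE`.
Markers are prefiltered: haplotypes carried fewer than three times are
excluded and duplicate segregation patterns at r^2 = 1 (including exact
complements) are collapsed to the first by genomic position.

Significance is controlled per scan at a 15% Benjamini–Hochberg false
discovery rate. Significant haplotypes on the same chromosome, closer than
1 Mb AND in LD at r^2 >= 0.8, mark the same genomic region (single-linkage
clumping); each region is represented by its focus haplotype — the minimum-p
member, with exact ties broken by larger |effect|, then smaller bp position,
so region assembly is deterministic and order-invariant.

## Multi-environment model and stability classification

Candidate focus haplotypes from all scans of a trait (each environment plus
across-environment) are deduplicated by the same same-region rule, keeping
the smaller discovery p, and enter a joint multi-environment model:

y_ijk = mu + env_i + landrace_j + sum_q x_kq b_q^i + u_k + e_ijk,

with environment-specific residual variances and per-haplotype,
per-environment fixed effects b_q^i that combine main and
haplotype-by-environment interaction. Backward elimination tests every
haplotype with a joint Wald test of its per-environment effects conditional
on all others ("as the last one entering the model"); the least significant
haplotype is removed while its P >= 0.01, and variance components are
re-estimated by REML after every step.

The fit (`remlFitHetero`) exploits the block structure of the covariance:
with an iid line effect the covariance is block-diagonal per line, and each
block is diagonal-plus-rank-one, so Sherman–Morrison reduces every
likelihood evaluation to vectorized O(n) algebra; optimization is L-BFGS-B
on log-variances. When the line effect is modelled with kinship (balanced
data), an eigen-rotation of the line space restores the same block
structure with per-line multipliers.

Two modelling choices deserve emphasis:

- **Random line effect.** The covariance of u_k in the multi-environment
  model is genuinely open; `backwardEliminate` defaults to iid. The
  pipeline (`runPipeline`), however, passes the kinship matrix by default
  (`kinship_random = TRUE`). The reason is visible in the synthetic data:
  the generator plants a polygenic background with covariance proportional
  to kinship, and with an iid line effect the haplotype fixed effects are
  partially confounded with founder relatedness — on unlucky draws a
  planted effect can be attenuated to invisibility. The scan stage already
  corrects for kinship; using the same correction in the elimination stage
  keeps the two stages consistent and restores reliable recovery.
- **Wald degrees of freedom.** The joint test uses df equal to the number
  of environments in which the haplotype's effect is estimable.

Per environment, a haplotype is significant when its 95% confidence
interval (estimate +/- 1.96 SE) excludes zero. Haplotypes whose significant
effects keep one sign are favorable or unfavorable according to the
trait's direction convention (positive favorable for early vigor/height
traits, negative favorable for lodging and tillering); sign changes across
significant environments mean interacting; traits without a breeding-goal
convention are reported with counts only (`direction = NA`). The proportion
of genetic variance explained is the relative reduction in REML line
variance between models excluding and including the haplotype terms,
floored at zero. Landrace-nested effects (haplotype x environment x
landrace) quantify background dependence for haplotypes segregating in at
least two landraces with at least three carriers each.

## Bivariate model and window contrast

Effects on secondary traits are tested in a two-trait mixed model with
genetic covariance G (x) K and residual covariance E (x) I — the residual
couples the two traits within each (line, environment) observation and is
independent across observations; environments are fixed per trait. This is
an explicit interpretation of the model's residual term, documented here
because the source formulation indexes observations by environment while
writing a single residual covariance. The fit rotates the line space by the
eigenvectors of K and the within-line environment space by an orthonormal
basis whose first vector is the environment mean, which splits each
per-line block into 2x2 trait blocks; REML maximization is over Cholesky
factors of G and E (guaranteeing PSD), Nelder-Mead with two restarts.
Significance on both traits requires both 95% CIs to exclude zero; per-trait
variance explained is the relative reduction of that trait's diagonal of G.
Balanced line x environment x trait data are required.

The window contrast model replaces a window's 0/2 focus-haplotype score
with a categorical window-haplotype factor (focus as reference, alternatives
with fewer than three carriers pooled into a `rare` level) on top of the
retained background haplotypes Q'. Each alternative's per-environment
coefficient is its effect relative to the focus haplotype. Because the null
model for the window's variance-explained is ambiguous, both variants are
reported: reduction from the model with no haplotype terms (default) and
from the Q'-only model (`var_explained_window_only`).

## Panel comparison

Catalog overlap (shared/private haplotypes, per-landrace occurrence),
enrichment of favorable/unfavorable haplotype frequencies in the breeding
panel against 500 randomly drawn haplotypes with landrace count >= 3
(two-sided Mann–Whitney; exact enumeration when both groups have at most
20 values and ties are absent, normal approximation with tie correction
otherwise), a strict upper-quartile "common" flag (type-7 linear
interpolation quartile), independence pruning (greedy by ascending p;
pruned only when within 1 Mb AND r^2 >= 0.8 of a kept haplotype), and
two-sided permutation tests for group mean differences (exact enumeration
whenever the number of distinct assignments does not exceed the requested
permutation count, otherwise seeded random permutations with the add-one
estimator). Recombination-integrity diagnostics report per-window genetic
length, Hudson–Kaplan nR, and haplotype similarity 1 - H_hap.

## Diversity and LD statistics

Gene diversity H = 1 - sum p_i^2 and Botstein's PIC =
1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2 are computed on SNP and haplotype
frequencies. nR is the Hudson–Kaplan lower bound: four-gamete tests on all
SNP pairs in a window, then the maximal set of mutually non-overlapping
incompatibility intervals (greedy by right endpoint, which attains the
bound); the test suite checks it against an exhaustive dynamic-programming
oracle. Modified Rogers' distance reduces, for homozygous lines, to the
square root of the proportion of differing markers; principal coordinates
come from classical double-centering, with negative eigenvalues dropped
from the variance denominator (no Lingoes/Cailliez correction). Pairwise
r^2 is the squared Pearson correlation of 0/2 genotype columns within 1 Mb
— identical to the gametic D^2/(p(1-p)q(1-q)) for homozygous lines, which
is why no phasing step exists. LD decay fits the Hill–Weir
drift-recombination expectation of r^2 with its finite-sample term by least
squares over the log recombination scale; the decay distance is where the
fitted curve first drops below r^2 = 0.2, evaluated on a 1-bp grid, flagged
when the curve never crosses the threshold within the data range.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. It emulates:

- **Ancestry.** Six deep base haplotypes drawn SNP-wise at ancestral
  frequencies in [0.1, 0.5]; a shared pool of 100 haplotypes built as
  Markov segmental mosaics of the bases (mean segment 50 SNPs). The mosaic
  design is deliberate: it bounds per-window haplotype diversity near the
  base count while decorrelating distant windows, so carrying a particular
  window haplotype does not make a line a genome-wide relative of other
  carriers. Landraces draw 32 founders each from the pool and add
  landrace-private mutations (rate 0.005 per founder allele); DH lines are
  single doubled gametes of one meiosis between two random founders, with
  crossovers Poisson(cM/100) placed uniformly on the cM map, no
  interference. Breeding lines are mosaics of a founder set that overlaps
  the landrace pools (60%) plus private founders, so part of the landrace
  catalog is absent from the breeding panel and frequencies correlate
  positively between panels.
- **Trait architecture.** Planted window-haplotype effects on the
  0/2-coded scale (a carrier differs from a non-carrier by twice the
  effect), with per-environment effect vectors whose sign structure matches
  their declared pattern (stable+, stable-, interacting, null); a polygenic
  line value drawn with covariance proportional to the SNP kinship matrix;
  environment and landrace means; environment-specific residual noise.
  Across-environment means serve as ACROSS BLUE stand-ins (the lattice
  design stage that produces real BLUEs is not simulated).
- **Defaults.** 3 landraces x 150 DH lines + 65 breeding lines, 2
  chromosomes x 500 SNPs on 1.5e8 bp / 160 cM, 6 environments, polygenic
  variance 1 (marginal ~2 with the kinship diagonal near 2) and residual
  variance 1 per environment. These defaults define the conditions under
  which the package's recovery tests run.

What the generator does **not** emulate: genotyping error and missing data
(inputs are assumed imputed), selection and adaptation gradients, realistic
site-frequency spectra, crossover interference, and the empirical marker
density of a 600k array (a desk-scale genome compresses the cM-per-SNP
scale, so simulated windows are genetically much longer than 0.026 cM and
within-window recombination is more common than in the real data).
Passing recovery tests therefore demonstrates the correctness of the
machinery under a plausible generative model, not the field performance of
the study design.

## Numerical choices

- Variance-ratio profile: grid + Brent, tolerance 1e-8; heteroscedastic
  REML: L-BFGS-B on log-variances, bounds 1e-6 to 1e4 times var(y),
  maximum 200 iterations, singular candidate steps rejected with a finite
  penalty. Boundary hits are flagged, not silently accepted.
- LRT statistics are clipped at zero (numerical noise produces a warning).
- Focus-haplotype ties and duplicate-marker collapse are resolved by fixed
  deterministic rules (position, then identifier), so identical inputs
  reproduce identical outputs byte for byte.
- All randomness (simulation, random haplotype draws, permutations) is
  seeded explicitly.

## Problem sizes used by the tests

The test suite validates the engine with, among others: dense-algebra
equivalence on 20-line instances (tolerance 1e-8); a 200-point
variance-ratio grid at n = 30; LRT calibration over 2000 null simulations
at n = 300 lines; CI coverage over 1000 heteroscedastic refits at
n = 100 x 4 environments; planted-QTL recovery over 25 seeds at
n = 600 DH lines x 6 environments; 500 random windows against the
exhaustive nR oracle; and 1000 random p-vectors against a brute-force
step-up oracle. These sizes are the package's own validation choices,
selected to make sampling error small relative to the tested tolerances.

## A worked example

```{r example, eval = FALSE}
b <- 0.45 * sqrt(3)
cfg <- simConfig(qtl = list(
  list(window = 8,  effects = rep(b, 6),  pattern = "stable+"),
  list(window = 30, effects = -rep(b, 6), pattern = "stable-")),
  seed = 1)
st <- simulateStudy(cfg)
res <- runPipeline(st$panel, st$phenotypes, "trait1", seed = 1)
res
res$classification
```

## Known limitations

- The heteroscedastic engine requires at least two observations per
  environment and, with a kinship random effect, balanced line x
  environment data; unbalanced kinship fits are not implemented.
- The bivariate model handles exactly two traits; no factor-analytic or
  >2-trait covariance structures.
- Fine-mapping by sliding-window re-scan is an explicit interpretation of
  an in-silico procedure whose details are not standardized; results
  should be read as localization evidence, not causal inference.
- FDR control is per scan (trait x environment); pooling across scans is a
  documented alternative the user can apply to the returned p-values.
- No imputation, no strand reconciliation, no array-level processing:
  inputs must be clean homozygous 0/2 calls.
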