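# landhap

Haplotype-based discovery of trait-associated variation in landrace-derived
doubled-haploid (DH) panels.

Landraces — open-pollinated, locally adapted crop populations — hold
quantitative-trait variation that elite breeding pools have lost. `landhap`
implements a genome-based strategy for finding it: map haplotype–trait
associations at high resolution within a few comprehensively sampled
landrace-derived DH libraries, characterize the stability of the discovered
effects across environments and genetic backgrounds, and ask which of the
favorable haplotypes are rare or absent in the breeding panel one wants to
improve. It is aimed at plant quantitative geneticists working with fully
homozygous material (DH or inbred lines) genotyped at dense biallelic SNPs.

## What it computes

Haplotypes are allele strings in nonoverlapping ten-SNP windows, coded as
presence/absence markers with scores 0/2. The association scan fits, per
haplotype marker x,

    y = W a + x b + u + e,    u ~ N(0, K sg^2),   e ~ N(0, I se^2)

with covariates W (intercept + landrace indicators) and the Astle–Balding
genomic relationship matrix K, via a spectral-path REML engine (one
eigendecomposition per scan, null variance components reused across
markers, likelihood-ratio p-values, 15% Benjamini–Hochberg FDR per scan).
Significant haplotypes within 1 Mb and r^2 >= 0.8 are clumped into regions,
each represented by its most significant (focus) haplotype. Candidates from
all scans of a trait enter a multi-environment model

    y_ijk = mu + env_i + landrace_j + sum_q x_kq b_q^i + u_k + e_ijk

with environment-specific residual variances, and are backward-eliminated
by joint Wald tests at P >= 0.01. Retained haplotypes are classified
favorable / unfavorable / interacting from the signs of their significant
per-environment effects (95% CI = estimate ± 1.96 SE) under the trait's
direction convention, with the proportion of genetic variance explained
taken as the relative reduction in REML line variance. Further stages:
landrace-nested effect stability, a bivariate model (G ⊗ K genetic,
E ⊗ I residual covariance) for effects on secondary traits, a window
contrast of alternative haplotypes against the focus haplotype, diversity
(PIC, H, Hudson–Kaplan nR) and LD-decay (Hill–Weir) statistics, and the
landrace-versus-breeding comparison: catalog overlap, frequency enrichment
of favorable/unfavorable haplotypes against 500 random haplotypes
(Mann–Whitney), upper-quartile "common" flags, and permutation mean tests.

A seeded synthetic-data generator (`simConfig`, `simulateStudy`) emulates
the study design — DH libraries from a shared ancestral pool with
landrace-private variation, a partially overlapping breeding panel, planted
stable/interacting window-haplotype effects, a kinship-structured polygenic
background, environment-specific noise — and returns machine-readable
truth for recovery testing.

## Worked example

```r
library(landhap)
b <- 0.45 * sqrt(3)   # planted effect: ~0.45 phenotypic SD, coded scale
cfg <- simConfig(qtl = list(
  list(window = 10, effects = rep(b, 6),              pattern = "stable+"),
  list(window = 40, effects = -rep(b, 6),             pattern = "stable-"),
  list(window = 70, effects = b * c(1, 1, -1, -1, 1, -1),
                                                      pattern = "interacting")),
  seed = 5)
st  <- simulateStudy(cfg)
res <- runPipeline(st$panel, st$phenotypes, "trait1", random_n = 300, seed = 5)
res
```

```
landhap pipeline result — trait1
  scans: 7 | significant associations: 21
  candidates: 5 | retained after elimination: 3

  favorable interacting unfavorable
          1           1           1
  genetic variance explained: 42.9 %
  landrace haplotypes absent from breeding panel: 49.4 %
```

The three retained haplotypes are exactly the three planted QTLs:
`res$classification` labels the stable positive effect favorable, the
stable negative effect unfavorable, and the sign-switching effect
interacting; `res$enrichment` holds the breeding-panel frequency
comparison and `res$regions` the per-scan region tables. Genotypes, maps
and phenotypes can be read from VCF/TSV with `readGenotypes`,
`readMarkerMap`, `readPhenotypes`, and all result tables exported with
`exportResults` (TSV + JSON manifest).

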