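Package: landhap
Title: Haplotype-Based Discovery of Trait-Associated Variation in
    Landrace-Derived Doubled-Haploid Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Window-based haplotype construction, diversity and linkage
    disequilibrium statistics, kinship-corrected mixed-model association
    scans, multi-environment backward elimination with effect-stability
    classification, bivariate cross-trait models, and genotypic and
    phenotypic comparison of landrace-derived doubled-haploid libraries
    against elite breeding panels. Includes a seeded synthetic-data
    generator emulating doubled-haploid libraries derived from landraces,
    with planted haplotype effects for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
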