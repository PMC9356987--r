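Package: vhlgp
Title: Genotype-Phenotype Correlation Analysis for Germline VHL Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for large-scale genotype-phenotype correlation analysis of
    germline variants in the VHL tumour-suppressor gene. Provides HGVS-lite
    variant classification against NM_000551.3, Human Phenotype Ontology
    term grouping into the canonical VHL manifestations, cohort assembly at
    patient, family and unique-variant resolution with literature-curation
    filtering rules, phenotype co-occurrence ratios, per-codon missense
    hotspot testing (exact binomial and BLOSUM90-weighted), truncating
    versus non-truncating and protein-domain contingency analyses,
    age-of-onset penetrance with pairwise Kolmogorov-Smirnov testing, and
    Jaccard-affinity spectral clustering with eigengap model selection.
    Includes a synthetic cohort simulator emulating the curated datasheet
    schema with planted hotspots, genotype-dependent phenotype models and
    phenotype-specific onset distributions, so every analysis stage can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    Matrix,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
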