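Package: evaluesnp
Title: Simultaneous SNP Selection in Family GWAS via Quantile E-Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint selection of important single nucleotide polymorphisms
    (SNPs) from multi-SNP linear mixed (ACE) models fitted to nuclear-pedigree
    data. Implements maximum-likelihood fitting of the three-variance-component
    ACE model with block-diagonal kinship covariance, a fast generalized
    bootstrap that reweights per-family estimating equations without refitting
    variance components, quantile e-value model selection with tail-quantile
    thresholding, holdout tuning of the bootstrap noise scale, a synthetic
    family-GWAS simulator with block-correlated genotypes, and single-SNP
    mixed-model and mBIC2 baselines with a benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
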