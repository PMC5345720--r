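Package: hatpress
Title: Hat-Matrix PRESS and Predictability for Mixed-Model Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the predicted residual error sum of squares (PRESS) and
    predictability of genomic best linear unbiased prediction (GBLUP) without
    refitting the mixed model for every cross-validation fold. Estimated
    residuals from a single whole-sample restricted maximum likelihood (REML)
    fit are corrected by leverage values of the random-effect hat matrix,
    obtained from one eigendecomposition of the marker-inferred kinship
    matrix. Also provides the exact K-fold cross-validation engine with
    per-fold REML re-estimation, generalized cross-validation (GCV),
    variance-ratio tuning for maximum predictability, kinship construction
    from biallelic markers or VCF, ANOVA heritability from replicated trials,
    and a seeded simulator of polygenic traits for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
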