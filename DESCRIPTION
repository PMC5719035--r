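Package: gpcurve
Title: Nonlinear Genotype-Phenotype Maps and Phenotypic Robustness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for linking the nonlinearity of a genotype-phenotype
    (G-P) curve to phenotypic robustness across an allelic series. Fits a
    saturating von Bertalanffy curve relating gene dosage (relative
    expression) to a multivariate shape score, and propagates expression
    variance through the fitted curve under truncated-normal developmental
    values to predict per-genotype phenotypic variance. Includes 3D
    landmark-based geometric morphometrics (generalized Procrustes
    analysis, covariate standardization, batch-offset removal, shape
    regression and regression scores, Procrustes variance / morphological
    disparity, permutation tests, variance power analysis), qPCR
    delta-delta-Ct quantification, transcriptome resampling statistics
    (fold-change profiles, nearest-neighbor bootstrap, within-genotype
    concordance, gene-set correlation tests with genome-wide resampling),
    SNP-based additive genetic variance summaries, and a synthetic
    allelic-series generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
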