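Package: perfusir
Title: FTIR Fingerprinting of Kidney Perfusion Fluids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mid-infrared (FTIR) absorbance spectra of
    kidney static cold-storage perfusion fluids, aimed at discriminating
    donation-after-circulatory-death (DCD) from donation-after-brain-death
    (DBD) donors. Provides spectral quality control (Amide I signal-to-noise,
    MAD-based spike detection, cosine shape coherence, baseline area
    fraction), rubber-band (convex hull) baseline correction, Savitzky-Golay
    derivatives, vector normalization, Fast Correlation-Based Filter feature
    selection via symmetrical uncertainty, donor-level leave-one-out
    cross-validation of SVM and Gaussian naive Bayes classifiers with exact
    binomial confidence intervals, exact small-sample statistics
    (enumeration Mann-Whitney, Fisher exact, chi-square, rank-biserial r),
    cosine-distance multidimensional scaling, Ward hierarchical clustering,
    generalized two-dimensional correlation spectroscopy, and a synthetic
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
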