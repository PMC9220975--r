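Package: scgalign
Title: DTW-Based Quasi-Synchronous Alignment for Seismocardiogram Fiducial Points
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects fiducial points (mitral and aortic valve opening and
    closure) in seismocardiogram (SCG) beats by projecting
    echocardiogram-annotated cardiac events through a matched-RR reference
    ECG/SCG beat with dynamic time warping (DTW) under a hybrid local cost
    (value, slope, concavity and index-shift terms). Provides the
    conventional shift-and-rescale alignment as a baseline with detection
    error analysis, cardiac time intervals (PEP, LVET, IVCT, IVRT) and the
    derived diagnostic indexes (PEP/LVET ratio, Tei index), per-subject
    aggregation, and cohort-level validation: univariate linear models of
    LVEF against the indexes and logistic-GLM ROC classification of HFrEF.
    Ships a 56-subject cohort table and a synthetic ECG/SCG generator with
    ground-truth fiducials, diastole-confined beat-length variability,
    monotone time warps and noise, so the whole pipeline is testable
    without access to recorded signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
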