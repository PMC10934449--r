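Package: pdvoice
Title: Cepstral Speech Biomarkers and Speaker Diarization for Parkinson's
    Disease Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discriminating Parkinson's disease
    from healthy-control voices using cepstral features. Implements MFCC and
    gammatone (GTCC) cepstral front-ends from scratch, clustering-based
    speaker diarization of two-party phone conversations, class-balanced
    table construction, nested cross-validated classification with three
    model families (cubic-kernel SVM, 1-nearest-neighbour, wide neural
    network), and per-coefficient two-sample inference. Ships a source-filter
    voice synthesizer with controllable jitter, shimmer, harmonics-to-noise
    ratio and pitch variability, so the whole pipeline is exercised on a
    synthetic hypokinetic-dysarthria cohort with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    class,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
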