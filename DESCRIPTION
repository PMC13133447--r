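Package: speechTRF
Title: Temporal Response Functions and Lexical Surprisal for Continuous-Speech EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of neural tracking of continuous speech:
    n-gram word surprisal regressors, speech-envelope extraction, EEG
    preprocessing, Tikhonov-regularized temporal response function (TRF)
    estimation with cross-validated regularization, model comparison for
    the added value of lexical surprisal, spatiotemporal cluster-based
    permutation statistics, TRF component (N1/P2/N400) extraction, and a
    synthetic-EEG generator with known ground-truth kernels for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
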