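Package: cohera
Title: Global Coherence of Connected Speech and Coherence-Modulated fMRI
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores the global and local coherence of connected-speech
    transcripts with a moving-window latent semantic analysis (LSA)
    approach, summarises coherence and other speech characteristics
    (type:token ratio, closed-class proportion, lexical norms of nouns)
    in 5-second blocks, decomposes the speech measures into
    promax-rotated latent factors, and carries the block-level measures
    forward into a first-level fMRI general linear model as winsorized,
    mean-centred parametric modulators convolved with the canonical
    haemodynamic response function.  Includes region-of-interest
    extraction from probabilistic atlases, quintile effect estimation,
    second-level one-sample tests with covariates, repeated-measures
    2x2 ANCOVA on ROI effects, Monte-Carlo cluster-extent thresholds for
    smoothed null fields, and seeded synthetic-data generators (topic
    corpora, drifting responses, lexical norms, BOLD time series) with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
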