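Package: eegmvpa
Title: Cross-Participant EEG Decoding and Representational Similarity
    Analysis with a Synthetic Cohort Generator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-resolved multivariate pattern analysis of multi-participant
    EEG. Implements leave-one-participant-out linear discriminant decoding of
    stimulus attributes (identity, sex, facial expression and expression
    pairs), bidirectional cross-classification, region-of-interest and
    spatio-temporal searchlight variants, time-resolved representational
    dissimilarity matrices from cross-participant pairwise decoding with
    partial Spearman model correlations, and group-level inference by
    sign-flip cluster permutation tests and interval-null Bayes factor time
    courses. A synthetic-EEG cohort generator with planted, participant-shared
    spatiotemporal effects provides a parameter-recovery test bed for every
    stage, together with a two-alternative forced-choice session scheduler and
    behavioural summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
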