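Package: dyadsync
Title: Turn-Taking, Prosodic Synchrony and Dyad-Aware Classification for
    Dyadic Conversations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of two-party conversations from speaking-
    instance annotations (Praat TextGrid or RTTM) and frame-level prosody
    tracks. Segments conversations into turns, computes individual speech
    features (articulation rate, pauses, pitch and intensity variance) and
    dyadic interactional features (turn counts, turn-taking gaps, silence-to-
    turn ratio), measures interpersonal coordination with windowed cross-
    lagged correlations and turn-based adaptation, contrasts coordination
    against segment-shuffled surrogate (pseudosynchrony) nulls with paired
    Jeffreys-Zellner-Siow Bayes factors, grades evidence on the logarithmic
    Jeffreys scheme, and classifies individuals into mixed versus non-autistic
    dyads with a dyad-aware nested stratified cross-validated linear support
    vector machine including a label-permutation significance test. A
    synthetic-conversation generator with configurable planted effects makes
    every stage testable without audio recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    readr,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    jsonlite
Config/testthat/edition: 3
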