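Package: temsf
Title: Temporal Expectation and Multisensory Facilitation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-alternative forced-choice (2AFC)
    psychophysics experiments in which temporal expectation (block-wise
    target-position probability) and multisensory interplay jointly shape
    performance. Provides a synthetic-observer session generator that
    emulates a four-experiment audiovisual target-discrimination design,
    trial filtering and n-1 annotation, 2AFC d-prime and response-time
    scoring, subject-specific max-criterion multisensory facilitation,
    balanced mixed repeated-measures ANOVA with generalized eta squared,
    exhaustive-subset leave-one-out cross-validated regression with
    proportionate reduction of error, and trial-history (n-1) conditional
    d-prime analysis. All user-facing functions take and return tidy
    tables so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
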