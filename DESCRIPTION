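Package: otitext
Title: Otitis Surveillance from Free-Text Pediatric Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, seeded pipeline for classifying otitis diagnoses
    from free-text pediatric visit records into six mutually exclusive
    classes (no otitis, otitis not media, otitis media not acute, acute
    otitis media, acute otitis media with perforation, recurrent acute
    otitis media). Provides a synthetic labeled-corpus generator emulating
    the statistical and linguistic structure of Italian pediatric
    primary-care notes, pattern-based record selection, SEP/NUM text
    normalization with skip-gram word embeddings, five convolutional
    text-classification architectures with a logit-averaging ensemble, a
    rule-based recurrent-otitis labeler, weighted Cohen's kappa for
    inter-rater agreement, and balanced (macro-averaged) evaluation
    metrics. All randomness is seed-controlled so runs are reproducible.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
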