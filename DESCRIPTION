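Package: treatpanel
Title: Rubric-Based Gene Panel Selection for Genomic Newborn Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and auditing gene panels for genomic newborn
    screening of treatable rare diseases. Harmonizes gene-disease pair lists
    from curated treatability sources onto HGNC and MONDO identifiers, scores
    each pair on a declarative four-criterion rubric (clinical validity, age
    of onset, disease severity, penetrance) with mandatory treatability and
    genetic-feasibility gates, applies a total-score inclusion threshold, and
    represents expert curation as a typed, replayable decision ledger with a
    reason taxonomy. Emits score distributions, selection flow counts, and
    panel composition reports, and ships a seeded synthetic-data generator so
    the full pipeline is testable without any external database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
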