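Package: gtaccess
Title: Identify Access to Germline Genetic Testing from Clinical Notes
Version: 0.1.0
Authors@R: person("gtaccess", "maintainers", email = "gtaccess@example.org",
    role = c("aut", "cre"))
Description: A pipeline for identifying whether patients with breast cancer
    had access to germline genetic testing from unstructured clinical notes.
    Extracts keyword-anchored context-window snippets, consolidates them into
    one cleaned document per patient, applies deterministic triage rules
    (zero snippets is an automatic negative; a high snippet or word burden is
    an automatic positive), classifies the remainder with a zero-shot
    answer-template prompt through a pluggable backend, and evaluates the
    binary consolidation against adjudicated dual-reviewer consensus labels
    with bootstrap confidence intervals and chi-square comparisons. Ships a
    calibrated synthetic note-corpus generator so the whole pipeline can be
    exercised and tested without access to protected records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
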