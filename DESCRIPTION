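Package: drbank
Title: Discourse Relation Bank Annotation Toolkit
Version: 0.1.0
Authors@R: person("drbank", "developers", role = c("aut", "cre"),
    email = "drbank@example.org")
Description: Tools for working with stand-off annotated discourse relation
    banks in the pipe-delimited PDTB style: a two-tier sense taxonomy with
    a four-class generalization, reading and writing character-offset
    stand-off annotation files, inter-annotator agreement statistics
    (span overlap, exact/partial argument match, Cohen's kappa over sense
    labels), descriptive corpus statistics (relation-type, sense,
    connective-ambiguity and rhetorical-segment distributions), and
    connective-string sense-classification experiments with
    cross-validation, learning curves and cross-domain transfer. Includes
    a seeded synthetic corpus generator with a controlled second-annotator
    noise model for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
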