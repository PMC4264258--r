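Package: contextnl
Title: Contextual Properties of Medical Terms in Dutch Clinical Text
Version: 0.1.0
Authors@R:
    person("EMR", "Tools", email = "emr-tools@example.org", role = c("aut", "cre"))
Description: Rule-based detection of the contextual properties negation,
    temporality and experiencer for pre-marked medical terms in Dutch
    clinical free text, in the tradition of the NegEx/ConText family of
    algorithms.  Ships a curated Dutch trigger lexicon with pre-, post-,
    pseudo- and termination triggers, document-type specific scope
    profiles for general practitioner entries, specialist letters,
    radiology reports and discharge letters, a regular-expression
    temporality module, one-vs-rest precision/recall/F evaluation with
    Cohen's kappa, and a deterministic synthetic annotated-corpus
    generator for testing without access to protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
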