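Package: cmdeid
Title: De-Identification of Code-Mixed Chinese-English Clinical Text
Version: 0.1.0
Authors@R: person("Pkg", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the removal of protected health information
    (PHI) from clinical narratives written in a mixture of Chinese and
    English.  Provides a 6-coarse/20-fine PHI taxonomy, a mixed-script
    tokenizer with per-token language tags, a BILOU span codec with repair,
    corpus readers and writers (JSON, CoNLL, brat-style standoff), a seeded
    generator of synthetic code-mixed discharge-summary corpora with gold
    PHI annotations and surrogate resynthesis, code-mixing index (CMI)
    metrics with corpus aggregates, a dictionary-based baseline tagger, a
    CMI-driven translation-normalization pipeline, a constrained-prompt
    LLM de-identification framework with majority voting, and an
    entity-level evaluation protocol with exact and approximate matching,
    micro and macro averaging, coarse-grained mapped scoring, CMI-binned
    sentence error rates, and in-vocabulary/out-of-vocabulary
    stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
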