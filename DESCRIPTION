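Package: fluctme
Title: Maternal-Effect Evolution in Fluctuating Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and simulations for the evolution of maternal effects in
    temporally fluctuating two-state (normoxia-anoxia) environments. Provides
    designers and diagnostics for binary environmental sequences, a
    two-phenotype maternal-effect fitness model with geometric mean fitness
    and the optimal bet-hedging fraction, Kimura fixation-probability theory
    and Wright-Fisher invasion simulations for deterministic versus
    randomizing maternal-effect alleles, an analysis pipeline for
    two-generation factorial fitness assays (ln relative fitness against
    per-block ancestral means, geometric mean fitness over experienced
    environmental transitions, expected adaptation over enumerated
    multi-generation sequences), and a synthetic assay-data generator for
    end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
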