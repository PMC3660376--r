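Package: macevol
Title: Agent-Based Simulation of Ciliate Macronuclear Genome Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An individual-based evolutionary simulator for the macronuclear
    genome architecture of ciliates. Cells carry heritable ploidy (copy
    number) and DNA-elimination traits; fitness is the product of a
    DNA-content cost and a chromosome-imbalance cost derived from the
    extinction probability of a critical Galton-Watson branching process
    describing amitotic chromosome assortment. The package provides the
    closed-form fitness components, an explicit per-chromosome binomial
    assortment simulator used as an independent Monte-Carlo oracle, the
    population iteration loop (self-conjugation with mutation,
    fitness-weighted division, uniform culling), replicated runs with
    convergence detection, one-at-a-time parameter sweeps, and CSV/JSON
    trajectory and manifest writers.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
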