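Package: contextomics
Title: Contextual Interaction Proteomics: Absolute Stoichiometry, Copy
    Numbers and Native-Gel Migration Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to place affinity-purification mass-spectrometry
    interaction data in their cellular context. Converts spiked-reference
    (AQUA) peptide intensity tables into absolute protein amounts and
    iBAQ abundances, infers relative and best-fit integer complex
    stoichiometries, calibrates copies per cell against a receptor ruler,
    derives resource-allocation constraints (copies required for
    isostoichiometry, limiting components, recovered copies), estimates
    signalosome molecule counts and mass over a stimulation time course,
    and analyses differential blue-native PAGE migration profiles
    (normalisation, peak periodicity, deubiquitinase-induced early-to-late
    signal shifts, comigration). A seeded synthetic-data generator
    emulates the full study design so every pipeline stage is testable
    without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
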