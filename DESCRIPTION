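Package: ironbudget
Title: Iron and Heme Budgeting for Anaerobic Gut Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline linking anaerobic growth curves of gut
    Bacteroidetes to a whole-microbiome iron reservoir estimate. Fits the
    modified Gompertz growth model to optical-density time series, converts
    optical density to DNA, cell number and pellet mass through measured
    conversion factors, quantifies total iron (atomic absorption) and the
    porphyrins heme and protoporphyrin IX (LC-MS extracted-ion chromatogram
    integration against linear standard curves), normalizes analyte loads to
    genomic DNA, and extrapolates them to the cell census of the human gut
    microbiome. A companion module surveys the six-gene hmu heme-uptake
    operon with Needleman-Wunsch global alignment, percent-identity homolog
    detection, 0/1/2 conservation-pattern strings, and synteny checks.
    Includes a synthetic-data generator emulating plate-reader, atomic
    absorption and Q-TOF instruments plus operon-bearing genomes, so the
    whole pipeline is testable without instrument access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    pracma,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
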