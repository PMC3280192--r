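Package: carrierscreen
Title: Chemical-Genomics Screening for Yeast Drug-Uptake Transporters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for identifying plasma-membrane carriers that
    mediate drug uptake in Saccharomyces cerevisiae from two screening
    platforms: robot-spotted colony arrays of transporter deletion mutants
    and barcoded deletion-pool competitions. Implements diamond-window
    colony-array quantification from plate images, SD-threshold
    resistance/sensitivity calling against control plates, AFU enrichment
    analysis of pool competitions, growth-curve analysis with Hill-model
    IC90 estimation and competitive-substrate protection, and aggregation
    of per-drug evidence into a summary table. Seeded synthetic-data
    generators emulate plate images, pool competitions, and growth curves
    so every stage is testable without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    png,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    deSolve,
    jsonlite,
    optparse,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
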