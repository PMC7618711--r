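Package: ntpshift
Title: NTP Pool Remodelling and Translation Shutdown After Glucose Withdrawal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for the differential-affinity model of
    translation shutdown under acute energy stress in budding yeast.
    Converts HPLC nucleotide quantifications (pmol per 1e8 cells) into
    intracellular concentrations and per-cell molecule counts; computes
    Michaelis-Menten occupancy of translation factors with competitive ADP
    inhibition and classifies factors as active or released; reproduces the
    translation energy-budget arithmetic; simulates post-shift NTP pool
    dynamics as residual production balanced against a hierarchy of
    Michaelis-Menten sinks, with an emergent concentration set point;
    simulates ribosome run-off on mRNA pools with occupancy-gated initiation
    and renders synthetic polysome profiles; implements the CRAC/RNA-seq
    binding quantification chain (RPM/RPKM normalisation, replicate-median
    detection, pseudocount imputation, annotation and expression filters) and
    a nascent-proteome stage (presence filtering, median centring,
    left-censored MinProb imputation, differential flags, z-scored k-means
    clustering). Seeded synthetic-data generators emulate the statistical
    structure of the corresponding experimental datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    edgeR,
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
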