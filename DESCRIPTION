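Package: FCplus
Title: Cell-Division-Cycle Timing of Midcell Protein Recruitment from
    Axial Fluorescence Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies when a protein arrives at the division site of
    rod-shaped bacteria from snapshots of fixed, immunolabeled cells.
    Per-cell lengths, diameters and background-subtracted axial
    fluorescence profiles are converted to cell-division-cycle ages via
    the steady-state length-rank transformation, to the FCPlus midcell
    fluorescence surplus (the concentration difference between the
    central 0.8 um of the cell and the remainder, times the midcell
    volume), to age-binned mean curves with confidence intervals, to
    arrival times t0 and t1/2, to molecule-number estimates, and to
    length-sorted demographs. A steady-state population simulator with a
    known recruitment model provides ground truth for validation, and a
    Welch t-test compares arrival timing between strains across
    replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    data.table,
    yaml,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
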