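Package: actomap
Title: Quantification of Actin Dynamics, Membrane Recovery and Mutant
    Mapping in Plant Root Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for live-cell imaging and mutant-mapping
    readouts of plant root cells: all-pairs frame correlation and per-pixel
    difference metrics for actin time-lapse stacks, skeleton-based filament
    bundling skewness and occupancy from z-stacks, single-exponential FRAP
    (fluorescence recovery after photobleaching) fits reporting mobile
    fraction and halftime, particle quantification of brefeldin A (BFA)
    compartments, SNP-index mutant mapping against a wild-type-substituted
    reference with strict depth and index filters, and relative qPCR
    expression by the 2^-dCp method. Every analysis stage is paired with a
    seeded synthetic-data generator with known ground truth (filament
    networks, FRAP traces, blob fields, allele-count tables) so the whole
    pipeline is testable without microscopes or sequencers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    IRanges,
    jsonlite,
    methods,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    e1071,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
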