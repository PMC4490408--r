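Package: cscMarker
Title: Cell-Surface-Capture Glycoproteomics and Time-Course Marker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cell-surface-capture (CSC) N-glycoproteomics
    of reprogramming time courses. Qualifies peptide-spectrum matches as genuine
    N-glycopeptides (NxS/T sequon including C-terminally truncated forms,
    PNGase-F deamidation evidence on the sequon asparagine, 20 ppm mass
    agreement), collapses protein isoforms into proteoform groups quantified
    collectively under one primary ID, tallies and depth-normalizes spectral
    counts (square-root normalization to a reference total of 400) with
    absence-as-zero replicate averaging, and discovers candidate surface
    markers from the time course by PCA, K-means trajectory clustering and
    principal-component-loading ranking against F-class, ESC and MEF states.
    Includes fold-change, overlap and category-dispersion statistics,
    delta-delta-Ct relative quantification for qPCR validation panels, and a
    fully seeded synthetic-data generator with planted ground truth for every
    stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
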