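Package: cellsig
Title: Cross-Species Chromatin Accessibility and Expression Signatures of
    Multicellularity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate unicellular and multicellular signature
    genes by intersecting ortholog-restricted chromatin-accessibility calls
    with stage-exclusive expression calls across a stage-transitioning focal
    organism (e.g. Dictyostelium discoideum) and unicellular and
    multicellular reference organisms. Provides priority-based peak-to-gene
    feature annotation, per-gene accessibility calling, TSS metagene
    profiles, a CPM/TMM/negative-binomial exact-test expression enrichment
    chain, fixed-motif promoter enrichment, accessibility-expression
    association tests, electron-microscopy heterochromatin quantification,
    a fully seeded three-species synthetic-data generator with planted
    ground truth, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
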