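Package: cellrecap
Title: Cell-Cycle-Controlled Phylostratum Expression Profiling of
    Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether cell differentiation recapitulates
    phylogenesis at the transcriptome level.  Gene expression is grouped by
    phylostratum (evolutionary gene age), averaged per cell, and contrasted
    between cell populations with an ANCOVA-style intercept difference at a
    common slope, using the mean expression of a mitotic cell-cycle
    signature as the covariate that controls for proliferative activity.
    Additional modules stratify genes by the unicellular/multicellular
    composition of their one-step protein-interaction neighborhood, perform
    DAG-propagated hypergeometric enrichment with false-discovery-rate
    control, and simulate single-cell expression matrices, interactomes and
    ontologies with known ground truth for benchmarking the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    limma,
    Matrix,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
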