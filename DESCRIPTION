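Package: qpcrpanel
Title: Absolute Quantification and Dysbiosis Scoring for Stool Microbial qPCR Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a 15-marker stool microbial qPCR test:
    converts threshold cycles to absolute abundances (gene copies per gram of
    stool) via per-marker standard curves and rRNA gene copy-number
    normalization, derives relative log abundances against total Eubacteria,
    fits per-marker tolerance ranges (borderline and beyond-norm limits) on a
    healthy reference cohort, computes the Firmicutes/Bacteroidetes balance
    and the Faecalibacterium/Escherichia dysbiosis index with clinical
    categories, provides cohort-level descriptive statistics, and simulates
    synthetic cohorts and qPCR plates with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
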