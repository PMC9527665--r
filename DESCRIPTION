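Package: aluedit
Title: Downstream Analysis of A-to-I RNA Editing Loss from Edit-Site Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for the downstream analysis of adenosine-to-
    inosine (A-to-I) RNA editing from per-sample edit-site call tables:
    site-inclusion filtering, cohort common-site sets and ranked edit/read
    curves, genome-wide and per-gene editing indices with case/control log2
    ratios, Alu and gene-feature annotation, cell-lineage editing comparisons
    driven by single-cell marker detection percentages (pct1/pct2), and
    RNA-binding-protein / interferon gene-panel expression screens. A seeded
    synthetic-data generator supplies every input with known ground truth so
    the full analysis runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
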