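Package: barcodeSH
Title: Species-Hypothesis Distance-Threshold Testing for Fungal ITS Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test UNITE-style species-hypothesis (SH) distance
    thresholds on fungal ITS barcode alignments. Computes pairwise
    p-distances with explicit overlap and ambiguity rules, forms
    single-linkage clusters across the 0-3% threshold grid, evaluates
    the resulting partitions against a reference species assignment
    (resolved / split / merged / mixed), identifies species-diagnostic
    nucleotide positions and places short or low-quality sequences by
    them, and screens record quality. A multispecies-coalescent
    generator produces ITS-like synthetic data sets (region structure,
    partial records, ambiguities) so the whole analysis runs without
    external data. Includes helpers for the five-number
    micro-morphological measurement notation used in species
    descriptions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
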