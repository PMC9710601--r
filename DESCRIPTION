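Package: linkdecon
Title: Reference-Free Barcode Deconvolution for Linked-Read Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deconvolves linked-read (10x-style) read clouds without a
    reference genome. Reads sharing a barcode but originating from different
    long DNA fragments are separated by sparse k-mer indexing of the whole
    dataset, construction of a per-barcode read graph whose edge weights count
    shared overlapped barcodes, and weighted Chinese-whispers clustering into
    enhanced barcodes. Also provides a linked-read simulator with ground
    truth, the expected shared-barcode theory model, entropy-based clustering
    evaluation metrics, and barcode-aware taxonomic rank promotion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
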