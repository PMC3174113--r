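Package: allelotile
Title: Tiling-Array Peak Calling, Chromatin-Mark Colocalization and
    Allele-Specific Expression Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for ChIP-chip tiling-array analysis and
    allele-specific assays: windowed peak detection with
    permutation-derived false-positive rates and three-replicate
    consensus filtering; pairing of peaks from two chromatin marks
    (e.g. CTCF and H3K9me3) by distance with promoter/intragenic/
    intergenic context classification; motif-read cluster depth
    spectra with power-law fits and confidence partitioning; per-CpG
    bisulfite methylation scoring; and allelic-mixture calibration
    with mono/biallelic expression calling.  A synthetic-data module
    generates every input with known ground truth so the whole chain
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
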