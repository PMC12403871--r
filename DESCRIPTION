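Package: tumapr
Title: Transcription Unit Mapping from Strand-Specific RNA End Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide mapping of bacterial transcription units from
    strand-specific read-end profiles. Calls and classifies transcription
    start sites (TSSs) from dRNA-seq 5'-end enrichment, calls transcript
    3'-end positions (TEPs) from Term-seq, types intrinsic terminators by
    minimum-free-energy hairpin folding and U-tract content (L-shaped
    versus I-shaped), quantifies terminator readthrough from RNA-seq
    coverage, and assembles TSS-TEP transcription units with a COG-based
    functional-relatedness statistic. Includes a deterministic simulator
    of high-GC genomes with planted promoters, terminators and replicate
    end-count tracks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    S4Vectors,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
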