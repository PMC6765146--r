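Package: circulome
Title: Detection and Characterization of Extrachromosomal Circular DNA from
    Circulome-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterizing extrachromosomal circular
    DNA (eccDNA) produced during programmed genome rearrangement in ciliates.
    Implements the three sequencing signatures of circularity from
    tagmentation-based circle sequencing (Circulome-seq): transposon (TBE)
    circular-junction motif reads, split reads mapping the germline genome in
    permuted order, and read pairs carrying the 9 bp tagmentation duplication.
    Assembles junction reads into circle isoforms, applies coverage-based
    high-confidence filtering and reads-per-million normalization, annotates
    circles against MDS/pointer/IES rearrangement maps (cut-site compartments,
    flanking direct repeats, eliminated-sequence categories) with
    interval-shuffle permutation nulls, and quantifies rearrangement-specific
    circle transcription from RNA-seq. Includes a synthetic germline-genome and
    paired-end read simulator with exhaustive ground truth, so the whole
    pipeline runs and is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    Rsamtools,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
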