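Package: anablastr
Title: Coding-Region Discovery by Accumulated Low-Stringency Protein
    Alignments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects present and fossil protein-coding regions in genomic
    DNA by translating inter-exon sequences in all six reading frames with
    stop codons masked, aligning each framed translation against a
    clustered protein database under deliberately permissive scoring
    (BLOSUM90, low bit-score threshold, very high E-value cap), and
    accumulating alignments from distinct database clusters into
    per-position profiles.  Contiguous profile positions above an
    empirically calibrated cutoff are called as significant peaks that
    flag putative coding sequence, including pseudogenes and degenerate
    gene fossils that lack intact open reading frames.  Shuffled-sequence
    null controls calibrate the cutoff and bound the false-positive rate;
    a synthetic-genome simulator with planted coding implants provides a
    self-contained benchmarking harness.  Standard formats (FASTA, GFF3,
    BED, bedGraph, 12-column tabular search output) are used throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
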