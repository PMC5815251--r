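Package: preyweb
Title: Predator Diet DNA Metabarcoding from Amplicon Reads
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for spider (Araneae) gut-content DNA metabarcoding of
    Hexapoda prey using the nuclear ITS2 marker. Implements
    clade-discriminative and blocking primer design from paired rRNA clade
    alignments, index-based demultiplexing with strict quality filtering of
    forward reads, abundance-ordered greedy clustering of amplicons into
    97 percent OTUs, lowest-common-ancestor taxonomic assignment against a
    lineage-annotated reference set, construction of predator-by-prey
    interaction matrices and per-PCR-setting summary statistics, rarefaction
    curves, and a ground-truthed amplicon read simulator (intragenomic ITS2
    variants, blocking-primer suppression, per-base error with a positional
    quality model, chimeras) so that the whole pipeline can be exercised
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
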