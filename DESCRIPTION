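Package: irscape
Title: Genome-Wide Analysis of Cruciform-Capable Inverted Repeats
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects all maximal perfect inverted repeats (IRs) with
    cruciform-forming potential (arm >= 5 bp, spacer 0-8 bp, total >= 13 bp)
    in a genome, classifies them into seven sequence types from AT content,
    A/T-tract occupancy and alternating-AT occupancy of the repeat unit,
    partitions the genome into genic and intergenic region classes anchored
    at TSS, start/stop codons and poly(A) sites, profiles IR-center positions
    in 10-bp bins against an ensemble of composition-preserving randomized
    control genomes with per-bin Grubbs outlier calls, and computes
    chromosome-normalized nucleosome-occupancy metaprofiles around IR
    centers. A seed-reproducible synthetic-genome generator with planted IRs
    and nucleosome depletion windows makes every stage testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
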