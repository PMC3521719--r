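Package: psiscan
Title: Genome-Wide Pseudogene Surveys from Resequencing Variant Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls disrupted alleles (frameshift and premature stop codon)
    per gene and per accession from homozygous variant tables against a
    reference annotation, and summarises the resulting pseudogene landscape:
    per-accession counts, allele-frequency spectra, accumulation curves with
    logarithmic fits, shared-pseudogene randomization nulls, windowed
    gene-density statistics, centromere/telomere feature contrasts, gene
    cluster and sequence-similarity family classification, Nei-Gojobori
    Ka/Ks with Jukes-Cantor correction, nucleotide diversity and Tajima's D,
    domain-family bias statistics, and a presence/absence neighbor-joining
    phylogeny. Includes a synthetic-data generator with planted disruptions
    and truth tables so the full pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
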