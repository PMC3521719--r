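# Hand-built fixtures used across test files.  All genome coordinates are
# 0-based half-open; CDS offsets are hand-mapped in the comments.

# Plus-strand two-exon gene:
#   CDS  = ATGAAACCC | GGGTTTTGGTAA   (21 bp, 7 codons, ends in TAA)
#   exon1 genome [10,19) -> CDS 0..8
#   intron       [19,27)
#   exon2 genome [27,39) -> CDS 9..20
plus_gene <- function() {
  gene_model(locus_id = "GP1", transcript_id = "GP1.1",
             chromosome = "chrT", strand = "+",
             cds_intervals = rbind(c(10, 19), c(27, 39)),
             cds_sequence = "ATGAAACCCGGGTTTTGGTAA")
}

# Minus-strand two-exon gene with the same CDS:
#   transcript order: exon at [30,39) (CDS 0..8) then [10,22) (CDS 9..20)
#   genome [30,39) = revcomp(ATGAAACCC) = GGGTTTCAT
#   genome [10,22) = revcomp(GGGTTTTGGTAA) = TTACCAAAACCC
minus_gene <- function() {
  gene_model(locus_id = "GM1", transcript_id = "GM1.1",
             chromosome = "chrT", strand = "-",
             cds_intervals = rbind(c(10, 22), c(30, 39)),
             cds_sequence = "ATGAAACCCGGGTTTTGGTAA")
}

# single-exon 100-codon gene on the plus strand starting at genome 0;
# codon 5 (1-based) is TGG so a G->A third-position change creates TGA
long_gene <- function() {
  body <- paste(rep("GAA", 94), collapse = "")
  cds <- paste0("ATG", "AAA", "CCC", "GGA", "TGG", body, "TAA")
  stopifnot(nchar(cds) == 300)
  gene_model(locus_id = "GL1", transcript_id = "GL1.1",
             chromosome = "chrL", strand = "+",
             cds_intervals = rbind(c(0, 300)), cds_sequence = cds)
}

variant_row <- function(chrom, pos, ref, alt, vclass) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             vclass = vclass, stringsAsFactors = FALSE)
}

no_variants <- function() {
  data.frame(chrom = character(), pos = numeric(), ref = character(),
             alt = character(), vclass = character(),
             stringsAsFactors = FALSE)
}

# indel list in the shape returned by coding_indels()
indel_df <- function(cds_position, signed_length, whole = FALSE) {
  d <- data.frame(cds_position = cds_position, signed_length = signed_length)
  attr(d, "whole_gene_deletion") <- whole
  d
}

small_sim <- function(seed = 1, ...) {
  p <- sim_params(seed = seed, n_chromosomes = 2,
                  chromosome_length_bp = 3e5, n_genes = 60,
                  n_accessions = 8, per_gene_disruption_prob = 0.3, ...)
  ref <- simulate_reference(p)
  list(params = p, ref = ref, variants = simulate_variants(p, ref))
}
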