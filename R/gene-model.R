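# Amino acids for codons indexed in TCAG order: idx = 16*b1 + 4*b2 + b3 + 1.
.AA_BY_INDEX <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", ""
)[[1]]
.BASE_INDEX <- c(T = 0L, C = 1L, A = 2L, G = 3L)
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Translate a coding sequence in the annotated frame
#'
#' Translates a nucleotide string with the standard genetic code, returning
#' one-letter amino acids with `*` for stop codons.  Codons containing
#' characters other than A, C, G, T translate to `NA`.
#'
#' @param seq Nucleotide string whose length is a multiple of 3.
#' @return Character vector of amino acids, one per codon.
#' @export
translate_cds <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
  b <- .BASE_INDEX[strsplit(toupper(seq), "")[[1]]]
  idx <- 16L * b[seq(1L, n, 3L)] + 4L * b[seq(2L, n, 3L)] + b[seq(3L, n, 3L)] + 1L
  .AA_BY_INDEX[idx]
}

#' Reverse complement of a nucleotide string
#' @param seq Nucleotide string (A/C/G/T/N).
#' @return Reverse-complemented string.
#' @keywords internal
revcomp <- function(seq) {
  paste(rev(.COMPLEMENT[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

#' Construct a gene model
#'
#' A gene model describes one reference locus by its first transcript: the
#' ordered CDS intervals on the genome and the spliced, strand-oriented
#' coding sequence.  All coordinates are 0-based half-open; `cds_intervals`
#' is stored in ascending genome order regardless of strand.
#'
#' @param locus_id,transcript_id Locus and transcript identifiers.
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds_intervals Two-column matrix of (start, end) 0-based half-open
#'   genome intervals, non-overlapping.
#' @param cds_sequence Spliced CDS in transcript orientation (starts with the
#'   start codon).
#' @param biotype One of `"protein_coding"`, `"pseudogene"`,
#'   `"transposable_element"`, `"other"`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(locus_id, transcript_id, chromosome, strand,
                       cds_intervals, cds_sequence,
                       biotype = "protein_coding") {
  stopifnot(strand %in% c("+", "-"))
  cds_intervals <- matrix(as.numeric(cds_intervals), ncol = 2L)
  o <- order(cds_intervals[, 1L])
  cds_intervals <- cds_intervals[o, , drop = FALSE]
  widths <- cds_intervals[, 2L] - cds_intervals[, 1L]
  if (any(widths <= 0)) stop("empty or inverted CDS interval in ", locus_id)
  if (sum(widths) != nchar(cds_sequence))
    stop("CDS sequence length disagrees with intervals in ", locus_id)
  if (nchar(cds_sequence) < 3L) stop("CDS shorter than one codon in ", locus_id)
  structure(
    list(locus_id = locus_id, transcript_id = transcript_id,
         chromosome = chromosome, strand = strand,
         cds_intervals = cds_intervals,
         cds_sequence = toupper(cds_sequence),
         exon_count = nrow(cds_intervals),
         biotype = biotype),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s strand %s, %d CDS exon(s), %d bp\n",
              x$locus_id, x$transcript_id, x$chromosome,
              paste0(min(x$cds_intervals), "-", max(x$cds_intervals)),
              x$strand, x$exon_count, nchar(x$cds_sequence)))
  invisible(x)
}

# Genome span covered by the CDS: c(start, end), 0-based half-open.
gene_span <- function(gene) {
  c(min(gene$cds_intervals[, 1L]), max(gene$cds_intervals[, 2L]))
}

#' Map a genome position to a CDS coordinate
#'
#' Returns the 0-based offset within the spliced CDS (transcript
#' orientation) of the base at 0-based genome position `gpos`, or `NA` when
#' the position is not coding.
#'
#' @param gene A [gene_model()].
#' @param gpos Vector of 0-based genome positions.
#' @return Integer vector of CDS offsets (NA for non-coding positions).
#' @export
genome_to_cds <- function(gene, gpos) {
  iv <- gene$cds_intervals
  widths <- iv[, 2L] - iv[, 1L]
  if (gene$strand == "+") {
    offs <- c(0, cumsum(widths))[-(nrow(iv) + 1L)]
  } else {
    # transcript reads intervals in descending genome order
    offs_rev <- c(0, cumsum(rev(widths)))[-(nrow(iv) + 1L)]
    offs <- rev(offs_rev)
  }
  vapply(gpos, function(g) {
    i <- which(iv[, 1L] <= g & g < iv[, 2L])
    if (length(i) != 1L) return(NA_real_)
    if (gene$strand == "+") offs[i] + (g - iv[i, 1L])
    else offs[i] + (iv[i, 2L] - 1 - g)
  }, numeric(1))
}

#' Map a CDS coordinate back to a genome position
#'
#' Inverse of [genome_to_cds()].
#'
#' @param gene A [gene_model()].
#' @param cpos Vector of 0-based CDS offsets.
#' @return Numeric vector of 0-based genome positions.
#' @export
cds_to_genome <- function(gene, cpos) {
  iv <- gene$cds_intervals
  widths <- iv[, 2L] - iv[, 1L]
  ord <- if (gene$strand == "+") seq_len(nrow(iv)) else rev(seq_len(nrow(iv)))
  bounds <- c(0, cumsum(widths[ord]))
  vapply(cpos, function(p) {
    j <- findInterval(p, bounds, rightmost.closed = FALSE)
    if (j < 1L || j > length(ord) || p >= bounds[length(bounds)])
      stop("CDS offset ", p, " outside CDS of ", gene$locus_id)
    i <- ord[j]
    within <- p - bounds[j]
    if (gene$strand == "+") iv[i, 1L] + within else iv[i, 2L] - 1 - within
  }, numeric(1))
}

#' Extract the spliced CDS of a gene from chromosome sequence
#'
#' @param gene A [gene_model()] (sequence field may be empty).
#' @param chrom_seq Chromosome sequence as a single string, or a
#'   `Biostrings::DNAStringSet` keyed by chromosome.
#' @return Spliced, strand-oriented CDS string.
#' @export
spliced_cds <- function(gene, chrom_seq) {
  if (inherits(chrom_seq, "DNAStringSet"))
    chrom_seq <- as.character(chrom_seq[[gene$chromosome]])
  pieces <- apply(gene$cds_intervals, 1L, function(iv)
    substr(chrom_seq, iv[1L] + 1L, iv[2L]))
  s <- paste(pieces, collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}

#' Basic per-gene features
#'
#' CDS length in bp, CDS exon count, and GC fraction of the spliced CDS —
#' the gene-level covariates contrasted between centromere and telomere
#' regions.
#'
#' @param gene A [gene_model()].
#' @return Named numeric vector `cds_length_bp`, `exon_count`, `gc_fraction`.
#' @export
gene_features <- function(gene) {
  s <- gene$cds_sequence
  n <- nchar(s)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C"))
  c(cds_length_bp = n, exon_count = gene$exon_count, gc_fraction = gc / n)
}
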