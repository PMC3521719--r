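# Disrupted-allele calling: frameshift (net coding indel length not a
# multiple of 3, or a compensating 3-indel set spanning > 300 bp) and
# premature stop codons created by SNVs, classified by relative position
# in the intact reference CDS.

#' Caller parameters
#'
#' @param set_span_bp Span threshold (bp) above which a set of three
#'   frame-disrupting but net-compensating indels still counts as a
#'   frameshift (default 300).
#' @param criterion Which part of the ORF a locus's 5'-most disruption must
#'   fall in for the locus to count as a pseudogene locus:
#'   `"whole_orf"` (any position), `"first_two_thirds"`, or
#'   `"first_third"`.
#' @param bin_edges Relative-position bin edges (default 1/3 and 2/3); ties
#'   at an edge fall in the lower bin.
#' @return List of class `caller_params`.
#' @export
caller_params <- function(set_span_bp = 300,
                          criterion = c("whole_orf", "first_two_thirds",
                                        "first_third"),
                          bin_edges = c(1 / 3, 2 / 3)) {
  criterion <- match.arg(criterion)
  stopifnot(all(bin_edges > 0), all(bin_edges < 1), !is.unsorted(bin_edges))
  structure(list(set_span_bp = set_span_bp, criterion = criterion,
                 bin_edges = bin_edges), class = "caller_params")
}

.criterion_cutoff <- function(criterion) {
  switch(criterion, first_third = 1 / 3, first_two_thirds = 2 / 3,
         whole_orf = 1)
}

.bin_of <- function(rel, edges = c(1 / 3, 2 / 3)) {
  # ties at an edge fall in the lower bin
  labels <- c("0-1/3", "1/3-2/3", "2/3-1")
  idx <- 1L + (rel > edges[1]) + (rel > edges[2])
  labels[idx]
}

#' Coding indels of one accession in one gene
#'
#' Maps an accession's insertions and deletions onto the intact reference
#' CDS.  Positions are 0-based offsets of the first affected coding base in
#' transcript orientation; a deletion overhanging an exon boundary
#' contributes only its coding bases to the signed length.
#'
#' @param gene A [gene_model()].
#' @param variants Variant data frame for one accession (see
#'   [read_variants()]); must be position-sorted and non-overlapping.
#' @return Data frame `cds_position`, `signed_length`, ordered 5' to 3',
#'   with attribute `whole_gene_deletion` (logical).
#' @export
coding_indels <- function(gene, variants) {
  v <- variants[variants$chrom == gene$chromosome &
                  variants$vclass %in% c("insertion", "deletion"), ,
                drop = FALSE]
  iv <- gene$cds_intervals
  out <- list()
  whole <- FALSE
  span <- gene_span(gene)
  for (i in seq_len(nrow(v))) {
    pos <- v$pos[i]
    if (v$vclass[i] == "insertion") {
      # inserted before genome base at `pos`; coding only if strictly
      # inside an exon (both flanking bases coding)
      inside <- any(iv[, 1L] < pos & pos < iv[, 2L])
      if (!inside) next
      cpos <- if (gene$strand == "+") genome_to_cds(gene, pos)
        else genome_to_cds(gene, pos - 1)
      out[[length(out) + 1L]] <-
        c(cds_position = cpos, signed_length = nchar(v$alt[i]))
    } else {
      del <- c(pos, pos + nchar(v$ref[i]))
      if (del[1L] <= span[1L] && del[2L] >= span[2L]) {
        whole <- TRUE
        out[[length(out) + 1L]] <- c(cds_position = 0, signed_length = -nchar(gene$cds_sequence))
        next
      }
      hit <- pmax(iv[, 1L], del[1L]) < pmin(iv[, 2L], del[2L])
      if (!any(hit)) next
      coding_bases <- sum(pmin(iv[hit, 2L], del[2L]) -
                            pmax(iv[hit, 1L], del[1L]))
      gfirst <- if (gene$strand == "+")
        max(del[1L], min(iv[hit, 1L]))
      else min(del[2L], max(iv[hit, 2L])) - 1
      cpos <- genome_to_cds(gene, gfirst)
      out[[length(out) + 1L]] <-
        c(cds_position = cpos, signed_length = -coding_bases)
    }
  }
  if (!length(out)) {
    res <- data.frame(cds_position = numeric(), signed_length = numeric())
  } else {
    res <- as.data.frame(do.call(rbind, out))
    res <- res[order(res$cds_position), , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "whole_gene_deletion") <- whole
  res
}

#' Detect a frameshift from coding indels
#'
#' If the net signed length of all coding indels is not a multiple of 3,
#' the allele is frameshifted at the 5'-most frame-disrupting indel.
#' Otherwise a sliding window of three consecutive frame-disrupting indels
#' is examined: if any window spans more than `set_span_bp` between its
#' first and last member, the frameshift is placed at that window's first
#' member.
#'
#' @param indels Output of [coding_indels()].
#' @param params A [caller_params()].
#' @return A one-row data frame `kind`, `cds_position`, or `NULL`.
#' @export
detect_frameshift <- function(indels, params = caller_params()) {
  if (!nrow(indels)) return(NULL)
  frame_dis <- indels[abs(indels$signed_length) %% 3 != 0, , drop = FALSE]
  net <- sum(indels$signed_length)
  if (net %% 3 != 0) {
    return(data.frame(kind = "frameshift",
                      cds_position = frame_dis$cds_position[1L]))
  }
  m <- nrow(frame_dis)
  if (m >= 3L) {
    for (i in seq_len(m - 2L)) {
      if (frame_dis$cds_position[i + 2L] - frame_dis$cds_position[i] >
            params$set_span_bp)
        return(data.frame(kind = "frameshift",
                          cds_position = frame_dis$cds_position[i]))
    }
  }
  if (isTRUE(attr(indels, "whole_gene_deletion")))
    return(data.frame(kind = "frameshift", cds_position = 0))
  NULL
}

#' Detect a premature stop codon created by SNVs
#'
#' Applies an accession's SNVs to the intact reference CDS and translates
#' in the annotated frame.  A stop codon in any codon before the annotated
#' terminal one, containing at least one substituted base, is a premature
#' stop; the event position is the first base of the 5'-most such codon.
#' Loss of the start codon or of the terminal stop is not a
#' disruption call.
#'
#' @param gene A [gene_model()].
#' @param variants Variant data frame for one accession.
#' @return A one-row data frame `kind`, `cds_position`, or `NULL`.
#' @export
detect_premature_stop <- function(gene, variants) {
  v <- variants[variants$chrom == gene$chromosome &
                  variants$vclass == "snv", , drop = FALSE]
  if (!nrow(v)) return(NULL)
  cpos <- genome_to_cds(gene, v$pos)
  keep <- !is.na(cpos)
  if (!any(keep)) return(NULL)
  cpos <- cpos[keep]
  alt <- v$alt[keep]
  if (gene$strand == "-") alt <- unname(.COMPLEMENT[alt])
  s <- strsplit(gene$cds_sequence, "")[[1]]
  s[cpos + 1L] <- alt
  L <- length(s)
  aa <- translate_cds(paste(s, collapse = ""))
  n_codons <- L / 3L
  mutated_codons <- unique(cpos %/% 3L)       # 0-based codon indices
  stops <- which(aa == "*") - 1L              # 0-based
  premature <- stops[stops < n_codons - 1L & stops %in% mutated_codons]
  if (!length(premature)) return(NULL)
  first <- min(premature)
  data.frame(kind = "premature_stop", cds_position = 3 * first)
}

#' Call one (gene, accession) allele
#'
#' Combines frameshift and premature-stop detection.  The primary event is
#' the 5'-most disruptive mutation; a positional tie is broken in favour of
#' the frameshift.
#'
#' @param gene A [gene_model()].
#' @param accession_variants Variant data frame for one accession.
#' @param params A [caller_params()].
#' @return List with `verdict` (`"intact"`/`"disrupted"`), `events`
#'   (data frame `kind`, `cds_position`, `relative_position`, `bin`) and
#'   `primary_event` (one-row data frame or `NULL`).
#' @export
call_allele <- function(gene, accession_variants,
                        params = caller_params()) {
  L <- nchar(gene$cds_sequence)
  ev <- rbind(detect_frameshift(coding_indels(gene, accession_variants),
                                params),
              detect_premature_stop(gene, accession_variants))
  if (is.null(ev) || !nrow(ev)) {
    return(list(verdict = "intact",
                events = data.frame(kind = character(),
                                    cds_position = numeric(),
                                    relative_position = numeric(),
                                    bin = character()),
                primary_event = NULL))
  }
  ev$relative_position <- ev$cds_position / L
  ev$bin <- .bin_of(ev$relative_position, params$bin_edges)
  # frameshift wins a positional tie
  o <- order(ev$cds_position, ev$kind != "frameshift")
  ev <- ev[o, , drop = FALSE]
  rownames(ev) <- NULL
  list(verdict = "disrupted", events = ev,
       primary_event = ev[1L, , drop = FALSE])
}

#' Call all loci across all accessions
#'
#' Applies [call_allele()] to every gene and accession.  Absence of a
#' variant record means the accession carries the reference allele (calls
#' in inaccessible regions are assumed to match the reference).
#'
#' @param genes Named list of [gene_model()] objects.
#' @param variant_sets Named list mapping accession to its variant data
#'   frame.
#' @param params A [caller_params()].
#' @return An object of class `psi_table`: list with `calls` (long data
#'   frame of disrupted calls: `locus`, `accession`, `kind`, `cds_pos`,
#'   `rel_pos`, `bin`), `loci`, `accessions`, `cds_length` (named), `k`
#'   (named per-locus disrupted count), `psi` (named list of logical
#'   per-locus pseudogene status under each criterion), `bin_counts`
#'   (per-bin locus counts, overlapping across accessions), and `params`.
#' @export
call_loci <- function(genes, variant_sets, params = caller_params()) {
  stopifnot(length(variant_sets) >= 1L)
  accessions <- names(variant_sets)
  # index variants per accession and chromosome for fast span queries
  idx <- lapply(variant_sets, function(d) split(d, d$chrom))
  calls <- vector("list", 1000L)
  nc <- 0L
  for (g in genes) {
    span <- gene_span(g)
    for (acc in accessions) {
      d <- idx[[acc]][[g$chromosome]]
      if (is.null(d) || !nrow(d)) next
      lo <- findInterval(span[1L] - max(nchar(d$ref)) - 1L, d$pos) + 1L
      hi <- findInterval(span[2L] - 1L, d$pos)
      if (lo > hi) next
      sub <- d[lo:hi, , drop = FALSE]
      sub <- sub[sub$pos + pmax(1L, nchar(sub$ref)) > span[1L] &
                   sub$pos < span[2L], , drop = FALSE]
      if (!nrow(sub)) next
      res <- call_allele(g, sub, params)
      if (res$verdict == "disrupted") {
        nc <- nc + 1L
        if (nc > length(calls)) calls <- c(calls, vector("list", length(calls)))
        p <- res$primary_event
        calls[[nc]] <- data.frame(
          locus = g$locus_id, accession = acc, kind = p$kind,
          cds_pos = p$cds_position, rel_pos = p$relative_position,
          bin = p$bin, stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (nc) do.call(rbind, calls[seq_len(nc)]) else
    data.frame(locus = character(), accession = character(),
               kind = character(), cds_pos = numeric(),
               rel_pos = numeric(), bin = character())
  loci <- names(genes)
  cds_length <- vapply(genes, function(g) nchar(g$cds_sequence), 0)
  k <- table(factor(calls$locus, levels = loci))
  k <- stats::setNames(as.integer(k), loci)
  psi <- lapply(c(first_third = 1 / 3, first_two_thirds = 2 / 3,
                  whole_orf = 1), function(cut) {
    hit <- unique(calls$locus[calls$rel_pos < cut])
    stats::setNames(loci %in% hit, loci)
  })
  bins <- c("0-1/3", "1/3-2/3", "2/3-1")
  bin_counts <- vapply(bins, function(b)
    length(unique(calls$locus[calls$bin == b])), 0L)
  structure(list(calls = calls, loci = loci, accessions = accessions,
                 cds_length = cds_length, k = k, psi = psi,
                 bin_counts = bin_counts, params = params),
            class = "psi_table")
}

#' @export
print.psi_table <- function(x, ...) {
  cat(sprintf(
    "<psi_table> %d loci x %d accessions; pseudogene loci: %d (whole ORF), %d (first 2/3), %d (first 1/3)\n",
    length(x$loci), length(x$accessions), sum(x$psi$whole_orf),
    sum(x$psi$first_two_thirds), sum(x$psi$first_third)))
  invisible(x)
}

#' Pseudogene loci under the table's active (or a given) criterion
#' @param table A `psi_table`.
#' @param criterion Optional criterion overriding the table's own.
#' @return Character vector of locus ids.
#' @export
psi_loci <- function(table, criterion = NULL) {
  criterion <- criterion %||% table$params$criterion
  table$loci[table$psi[[criterion]]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chi-square test for positional bias of disabling mutations
#'
#' Goodness-of-fit of per-bin pseudogene locus counts against a uniform
#' distribution over the three ORF thirds.
#'
#' @param bin_counts Numeric vector of three per-bin locus counts.
#' @return `htest` object from [stats::chisq.test()].
#' @export
positional_bias_chisq <- function(bin_counts) {
  stats::chisq.test(bin_counts)
}
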