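# Format boundary: GFF3/FASTA/VCF/TSV/BED live 1-based outside, everything
# internal is 0-based half-open.

.natural_transcript_order <- function(ids) {
  # ".1" before ".2" before ".10"; non-numeric suffixes sort after, by name
  suffix <- suppressWarnings(as.numeric(sub("^.*\\.", "", ids)))
  order(is.na(suffix), suffix, ids)
}

#' Read a reference annotation into gene models
#'
#' Parses a GFF3 (gene/mRNA/CDS features) plus the genome FASTA and returns
#' one [gene_model()] per protein-coding locus.  When a locus has several
#' mRNAs, the transcript whose identifier sorts first under natural sort
#' (".1" before ".2") is kept.  Loci annotated as pseudogenes or transposable
#' elements are excluded from the analysis set but counted in the attached
#' parse report; genes whose CDS length is not a positive multiple of 3 are
#' skipped with a warning.
#'
#' @param gff3_path Path to a GFF3 file.
#' @param fasta_path Path to the genome FASTA covering all referenced
#'   chromosomes.
#' @return Named list of `gene_model` objects (analysis set), with
#'   attributes `report` (named counts of excluded loci) and
#'   `chromosome_lengths` (named numeric vector).
#' @export
read_annotation <- function(gff3_path, fasta_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  type <- as.character(gff$type)
  chrom <- as.character(GenomicRanges::seqnames(gff))
  # 0-based half-open
  gstart <- GenomicRanges::start(gff) - 1
  gend <- GenomicRanges::end(gff)
  strand <- as.character(GenomicRanges::strand(gff))
  id <- if (!is.null(gff$ID)) as.character(gff$ID) else rep(NA_character_, length(gff))
  parent <- if (!is.null(gff$Parent))
    vapply(gff$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  else rep(NA_character_, length(gff))

  biotype_of <- function(i) {
    bt <- if (!is.null(gff$biotype)) as.character(gff$biotype)[i] else NA
    if (!is.na(bt)) return(bt)
    switch(type[i],
           gene = "protein_coding",
           pseudogene = "pseudogene",
           pseudogenic_gene = "pseudogene",
           transposable_element_gene = "transposable_element",
           transposable_element = "transposable_element",
           "other")
  }

  gene_idx <- which(type %in% c("gene", "pseudogene", "pseudogenic_gene",
                                "transposable_element_gene"))
  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  cds_idx <- which(type == "CDS")
  mrna_by_gene <- split(mrna_idx, parent[mrna_idx])
  cds_by_tx <- split(cds_idx, parent[cds_idx])

  models <- list()
  report <- c(protein_coding = 0L, pseudogene = 0L,
              transposable_element = 0L, other = 0L, skipped_bad_cds = 0L)
  for (gi in gene_idx) {
    locus <- id[gi]
    bt <- biotype_of(gi)
    if (bt != "protein_coding") {
      report[bt] <- report[bt] + 1L
      next
    }
    txs <- mrna_by_gene[[locus]]
    if (is.null(txs) || !length(txs)) next
    tx_ids <- id[txs]
    tx <- txs[.natural_transcript_order(tx_ids)[1L]]
    cds <- cds_by_tx[[id[tx]]]
    if (is.null(cds) || !length(cds)) next
    iv <- cbind(gstart[cds], gend[cds])
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    chr <- chrom[cds[1L]]
    if (!chr %in% names(genome))
      stop("chromosome ", chr, " of ", locus, " absent from FASTA")
    clen <- length(genome[[chr]])
    if (any(iv[, 1L] < 0) || any(iv[, 2L] > clen))
      stop("CDS of ", id[tx], " outside chromosome ", chr)
    total <- sum(iv[, 2L] - iv[, 1L])
    if (total < 3L || total %% 3L != 0L) {
      warning("skipping ", locus, ": CDS length ", total,
              " not a positive multiple of 3")
      report["skipped_bad_cds"] <- report["skipped_bad_cds"] + 1L
      next
    }
    g <- gene_model(locus_id = locus, transcript_id = id[tx],
                    chromosome = chr, strand = strand[cds[1L]],
                    cds_intervals = iv, cds_sequence = strrep("N", total))
    g$cds_sequence <- spliced_cds(g, as.character(genome[[chr]]))
    models[[locus]] <- g
    report["protein_coding"] <- report["protein_coding"] + 1L
  }
  structure(models, report = report,
            chromosome_lengths = stats::setNames(
              vapply(genome, length, 0L), names(genome)))
}

.empty_variants <- function() {
  data.frame(chrom = character(), pos = numeric(), ref = character(),
             alt = character(), vclass = character(),
             stringsAsFactors = FALSE)
}

.finish_variant_set <- function(df, accession) {
  o <- order(df$chrom, df$pos)
  if (any(o != seq_along(o))) {
    warning("variants for ", accession, " were unsorted; sorting")
  }
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  # overlap check: ref footprint [pos, pos + max(1, nchar(ref)))
  by_chrom <- split(df, df$chrom)
  for (d in by_chrom) {
    if (nrow(d) < 2L) next
    span_end <- d$pos + pmax(1L, nchar(d$ref))
    bad <- which(d$pos[-1L] < span_end[-nrow(d)])
    if (length(bad))
      stop("overlapping variants for accession ", accession, " at ",
           d$chrom[1L], ":", paste(d$pos[bad] + 1L, collapse = ","))
  }
  df
}

#' Read per-accession variant tables
#'
#' Two dialects are supported.  `"vcf"` reads a minimal multi-sample VCF
#' (CHROM/POS/REF/ALT plus one GT-bearing column per accession); genotypes
#' must be homozygous (the accessions are selfing lines) and anchor bases
#' are stripped so indel positions point at the first changed base.
#' `"tsv1001"` reads a directory of per-accession tab-separated files named
#' `<accession>.tsv` with columns `chrom pos_1based ref alt class`, where
#' `ref`/`alt` use `-` for the empty allele and `pos_1based` is the 1-based
#' position of the first affected base (for insertions, of the base before
#' which the new sequence is inserted).
#'
#' @param path VCF file (`dialect = "vcf"`) or directory of TSVs
#'   (`dialect = "tsv1001"`).
#' @param dialect `"vcf"` or `"tsv1001"`.
#' @return Named list mapping accession id to a data frame with columns
#'   `chrom`, `pos` (0-based first affected base), `ref`, `alt` (empty
#'   string for absent allele), `vclass` (`snv`/`insertion`/`deletion`),
#'   sorted by chromosome and position.
#' @export
read_variants <- function(path, dialect = c("vcf", "tsv1001")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv1001") {
    files <- list.files(path, pattern = "\\.tsv$", full.names = TRUE)
    if (!length(files)) stop("no .tsv files in ", path)
    out <- lapply(files, function(f) {
      d <- utils::read.table(f, header = TRUE, sep = "\t",
                             colClasses = c("character", "numeric",
                                            "character", "character",
                                            "character"))
      names(d) <- c("chrom", "pos_1based", "ref", "alt", "vclass")
      data.frame(chrom = d$chrom, pos = d$pos_1based - 1,
                 ref = ifelse(d$ref == "-", "", toupper(d$ref)),
                 alt = ifelse(d$alt == "-", "", toupper(d$alt)),
                 vclass = d$vclass, stringsAsFactors = FALSE)
    })
    names(out) <- sub("\\.tsv$", "", basename(files))
    return(mapply(.finish_variant_set, out, names(out), SIMPLIFY = FALSE))
  }
  lines <- readLines(path)
  header <- grep("^#CHROM", lines, value = TRUE)
  if (!length(header)) stop("no #CHROM header line in ", path)
  cols <- strsplit(header, "\t")[[1]]
  if (length(cols) < 10L) stop("VCF has no sample columns")
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t")
  sets <- stats::setNames(
    replicate(length(samples), list(.empty_variants())), samples)
  rows <- lapply(fields, function(f) {
    ref <- toupper(f[4L]); alt <- toupper(f[5L])
    pos1 <- as.numeric(f[2L])
    # strip shared anchor base
    if (nchar(ref) != nchar(alt) &&
        nchar(ref) >= 1L && nchar(alt) >= 1L &&
        substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nchar(ref))
      alt <- substr(alt, 2L, nchar(alt))
      pos1 <- pos1 + 1
    }
    vclass <- if (nchar(ref) == 1L && nchar(alt) == 1L) "snv"
      else if (nchar(ref) == 0L) "insertion"
      else if (nchar(alt) == 0L) "deletion"
      else stop("unsupported complex allele at ", f[1L], ":", f[2L])
    gts <- f[-(1:9)]
    gt <- sub(":.*$", "", gts)
    list(chrom = f[1L], pos = pos1 - 1, ref = ref, alt = alt,
         vclass = vclass, gt = gt)
  })
  for (s in seq_along(samples)) {
    carrier <- vapply(rows, function(r) {
      g <- r$gt[s]
      if (g %in% c("0/1", "1/0", "0|1", "1|0"))
        stop("heterozygous genotype for ", samples[s],
             "; accessions must be homozygous")
      g %in% c("1/1", "1|1", "1")
    }, logical(1))
    if (any(carrier)) {
      sub <- rows[carrier]
      sets[[s]] <- data.frame(
        chrom = vapply(sub, `[[`, "", "chrom"),
        pos = vapply(sub, `[[`, 0, "pos"),
        ref = vapply(sub, `[[`, "", "ref"),
        alt = vapply(sub, `[[`, "", "alt"),
        vclass = vapply(sub, `[[`, "", "vclass"),
        stringsAsFactors = FALSE)
    }
  }
  mapply(.finish_variant_set, sets, names(sets), SIMPLIFY = FALSE)
}

#' Write variant sets in the per-accession TSV dialect
#'
#' Inverse of `read_variants(dialect = "tsv1001")`; round-trips exactly.
#'
#' @param variant_sets Named list of variant data frames (see
#'   [read_variants()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_variants_tsv <- function(variant_sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(variant_sets), function(acc) {
    d <- variant_sets[[acc]]
    out <- data.frame(chrom = d$chrom, pos_1based = format(d$pos + 1, scientific = FALSE, trim = TRUE),
                      ref = ifelse(d$ref == "", "-", d$ref),
                      alt = ifelse(d$alt == "", "-", d$alt),
                      class = d$vclass)
    p <- file.path(dir, paste0(acc, ".tsv"))
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, "")
  invisible(paths)
}

#' Build centromere and telomere region sets
#'
#' Centromere regions span `span` bp centred on each chromosome's
#' centromere midpoint (clipped to the chromosome); telomere regions are
#' `span` bp from each chromosome tip.
#'
#' @param chromosome_lengths Named numeric vector of chromosome lengths.
#' @param centromere_midpoints Named numeric vector (same names) of 0-based
#'   centromere midpoints.
#' @param span Region width in bp (default 4 Mb).
#' @return List with elements `centromere` and `telomere`, each a data frame
#'   `chrom`, `start`, `end` (0-based half-open) with a `name` attribute.
#' @export
build_regions <- function(chromosome_lengths, centromere_midpoints,
                          span = 4e6) {
  if (any(span > chromosome_lengths))
    stop("span exceeds a chromosome length")
  cen <- do.call(rbind, lapply(names(chromosome_lengths), function(ch) {
    len <- chromosome_lengths[[ch]]
    mid <- centromere_midpoints[[ch]]
    start <- max(0, mid - span / 2)
    end <- min(len, mid + span / 2)
    data.frame(chrom = ch, start = start, end = end)
  }))
  tel <- do.call(rbind, lapply(names(chromosome_lengths), function(ch) {
    len <- chromosome_lengths[[ch]]
    data.frame(chrom = ch, start = c(0, len - span), end = c(span, len))
  }))
  for (i in seq_len(nrow(cen))) {
    t_i <- tel[tel$chrom == cen$chrom[i], ]
    if (any(cen$start[i] < t_i$end & t_i$start < cen$end[i]))
      warning("centromere and telomere regions overlap on ", cen$chrom[i])
  }
  list(centromere = structure(cen, name = "centromere"),
       telomere = structure(tel, name = "telomere"))
}

#' Read a BED file as a region data frame
#' @param path BED path (chrom, start, end; 0-based half-open already).
#' @return Data frame `chrom`, `start`, `end`.
#' @export
read_regions_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = c("character", "numeric", "numeric"))
  stats::setNames(d[, 1:3], c("chrom", "start", "end"))
}

#' Read a locus-to-domain assignment table
#' @param path TSV with columns `locus_id` and `domain_name` (header
#'   optional).
#' @return Data frame with those two columns.
#' @export
read_domain_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character")
  if (identical(tolower(d[1, 1]), "locus_id")) d <- d[-1, , drop = FALSE]
  rownames(d) <- NULL
  stats::setNames(d[, 1:2], c("locus_id", "domain_name"))
}

# Membership of a genome point (e.g. a gene's CDS start) in a region set.
.in_regions <- function(chrom, pos, regions) {
  vapply(seq_along(chrom), function(i) {
    any(regions$chrom == chrom[i] & regions$start <= pos[i] &
          pos[i] < regions$end)
  }, logical(1))
}
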