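# Synthetic reference genomes, gene models and accession variant sets with
# planted disruptions and an exact truth table.  One master seed drives all
# randomness; sub-stages derive child seeds deterministically.

#' Simulation parameters
#'
#' Defines the study conditions emulated by the generator: a small
#' multi-chromosome genome, intron/exon gene models of varying density,
#' per-accession homozygous variants with a neutral-like frequency
#' spectrum, and disruptive mutations planted at controlled per-gene rates.
#'
#' @param seed Master seed; all randomness derives from it.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length_bp Length of each chromosome (bp).
#' @param n_genes Total genes to place.
#' @param density_profile `"uniform"` or `"centromere_dip"` (gene placement
#'   probability reduced to one fifth within the central 30% of each
#'   chromosome, mimicking pericentromeric gene deserts).
#' @param n_accessions Number of accessions.
#' @param per_gene_disruption_prob Probability a gene carries a planted
#'   disruption, or a function of local gene density (genes per window)
#'   returning that probability.
#' @param frameshift_fraction Fraction of planted disruptions that are
#'   frame-disrupting indels (the rest are nonsense SNVs).
#' @param allele_frequency_model `"singleton"` (every planted disruption in
#'   exactly one accession) or `"neutral_sfs"` (carrier count k drawn with
#'   probability proportional to 1/k, k = 1..n_accessions - 1).
#' @param background_snv_rate Per-site per-accession rate of background
#'   SNVs (synonymous-biased inside CDS so planted verdicts stay exact).
#' @param domain_families Data frame `name`, `n_members`, `enrichment`
#'   (multiplier on the disruption probability of member genes), or `NULL`.
#' @param density_window_bp Window used to measure local density for
#'   density-coupled disruption probabilities.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(seed = 1L, n_chromosomes = 2L,
                       chromosome_length_bp = 1e6, n_genes = 200L,
                       density_profile = c("uniform", "centromere_dip"),
                       n_accessions = 20L,
                       per_gene_disruption_prob = 0.25,
                       frameshift_fraction = 0.55,
                       allele_frequency_model = c("neutral_sfs", "singleton"),
                       background_snv_rate = 0,
                       domain_families = NULL,
                       density_window_bp = 1e6) {
  density_profile <- match.arg(density_profile)
  allele_frequency_model <- match.arg(allele_frequency_model)
  stopifnot(frameshift_fraction >= 0, frameshift_fraction <= 1,
            background_snv_rate >= 0)
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 chromosome_length_bp = chromosome_length_bp,
                 n_genes = n_genes, density_profile = density_profile,
                 n_accessions = n_accessions,
                 per_gene_disruption_prob = per_gene_disruption_prob,
                 frameshift_fraction = frameshift_fraction,
                 allele_frequency_model = allele_frequency_model,
                 background_snv_rate = background_snv_rate,
                 domain_families = domain_families,
                 density_window_bp = density_window_bp),
            class = "sim_params")
}

.child_seed <- function(seed, stage) {
  # deterministic, stage-tagged, < 2^31
  (seed * 7919L + stage * 104729L) %% 2000000011L
}

.random_cds <- function(n_codons) {
  sense <- setdiff(
    apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                      c("T", "C", "A", "G"))[, c(1, 2, 3)], 1L, paste,
          collapse = ""),
    c("TAA", "TAG", "TGA"))
  body <- sample(setdiff(sense, "ATG"), n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
}

#' Simulate a reference genome with gene models and a domain table
#'
#' Places non-overlapping multi-exon genes (CDS beginning with ATG, ending
#' in a stop, no internal stop) on random-sequence chromosomes.  Under the
#' `centromere_dip` profile, placement density near the chromosome midpoint
#' is one fifth of the arm density.
#'
#' @param params A [sim_params()].
#' @return List of class `sim_reference`: `genome` (named character vector
#'   of chromosome sequences), `genes` (named list of [gene_model()]),
#'   `domains` (data frame `locus_id`, `domain_name` or NULL),
#'   `chromosome_lengths`, `centromere_midpoints`, `params`.
#' @export
simulate_reference <- function(params) {
  set.seed(.child_seed(params$seed, 1L))
  clen <- params$chromosome_length_bp
  chroms <- paste0("chr", seq_len(params$n_chromosomes))
  genome <- stats::setNames(vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), clen, replace = TRUE,
                 prob = c(0.32, 0.18, 0.18, 0.32)), collapse = ""), ""),
    chroms)

  per_chrom <- diff(round(seq(0, params$n_genes,
                              length.out = params$n_chromosomes + 1L)))
  genes <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    n <- per_chrom[ci]
    placed <- matrix(numeric(0), ncol = 2L)
    tries <- 0L
    while (nrow(placed) < n) {
      tries <- tries + 1L
      if (tries > 60L * n)
        stop("cannot place ", n, " genes without overlap; reduce n_genes")
      n_ex <- sample(1:4, 1L)
      ex_codons <- pmax(10L, stats::rpois(n_ex, 60L))
      introns <- if (n_ex > 1L) sample(80:250, n_ex - 1L, replace = TRUE)
        else integer(0)
      span <- sum(ex_codons) * 3L + sum(introns)
      start <- sample.int(clen - span - 1L, 1L)
      if (params$density_profile == "centromere_dip") {
        mid <- clen / 2
        in_dip <- abs(start - mid) < 0.15 * clen
        if (in_dip && stats::runif(1) > 0.2) next
      }
      end <- start + span
      if (nrow(placed) &&
            any(pmax(placed[, 1L], start - 50) < pmin(placed[, 2L], end + 50)))
        next
      placed <- rbind(placed, c(start, end))
      gid <- gid + 1L
      strand <- sample(c("+", "-"), 1L)
      cds <- .random_cds(sum(ex_codons))
      # carve exon intervals
      starts <- start + c(0, cumsum(ex_codons * 3L + c(introns, 0)))[seq_len(n_ex)]
      ivs <- cbind(starts, starts + ex_codons * 3L)
      locus <- sprintf("SG%d0%04d", ci, gid)
      g <- gene_model(locus_id = locus,
                      transcript_id = paste0(locus, ".1"),
                      chromosome = chroms[ci], strand = strand,
                      cds_intervals = ivs, cds_sequence = cds)
      # write the CDS into the chromosome (strand-aware)
      chrom_chars <- genome[[chroms[ci]]]
      genome_cds <- if (strand == "-") revcomp(cds) else cds
      offset <- 0L
      ivs_tx <- ivs
      pieces <- character(n_ex)
      for (e in seq_len(n_ex)) {
        w <- ivs[e, 2L] - ivs[e, 1L]
        pieces[e] <- substr(genome_cds, offset + 1L, offset + w)
        offset <- offset + w
      }
      for (e in seq_len(n_ex)) {
        substr(chrom_chars, ivs[e, 1L] + 1L, ivs[e, 2L]) <- pieces[e]
      }
      genome[[chroms[ci]]] <- chrom_chars
      genes[[locus]] <- g
    }
  }
  domains <- NULL
  if (!is.null(params$domain_families)) {
    fam <- params$domain_families
    pool <- names(genes)
    rows <- list()
    for (i in seq_len(nrow(fam))) {
      if (fam$n_members[i] > length(pool))
        stop("domain family larger than remaining gene pool")
      members <- sample(pool, fam$n_members[i])
      pool <- setdiff(pool, members)
      rows[[i]] <- data.frame(locus_id = members,
                              domain_name = fam$name[i])
    }
    domains <- do.call(rbind, rows)
  }
  structure(list(genome = genome, genes = genes, domains = domains,
                 chromosome_lengths = stats::setNames(
                   rep(clen, length(chroms)), chroms),
                 centromere_midpoints = stats::setNames(
                   rep(clen / 2, length(chroms)), chroms),
                 params = params),
            class = "sim_reference")
}

.draw_carrier_count <- function(model, n_accessions) {
  if (model == "singleton") return(1L)
  k <- seq_len(n_accessions - 1L)
  sample(k, 1L, prob = 1 / k)
}

# codons one substitution away from a stop, with the substitution
.nonsense_options <- function(codon) {
  stops <- c("TAA", "TAG", "TGA")
  opts <- list()
  for (p in 1:3) for (b in c("A", "C", "G", "T")) {
    if (substr(codon, p, p) == b) next
    mut <- codon
    substr(mut, p, p) <- b
    if (mut %in% stops)
      opts[[length(opts) + 1L]] <- list(offset = p - 1L, base = b)
  }
  opts
}

#' Simulate accession variant sets with planted disruptions
#'
#' For each gene, with the configured probability, plants one disruptive
#' mutation — a frame-disrupting indel (length 1, 2, 4 or 5) or a nonsense
#' SNV creating an in-frame premature stop — carried by k accessions drawn
#' from the allele-frequency model.  Background SNVs are synonymous inside
#' CDS (third positions) and free elsewhere, so the truth table stays an
#' exact oracle for the caller.
#'
#' @param params A [sim_params()].
#' @param reference Output of [simulate_reference()].
#' @return List of class `sim_variants`: `variant_sets` (accession ->
#'   variant data frame), `truth` (data frame `locus`, `accession`, `kind`,
#'   `cds_pos`), `params`.
#' @export
simulate_variants <- function(params, reference) {
  set.seed(.child_seed(params$seed, 2L))
  genes <- reference$genes
  accs <- sprintf("acc%03d", seq_len(params$n_accessions))
  sets <- stats::setNames(replicate(length(accs), list(), simplify = FALSE),
                          accs)
  truth <- list()

  # local density per gene (genes per window at the gene's CDS start)
  starts <- vapply(genes, function(g) gene_span(g)[1L], 0)
  chrom <- vapply(genes, function(g) g$chromosome, "")
  win <- floor(starts / params$density_window_bp)
  density <- as.numeric(table(paste(chrom, win))[paste(chrom, win)])
  names(density) <- names(genes)

  enrich <- stats::setNames(rep(1, length(genes)), names(genes))
  if (!is.null(reference$domains) && !is.null(params$domain_families)) {
    fam <- params$domain_families
    for (i in seq_len(nrow(fam))) {
      members <- reference$domains$locus_id[
        reference$domains$domain_name == fam$name[i]]
      enrich[members] <- fam$enrichment[i]
    }
  }

  for (locus in names(genes)) {
    g <- genes[[locus]]
    p <- params$per_gene_disruption_prob
    if (is.function(p)) p <- p(density[[locus]])
    p <- min(1, p * enrich[[locus]])
    if (stats::runif(1) >= p) next
    L <- nchar(g$cds_sequence)
    is_fs <- stats::runif(1) < params$frameshift_fraction
    if (is_fs) {
      len <- sample(c(1L, 2L, 4L, 5L), 1L)
      ins <- stats::runif(1) < 0.5
      # pick a CDS offset whose exon can host the event away from edges
      iv <- g$cds_intervals
      widths <- iv[, 2L] - iv[, 1L]
      ok <- which(widths >= len + 4L)
      e <- if (length(ok) == 1L) ok else sample(ok, 1L)
      gpos <- iv[e, 1L] + sample.int(widths[e] - len - 2L, 1L)  # interior
      if (ins) {
        alt <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
        rec <- data.frame(chrom = g$chromosome, pos = gpos, ref = "",
                          alt = alt, vclass = "insertion")
        cpos <- if (g$strand == "+") genome_to_cds(g, gpos)
          else genome_to_cds(g, gpos - 1)
      } else {
        ref <- substr(reference$genome[[g$chromosome]], gpos + 1L,
                      gpos + len)
        rec <- data.frame(chrom = g$chromosome, pos = gpos, ref = ref,
                          alt = "", vclass = "deletion")
        cpos <- if (g$strand == "+") genome_to_cds(g, gpos)
          else genome_to_cds(g, gpos + len - 1L)
      }
      kind <- "frameshift"
    } else {
      codons <- substring(g$cds_sequence, seq(1L, L - 2L, 3L),
                          seq(3L, L, 3L))
      interior <- seq_len(L / 3L - 2L)[-1L]       # skip start, keep < terminal
      cand <- interior[vapply(interior, function(i)
        length(.nonsense_options(codons[i])) > 0L, logical(1))]
      if (!length(cand)) next                     # no mutable codon; skip gene
      ci <- if (length(cand) == 1L) cand else sample(cand, 1L)
      opt <- .nonsense_options(codons[ci])
      opt <- opt[[sample.int(length(opt), 1L)]]
      gpos <- cds_to_genome(g, (ci - 1L) * 3L + opt$offset)
      cpos <- (ci - 1L) * 3L          # event convention: stop-codon start
      alt_tx <- opt$base
      ref_g <- substr(reference$genome[[g$chromosome]], gpos + 1L, gpos + 1L)
      alt_g <- if (g$strand == "-") unname(.COMPLEMENT[alt_tx]) else alt_tx
      rec <- data.frame(chrom = g$chromosome, pos = gpos, ref = ref_g,
                        alt = alt_g, vclass = "snv")
      kind <- "premature_stop"
    }
    kcar <- .draw_carrier_count(params$allele_frequency_model,
                                params$n_accessions)
    carriers <- sample(accs, kcar)
    rec$planted <- TRUE
    for (acc in carriers) {
      sets[[acc]][[length(sets[[acc]]) + 1L]] <- rec
      truth[[length(truth) + 1L]] <- data.frame(
        locus = locus, accession = acc, kind = kind, cds_pos = cpos)
    }
  }

  # background SNVs (synonymous-biased: restricted to third codon
  # positions with a synonymous alternative inside CDS)
  if (params$background_snv_rate > 0) {
    glen <- sum(reference$chromosome_lengths)
    cds_index <- lapply(genes, function(g) g$cds_intervals)
    for (acc in accs) {
      n_bg <- stats::rpois(1L, params$background_snv_rate * glen)
      for (i in seq_len(n_bg)) {
        ch <- sample(names(reference$chromosome_lengths), 1L)
        gpos <- sample.int(reference$chromosome_lengths[[ch]], 1L) - 1L
        hit <- NULL
        for (locus in names(genes)) {
          g <- genes[[locus]]
          if (g$chromosome != ch) next
          if (!is.na(genome_to_cds(g, gpos))) { hit <- g; break }
        }
        ref_g <- substr(reference$genome[[ch]], gpos + 1L, gpos + 1L)
        if (is.null(hit)) {
          alt_g <- sample(setdiff(c("A", "C", "G", "T"), ref_g), 1L)
        } else {
          cpos <- genome_to_cds(hit, gpos)
          if (cpos %% 3L != 2L) next               # only third positions
          codon <- substr(hit$cds_sequence, cpos - 1L, cpos + 1L)
          aa <- translate_cds(codon)
          syn <- Filter(function(b) {
            mut <- codon; substr(mut, 3L, 3L) <- b
            !identical(mut, codon) && identical(translate_cds(mut), aa)
          }, c("A", "C", "G", "T"))
          if (!length(syn)) next
          alt_tx <- if (length(syn) == 1L) syn[[1L]] else sample(unlist(syn), 1L)
          alt_g <- if (hit$strand == "-") unname(.COMPLEMENT[alt_tx]) else alt_tx
        }
        sets[[acc]][[length(sets[[acc]]) + 1L]] <- data.frame(
          chrom = ch, pos = gpos, ref = ref_g, alt = alt_g,
          vclass = "snv", planted = FALSE)
      }
    }
  }

  variant_sets <- lapply(accs, function(acc) {
    recs <- sets[[acc]]
    if (!length(recs)) return(.empty_variants())
    d <- do.call(rbind, recs)
    # planted records take priority over colliding background SNVs
    d <- d[order(d$chrom, d$pos, !d$planted), , drop = FALSE]
    keep <- rep(TRUE, nrow(d))
    by <- split(seq_len(nrow(d)), d$chrom)
    for (ix in by) {
      if (length(ix) < 2L) next
      pos <- d$pos[ix]
      ends <- pos + pmax(1L, nchar(d$ref[ix]))
      planted <- d$planted[ix]
      kept_end <- -Inf
      for (j in seq_along(ix)) {
        if (pos[j] < kept_end && !planted[j]) {
          keep[ix[j]] <- FALSE
        } else if (pos[j] < kept_end && planted[j]) {
          # background record admitted first; evict it
          prev <- ix[seq_len(j - 1L)]
          clash <- prev[keep[prev] & d$pos[prev] +
                          pmax(1L, nchar(d$ref[prev])) > pos[j]]
          keep[clash[!d$planted[clash]]] <- FALSE
          kept_end <- max(kept_end, ends[j])
        } else {
          kept_end <- max(kept_end, ends[j])
        }
      }
    }
    d <- d[keep, c("chrom", "pos", "ref", "alt", "vclass"), drop = FALSE]
    rownames(d) <- NULL
    d
  })
  names(variant_sets) <- accs
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(locus = character(), accession = character(),
               kind = character(), cds_pos = numeric())
  structure(list(variant_sets = variant_sets, truth = truth,
                 params = params),
            class = "sim_variants")
}

#' Write a simulated reference and variant sets to disk
#'
#' Emits FASTA, GFF3, per-accession TSV variant files, a domain table and
#' the truth table, so the file-based readers can consume a complete
#' synthetic data set.
#'
#' @param reference A `sim_reference`.
#' @param variants A `sim_variants` (optional).
#' @param dir Output directory.
#' @return Invisibly, a named list of written paths.
#' @export
write_simulation <- function(reference, variants = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference$genome), fasta)
  gff <- file.path(dir, "genes.gff3")
  lines <- c("##gff-version 3")
  for (g in reference$genes) {
    span <- gene_span(g)
    lines <- c(lines,
      sprintf("%s\tpsiscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chromosome, span[1L] + 1L, span[2L], g$strand, g$locus_id),
      sprintf("%s\tpsiscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chromosome, span[1L] + 1L, span[2L], g$strand,
              g$transcript_id, g$locus_id),
      sprintf("%s\tpsiscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
              g$chromosome, g$cds_intervals[, 1L] + 1L,
              g$cds_intervals[, 2L], g$strand, g$transcript_id,
              g$transcript_id))
  }
  writeLines(lines, gff)
  out <- list(fasta = fasta, gff3 = gff)
  if (!is.null(reference$domains)) {
    out$domains <- file.path(dir, "domains.tsv")
    utils::write.table(reference$domains, out$domains, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(variants)) {
    out$variants_dir <- file.path(dir, "variants")
    write_variants_tsv(variants$variant_sets, out$variants_dir)
    out$truth <- file.path(dir, "truth.tsv")
    utils::write.table(variants$truth, out$truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
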