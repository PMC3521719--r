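# Windowed pseudogene/ORF statistics along chromosomes and
# centromere/telomere contrasts of gene features.

#' Per-window gene and pseudogene counts
#'
#' Tiles each chromosome into non-overlapping windows and assigns every
#' gene to the window containing its CDS start (leftmost genome
#' coordinate).  The pseudogene status used is the table's active
#' criterion.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param table A `psi_table`.
#' @param chromosome_lengths Named numeric vector.
#' @param window_bp Window width (default 1 Mb).
#' @param strata Optional named character vector (locus -> `"singleton"` or
#'   `"duplicated"`) from [build_families()] output, enabling the stratified
#'   columns.
#' @return Data frame `chrom`, `start`, `end`, `gene_count`, `psi_count`,
#'   `psi_over_orf` (NA when no genes), plus stratified counts when
#'   `strata` is given.
#' @export
window_stats <- function(genes, table, chromosome_lengths,
                         window_bp = 1e6, strata = NULL) {
  psi <- psi_loci(table)
  rows <- list()
  starts <- vapply(genes, function(g) gene_span(g)[1L], 0)
  chrom <- vapply(genes, function(g) g$chromosome, "")
  ids <- names(genes)
  for (ch in names(chromosome_lengths)) {
    len <- chromosome_lengths[[ch]]
    w_start <- seq(0, len - 1, by = window_bp)
    for (ws in w_start) {
      we <- min(ws + window_bp, len)
      in_w <- chrom == ch & starts >= ws & starts < we
      ids_w <- ids[in_w]
      n <- length(ids_w)
      npsi <- sum(ids_w %in% psi)
      row <- data.frame(chrom = ch, start = ws, end = we, gene_count = n,
                        psi_count = npsi,
                        psi_over_orf = if (n) npsi / n else NA_real_)
      if (!is.null(strata)) {
        for (s in c("singleton", "duplicated")) {
          ids_s <- ids_w[!is.na(strata[ids_w]) & strata[ids_w] == s]
          row[[paste0(s, "_count")]] <- length(ids_s)
          row[[paste0(s, "_psi")]] <- sum(ids_s %in% psi)
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between pseudogene proportion and local gene density
#'
#' Pearson correlation between per-window psi/ORF ratios and gene counts.
#'
#' @param windows Output of [window_stats()].
#' @param stratum `"all"`, `"singleton"` or `"duplicated"` (strata require
#'   `window_stats(..., strata = )`).
#' @return List `r`, `p_value`, `n_windows`; `r` is NA with a message
#'   attribute when either vector has zero variance.
#' @export
density_correlation <- function(windows, stratum = c("all", "singleton",
                                                     "duplicated")) {
  stratum <- match.arg(stratum)
  if (stratum == "all") {
    x <- windows$gene_count
    y <- windows$psi_over_orf
  } else {
    x <- windows[[paste0(stratum, "_count")]]
    y <- ifelse(x > 0, windows[[paste0(stratum, "_psi")]] / x, NA)
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 windows with a defined ratio")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n_windows = length(x),
                note = "zero variance"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n_windows = length(x))
}

.welch_or_na <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L ||
        (stats::sd(a) == 0 && stats::sd(b) == 0))
    return(c(t = NA_real_, p = NA_real_))
  tt <- stats::t.test(a, b)
  c(t = unname(tt$statistic), p = tt$p.value)
}

#' Centromere versus telomere contrasts of pseudogene features
#'
#' Assigns genes to region classes by CDS start and contrasts, for
#' pseudogene and non-pseudogene loci separately, the mean disrupted-allele
#' frequency (k / n accessions over pseudogene loci), CDS length, exon
#' count and GC fraction, with Welch two-sided t-tests between regions.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param table A `psi_table`.
#' @param centromere,telomere Region data frames (`chrom`,`start`,`end`).
#' @return List with `means` (data frame: region x locus class x feature)
#'   and `tests` (data frame of Welch t and P per feature and locus class,
#'   centromere vs telomere), plus `psi_freq` per region.
#' @export
region_compare <- function(genes, table, centromere, telomere) {
  stopifnot(nrow(centromere) > 0, nrow(telomere) > 0)
  psi <- psi_loci(table)
  ids <- names(genes)
  starts <- vapply(genes, function(g) gene_span(g)[1L], 0)
  chrom <- vapply(genes, function(g) g$chromosome, "")
  feats <- t(vapply(genes, gene_features, numeric(3)))
  n_acc <- length(table$accessions)
  region_of <- ifelse(.in_regions(chrom, starts, centromere), "centromere",
                      ifelse(.in_regions(chrom, starts, telomere),
                             "telomere", NA))
  means <- list(); tests <- list(); psi_freq <- list()
  for (cls in c("psi", "non_psi")) {
    in_cls <- if (cls == "psi") ids %in% psi else !(ids %in% psi)
    groups <- lapply(c(centromere = "centromere", telomere = "telomere"),
                     function(rg) which(in_cls & !is.na(region_of) &
                                          region_of == rg))
    for (rg in names(groups)) {
      sel <- groups[[rg]]
      means[[length(means) + 1L]] <- data.frame(
        region = rg, class = cls, n = length(sel),
        mean_cds_length = if (length(sel) >= 2L)
          mean(feats[sel, 1L]) else NA_real_,
        mean_exon_count = if (length(sel) >= 2L)
          mean(feats[sel, 2L]) else NA_real_,
        mean_gc = if (length(sel) >= 2L) mean(feats[sel, 3L]) else NA_real_,
        mean_psi_freq = if (cls == "psi" && length(sel) >= 1L)
          mean(table$k[ids[sel]] / n_acc) else NA_real_)
    }
    for (f in 1:3) {
      w <- .welch_or_na(feats[groups$centromere, f],
                        feats[groups$telomere, f])
      tests[[length(tests) + 1L]] <- data.frame(
        class = cls, feature = colnames(feats)[f], t = w["t"], p = w["p"])
    }
    if (cls == "psi") {
      w <- .welch_or_na(table$k[ids[groups$centromere]] / n_acc,
                        table$k[ids[groups$telomere]] / n_acc)
      tests[[length(tests) + 1L]] <- data.frame(
        class = cls, feature = "psi_freq", t = w["t"], p = w["p"])
    }
  }
  means <- do.call(rbind, means); rownames(means) <- NULL
  tests <- do.call(rbind, tests); rownames(tests) <- NULL
  list(means = means, tests = tests)
}
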