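# Domain-family pseudogene bias: PPD (proportion of pseudogene loci in
# the family), FDA (mean disrupted-allele count over the family's
# pseudogene loci), per-ecotype frequency, and the top-1% partition.

#' Per-domain-family pseudogene statistics
#'
#' One row per domain family: member count, pseudogene-locus count,
#' PPD = psi_count / gene_count, FDA = mean disrupted-allele carrier count
#' over the family's pseudogene loci, and the per-ecotype frequency
#' PPD * FDA / n_accessions.  A locus carrying several domains contributes
#' to each family.  The Pearson correlation between psi_count and
#' gene_count across families is attached as attribute `r_psi_vs_size`.
#'
#' @param domain_table Data frame `locus_id`, `domain_name`.
#' @param table A `psi_table`.
#' @param n_accessions Number of accessions (defaults to the table's).
#' @return Data frame of class `domain_family_stats`.
#' @export
family_psi_stats <- function(domain_table, table,
                             n_accessions = length(table$accessions)) {
  missing_loci <- setdiff(domain_table$locus_id, table$loci)
  if (length(missing_loci))
    stop("domain table loci absent from the gene set: ",
         paste(utils::head(missing_loci, 3L), collapse = ", "))
  psi <- psi_loci(table)
  rows <- lapply(split(domain_table$locus_id, domain_table$domain_name),
                 function(members) {
    members <- unique(members)
    pm <- intersect(members, psi)
    fda <- if (length(pm)) mean(table$k[pm]) else NA_real_
    ppd <- length(pm) / length(members)
    data.frame(gene_count = length(members), psi_count = length(pm),
               ppd = ppd, fda = fda,
               per_ecotype_freq = if (is.na(fda)) NA_real_ else
                 ppd * fda / n_accessions)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(domain_name = names(rows), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  r <- if (nrow(out) >= 3L && stats::sd(out$gene_count) > 0 &&
             stats::sd(out$psi_count) > 0)
    stats::cor(out$psi_count, out$gene_count) else NA_real_
  structure(out, r_psi_vs_size = r, n_accessions = n_accessions,
            class = c("domain_family_stats", "data.frame"))
}

#' Arithmetic of one domain-family row
#'
#' Computes PPD and the per-ecotype pseudogene frequency from a family's
#' pseudogene-locus count, member count and FDA.
#'
#' @param psi_count Pseudogene loci in the family.
#' @param gene_count Family members in the reference.
#' @param fda Mean disrupted-allele carrier count over the family's
#'   pseudogene loci.
#' @param n_accessions Panel size.
#' @return Named numeric vector `ppd`, `fda`, `per_ecotype_freq`.
#' @export
domain_family_row <- function(psi_count, gene_count, fda, n_accessions) {
  ppd <- psi_count / gene_count
  c(ppd = ppd, fda = fda, per_ecotype_freq = ppd * fda / n_accessions)
}

#' Top-quantile partition of domain families into regions I-IV
#'
#' Cutoffs are the empirical `quantile` order statistics of PPD and FDA
#' across families (linear interpolation; ties included by `>=`).
#' Region I: both parameters at or above their cutoff; region II: FDA
#' only; region III: PPD only; region IV: neither.  Families without a
#' defined FDA are treated as FDA = 0.
#'
#' @param stats A `domain_family_stats` data frame.
#' @param quantile Cutoff quantile (default 0.99, the top 1%).
#' @return List `ppd_cutoff`, `fda_cutoff`, `region` (named factor
#'   I/II/III/IV per family), `counts`.
#' @export
partition_regions <- function(stats, quantile = 0.99) {
  if (nrow(stats) < 2L) stop("need at least 2 families")
  fda <- ifelse(is.na(stats$fda), 0, stats$fda)
  ppd_cut <- stats::quantile(stats$ppd, quantile, names = FALSE)
  fda_cut <- stats::quantile(fda, quantile, names = FALSE)
  hi_ppd <- stats$ppd >= ppd_cut
  hi_fda <- fda >= fda_cut
  region <- factor(ifelse(hi_ppd & hi_fda, "I",
                          ifelse(hi_fda, "II",
                                 ifelse(hi_ppd, "III", "IV"))),
                   levels = c("I", "II", "III", "IV"))
  names(region) <- stats$domain_name
  list(ppd_cutoff = ppd_cut, fda_cutoff = fda_cut, region = region,
       counts = table(region))
}

#' Shared-pseudogene randomization test restricted to a gene subset
#'
#' Runs the same equal-probability randomization engine as
#' [shared_null()], but over the loci of a family subset only: each
#' accession redraws its observed subset pseudogene count from the subset
#' universe.
#'
#' @param table A `psi_table`.
#' @param subset_loci Loci forming the subset universe.
#' @param reps Randomization replicates.
#' @param seed RNG seed.
#' @param denom Shared-proportion denominator (see [shared_null()]).
#' @return A `shared_stats` object (observed and null restricted to the
#'   subset).
#' @export
shared_psi_functional_test <- function(table, subset_loci, reps = 1000L,
                                       seed = 1L,
                                       denom = c("jaccard", "mean_size")) {
  denom <- match.arg(denom)
  if (reps < 1L) stop("reps must be >= 1")
  if (!length(subset_loci)) stop("empty subset")
  sub <- table
  sub$loci <- intersect(table$loci, subset_loci)
  sub$calls <- table$calls[table$calls$locus %in% sub$loci, , drop = FALSE]
  sub$k <- table$k[sub$loci]
  counts <- per_accession_counts(sub)$counts
  if (any(counts > length(sub$loci)))
    stop("an accession's subset count exceeds the subset size")
  shared_null(sub, counts = counts, n_genes = length(sub$loci),
              reps = reps, seed = seed, denom = denom)
}
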