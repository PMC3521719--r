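# Pseudogene clusters along chromosomes and sequence-similarity gene
# families (internal aligner with a k-mer prefilter in place of an
# external BLASTN/ClustalW2 step).

#' Pseudogene clusters and singletons
#'
#' Two pseudogene loci on the same chromosome join a cluster when at most
#' `max_intervening_genes` genes (of any status) lie between them
#' ("separated by less than ten genes"); clusters are maximal chains and
#' never span chromosomes.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param psi Character vector of pseudogene locus ids.
#' @param max_intervening_genes Maximum intervening gene count (default 9).
#' @return List with `clusters` (list of character vectors, each a cluster
#'   of >= 2 loci) and `singletons` (character vector), plus `stratum`
#'   (named vector locus -> `"clustered"`/`"singleton"` over psi loci).
#' @export
find_clusters <- function(genes, psi, max_intervening_genes = 9L) {
  stopifnot(max_intervening_genes >= 0L)
  starts <- vapply(genes, function(g) gene_span(g)[1L], 0)
  chrom <- vapply(genes, function(g) g$chromosome, "")
  clusters <- list()
  singles <- character()
  for (ch in unique(chrom)) {
    ids <- names(genes)[chrom == ch]
    ids <- ids[order(starts[ids])]
    pos <- which(ids %in% psi)
    if (!length(pos)) next
    gaps <- diff(pos) - 1L               # intervening genes
    brk <- c(0L, which(gaps > max_intervening_genes), length(pos))
    for (i in seq_len(length(brk) - 1L)) {
      members <- ids[pos[(brk[i] + 1L):brk[i + 1L]]]
      if (length(members) >= 2L)
        clusters[[length(clusters) + 1L]] <- members
      else singles <- c(singles, members)
    }
  }
  stratum <- stats::setNames(rep("singleton", length(psi)), psi)
  for (cl in clusters) stratum[cl] <- "clustered"
  list(clusters = clusters, singletons = singles, stratum = stratum)
}

#' Pairwise local-alignment identity and coverage
#'
#' Local alignment with affine gaps (match +1, mismatch -2, gap open -5,
#' extend -2).  Identity is matches over aligned columns excluding gap
#' columns; coverage is the aligned span over the length of the shorter
#' sequence (capped at 1).  Strand is not searched.
#'
#' @param cds_a,cds_b Nucleotide strings.
#' @return Named numeric vector `identity`, `coverage`.
#' @export
pairwise_identity <- function(cds_a, cds_b) {
  if (!nchar(cds_a) || !nchar(cds_b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(cds_a), Biostrings::DNAString(cds_b),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2),
    gapOpening = 5, gapExtension = 2)
  matches <- Biostrings::nmatch(aln)
  mismatches <- Biostrings::nmismatch(aln)
  columns <- nchar(as.character(Biostrings::pattern(aln)))
  ident <- if (matches + mismatches == 0) 0 else
    matches / (matches + mismatches)
  cov <- min(1, columns / min(nchar(cds_a), nchar(cds_b)))
  c(identity = ident, coverage = cov)
}

.kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Sequence-similarity gene families
#'
#' Candidate pairs from a shared-k-mer prefilter are aligned with
#' [pairwise_identity()]; pairs passing both the identity and coverage
#' thresholds become edges and families are the connected components
#' (single linkage).  The family identity is the maximum pairwise identity
#' among members; a gene with no qualifying hit is a singleton.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param min_identity Minimum identity (default 0.70).
#' @param min_coverage Minimum coverage of the shorter sequence (default
#'   0.50).
#' @param kmer_k Prefilter k-mer size (default 11).
#' @param min_shared_kmers Minimum shared k-mers for a candidate pair
#'   (default 3).
#' @param use_prefilter `TRUE`, `FALSE`, or `"auto"` (prefilter whenever
#'   more than 20 genes; smaller inputs are aligned all-against-all).
#' @return List with `families` (data frame `family_id`, `locus_id`,
#'   `family_size`, `family_identity`, `singleton`) and `stratum` (named
#'   vector locus -> `"singleton"`/`"duplicated"`).
#' @export
build_families <- function(genes, min_identity = 0.70, min_coverage = 0.50,
                           kmer_k = 11L, min_shared_kmers = 3L,
                           use_prefilter = "auto") {
  stopifnot(length(genes) >= 1L)
  ids <- names(genes)
  seqs <- vapply(genes, function(g) g$cds_sequence, "")
  n <- length(ids)
  if (identical(use_prefilter, "auto")) use_prefilter <- n > 20L
  pairs <- NULL
  if (n >= 2L) {
    all_pairs <- utils::combn(n, 2L)
    if (use_prefilter) {
      km <- lapply(seqs, .kmer_set, k = kmer_k)
      keep <- vapply(seq_len(ncol(all_pairs)), function(j) {
        i1 <- all_pairs[1L, j]; i2 <- all_pairs[2L, j]
        length(intersect(km[[i1]], km[[i2]])) >= min_shared_kmers
      }, logical(1))
      pairs <- all_pairs[, keep, drop = FALSE]
    } else pairs <- all_pairs
  }
  edges <- integer(0)
  edge_ident <- numeric(0)
  if (!is.null(pairs) && ncol(pairs)) {
    for (j in seq_len(ncol(pairs))) {
      pc <- pairwise_identity(seqs[[pairs[1L, j]]], seqs[[pairs[2L, j]]])
      if (pc["identity"] >= min_identity && pc["coverage"] >= min_coverage) {
        edges <- c(edges, pairs[1L, j], pairs[2L, j])
        edge_ident <- c(edge_ident, pc["identity"])
      }
    }
  }
  gr <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) gr <- igraph::add_edges(gr, edges)
  comp <- igraph::components(gr)$membership
  fam_identity <- vapply(seq_len(max(comp)), function(f) {
    e_in <- which(comp[edges[c(TRUE, FALSE)]] == f)
    if (!length(e_in)) NA_real_ else max(edge_ident[e_in])
  }, 0)
  sizes <- as.integer(table(comp))
  families <- data.frame(
    family_id = sprintf("FAM%04d", comp),
    locus_id = ids,
    family_size = sizes[comp],
    family_identity = fam_identity[comp],
    singleton = sizes[comp] == 1L,
    stringsAsFactors = FALSE)
  families <- families[order(families$family_id, families$locus_id), ]
  rownames(families) <- NULL
  stratum <- stats::setNames(
    ifelse(families$singleton, "singleton", "duplicated"),
    families$locus_id)
  list(families = families, stratum = stratum)
}
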