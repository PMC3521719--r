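# Presence/absence matrix over pseudogene loci and a neighbor-joining
# tree on Hamming distances, emitted as Newick.

#' Pseudogene presence/absence matrix
#'
#' Accessions x pseudogene loci, with 1 for an intact (non-pseudogene)
#' allele and 0 for a disrupted one; columns sorted by locus id.
#'
#' @param table A `psi_table` with >= 2 accessions.
#' @return Binary integer matrix (rownames accessions, colnames loci).
#' @export
presence_matrix <- function(table) {
  if (length(table$accessions) < 2L) stop("need at least 2 accessions")
  loci <- sort(psi_loci(table))
  m <- matrix(1L, nrow = length(table$accessions), ncol = length(loci),
              dimnames = list(table$accessions, loci))
  calls <- table$calls[table$calls$locus %in% loci, , drop = FALSE]
  m[cbind(calls$accession, calls$locus)] <- 0L
  m
}

#' Hamming-proportion distance matrix
#' @param m Binary matrix, rows = taxa.
#' @return Symmetric matrix of per-column mismatch proportions.
#' @export
hamming_distance <- function(m) {
  d <- as.matrix(stats::dist(m, method = "manhattan")) / ncol(m)
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

# move a negative branch length onto its sister branch (standard NJ
# post-processing), then clamp at zero
.clamp_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1L]
    parent <- tree$edge[e, 1L]
    sisters <- setdiff(which(tree$edge[, 1L] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sisters))
      tree$edge.length[sisters] <- tree$edge.length[sisters] + deficit
    tree$edge.length[tree$edge.length < 0 & abs(tree$edge.length) < 1e-12] <- 0
    if (all(tree$edge.length >= 0)) break
    # avoid cycling: clamp any residual negatives outright
    if (any(tree$edge.length[sisters] < 0)) {
      tree$edge.length[tree$edge.length < 0] <- 0
      break
    }
  }
  tree
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining (via [ape::nj()]); negative
#' branch lengths are clamped to zero with the deficit moved to the sister
#' branch.  The unrooted tree is serialized as Newick with branch lengths.
#'
#' @param distance_matrix Symmetric matrix with taxon dimnames (>= 3
#'   taxa).
#' @return List `tree` (an `ape::phylo`) and `newick` (string).
#' @export
nj_tree <- function(distance_matrix) {
  if (nrow(distance_matrix) < 3L) stop("need at least 3 taxa")
  tree <- ape::nj(stats::as.dist(distance_matrix))
  tree <- .clamp_negative_edges(tree)
  list(tree = tree, newick = ape::write.tree(tree))
}
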