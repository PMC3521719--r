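# Cluster chains along chromosomes and similarity families.

spaced_genes <- function(n, chrom = "c1", gap = 500) {
  genes <- list()
  for (i in seq_len(n)) {
    id <- sprintf("G%03d", i)
    start <- i * gap
    genes[[id]] <- gene_model(id, paste0(id, ".1"), chrom, "+",
                              rbind(c(start, start + 21)),
                              "ATGAAACCCGGGTTTTGGTAA")
  }
  genes
}

test_that("cluster rule: less than ten intervening genes joins loci", {
  genes <- spaced_genes(30)
  ids <- names(genes)
  # 9 intervening genes (positions 1 and 11) -> one cluster
  cl <- find_clusters(genes, psi = ids[c(1, 11)])
  expect_length(cl$clusters, 1L)
  expect_equal(sort(cl$clusters[[1]]), ids[c(1, 11)])
  # 10 intervening genes -> two singletons
  cl2 <- find_clusters(genes, psi = ids[c(1, 12)])
  expect_length(cl2$clusters, 0L)
  expect_equal(sort(cl2$singletons), ids[c(1, 12)])
  # single locus is a singleton
  cl3 <- find_clusters(genes, psi = ids[5])
  expect_equal(cl3$singletons, ids[5])
  # chains are maximal
  cl4 <- find_clusters(genes, psi = ids[c(1, 8, 15, 30)])
  expect_length(cl4$clusters, 1L)
  expect_equal(sort(cl4$clusters[[1]]), ids[c(1, 8, 15)])
})

test_that("clusters never span chromosomes and survive order reversal", {
  g1 <- spaced_genes(6, chrom = "c1")
  g2 <- spaced_genes(6, chrom = "c2")
  names(g2) <- sub("G", "H", names(g2))
  for (i in seq_along(g2)) g2[[i]]$locus_id <- names(g2)[i]
  genes <- c(g1, g2)
  cl <- find_clusters(genes, psi = c("G006", "H001"))
  expect_length(cl$clusters, 0L)
  # reversing the input order changes nothing
  cl_rev <- find_clusters(rev(genes), psi = c("G006", "H001"))
  expect_equal(sort(cl_rev$singletons), sort(cl$singletons))
})

test_that("pairwise identity and coverage behave on controlled pairs", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
             collapse = "")
  expect_equal(unname(pairwise_identity(s, s)), c(1, 1))
  # reverse complement is not searched
  rc <- psiscan:::revcomp(s)
  expect_lt(pairwise_identity(s, rc)["identity"] *
              pairwise_identity(s, rc)["coverage"], 0.7)
  # 30 substitutions in 300 bp -> identity about 0.90
  chars <- strsplit(s, "")[[1]]
  idx <- sample(300, 30)
  chars[idx] <- vapply(chars[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  mut <- paste(chars, collapse = "")
  pid <- pairwise_identity(s, mut)
  expect_equal(unname(pid["identity"]), 0.90, tolerance = 0.03)
  expect_error(pairwise_identity("", s), "empty")
})

test_that("local alignment identity matches a full-DP oracle on 30-mers", {
  # brute-force Needleman-Wunsch style local DP (Smith-Waterman),
  # match 1 / mismatch -2 / linear-ish gap handled as open 5 extend 2
  sw_oracle <- function(a, b) {
    A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    M <- matrix(0, n + 1, m + 1)   # best score ending in match/mismatch
    X <- matrix(-Inf, n + 1, m + 1) # gap in b
    Y <- matrix(-Inf, n + 1, m + 1) # gap in a
    best <- 0
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
      sc <- if (A[i - 1] == B[j - 1]) 1 else -2
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + sc
      X[i, j] <- max(M[i - 1, j] - 7, X[i - 1, j] - 2)
      Y[i, j] <- max(M[i, j - 1] - 7, Y[i, j - 1] - 2)
      best <- max(best, M[i, j])
    }
    best
  }
  set.seed(11)
  for (rep in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
    chars <- strsplit(a, "")[[1]]
    idx <- sample(30, 4)
    chars[idx] <- vapply(chars[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    b <- paste(chars, collapse = "")
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2),
      gapOpening = 5, gapExtension = 2)
    expect_equal(Biostrings::score(aln), sw_oracle(a, b))
  }
})

test_that("families form by single linkage with identity and coverage", {
  set.seed(77)
  base <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  mutate <- function(s, k) {
    chars <- strsplit(s, "")[[1]]
    idx <- sample(length(chars), k)
    chars[idx] <- vapply(chars[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(chars, collapse = "")
  }
  mk <- function(id, seq, start) gene_model(
    id, paste0(id, ".1"), "c1", "+", rbind(c(start, start + nchar(seq))),
    seq)
  genes <- list(
    F1a = mk("F1a", base, 1000),
    F1b = mk("F1b", mutate(base, 15), 2000),       # ~95% identity
    F1c = mk("F1c", mutate(base, 15), 3000),
    LON = mk("LON", paste(sample(c("A", "C", "G", "T"), 300,
                                 replace = TRUE), collapse = ""), 4000))
  fam <- build_families(genes)
  fams <- fam$families
  expect_equal(sort(fams$locus_id[!fams$singleton]),
               c("F1a", "F1b", "F1c"))
  expect_true(fams$singleton[fams$locus_id == "LON"])
  expect_equal(unname(fam$stratum["LON"]), "singleton")
  expect_equal(unname(fam$stratum["F1a"]), "duplicated")
  f1 <- fams[fams$locus_id == "F1a", ]
  expect_gte(f1$family_identity, 0.90)
})

test_that("small inputs match the all-pairs construction exactly", {
  set.seed(13)
  mk_seq <- function() paste(sample(c("A", "C", "G", "T"), 60,
                                    replace = TRUE), collapse = "")
  base <- mk_seq()
  seqs <- c(base,
            sub("^(.{10}).", "\\1A", base),
            mk_seq(), mk_seq(), mk_seq(), base)
  genes <- list()
  for (i in seq_along(seqs)) {
    id <- paste0("S", i)
    genes[[id]] <- gene_model(id, paste0(id, ".1"), "c1", "+",
                              rbind(c(i * 100, i * 100 + 60)), seqs[i])
  }
  with_pf <- build_families(genes, use_prefilter = FALSE)
  brute <- {
    n <- length(genes)
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      pc <- pairwise_identity(seqs[i], seqs[j])
      adj[i, j] <- adj[j, i] <- pc["identity"] >= 0.70 &&
        pc["coverage"] >= 0.50
    }
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in 1:n) for (j in 1:n) if (adj[i, j] &&
                                          comp[j] != comp[i]) {
        comp[c(i, j)] <- min(comp[c(i, j)]); changed <- TRUE
      }
      if (!changed) break
    }
    comp
  }
  got <- as.integer(factor(with_pf$families$family_id[
    order(with_pf$families$locus_id)]))
  want <- as.integer(factor(brute))
  # same partition (up to label renaming)
  expect_equal(length(unique(got)), length(unique(want)))
  expect_true(all(outer(got, got, "==") == outer(want, want, "==")))
})
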