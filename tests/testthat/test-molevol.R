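# NG86 site/difference counting, JC correction, diversity, Tajima's D.

# independent translation used by the oracles below (Biostrings genetic
# code, precomputed once for speed)
.AA_MAP <- local({
  b <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  stats::setNames(vapply(all64, function(cd)
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE)), ""), all64)
})
aa_of <- function(codon) unname(.AA_MAP[codon])

sense_codons <- function() {
  setdiff(names(.AA_MAP), c("TAA", "TAG", "TGA"))
}

test_that("site counts match enumeration of all nine single-base changes", {
  # spot-checked worked examples
  expect_equal(unname(ng_site_counts("TTT")["s"]), 1 / 3)
  expect_equal(unname(ng_site_counts("TTA")["s"]), 2 / 3)
  expect_equal(unname(ng_site_counts("ATG")["s"]), 0)
  # full oracle over every sense codon
  worst <- 0
  for (codon in sense_codons()) {
    s_oracle <- 0
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                     substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (!(mut %in% c("TAA", "TAG", "TGA")) &&
            aa_of(mut) == aa_of(codon))
        s_oracle <- s_oracle + 1 / 3
    }
    worst <- max(worst, abs(unname(ng_site_counts(codon)["s"]) - s_oracle))
  }
  expect_lt(worst, 1e-12)
})

test_that("ng_pair reproduces the hand-worked NG86 examples", {
  ex <- ng_pair("TTT", "TTA")
  expect_equal(ex$S, 0.5)
  expect_equal(ex$N, 2.5)
  expect_equal(ex$Sd, 0)
  expect_equal(ex$Nd, 1)
  expect_equal(ex$Ka, -0.75 * log(1 - 4 * 0.4 / 3), tolerance = 1e-12)
  expect_equal(ex$Ks, 0)
  expect_true(is.na(ex$ka_ks))
  ex2 <- ng_pair("GGTGGT", "GGCGGT")
  expect_equal(ex2$S, 2)
  expect_equal(ex2$Sd, 1)
  expect_equal(ex2$Ks, -0.75 * log(1 / 3), tolerance = 1e-12)
  expect_equal(ex2$Ka, 0)
  ident <- ng_pair("ATGAAA", "ATGAAA")
  expect_equal(ident$Ka, 0)
  expect_equal(ident$Ks, 0)
})

test_that("ng_pair is symmetric and conserves sites and differences", {
  set.seed(2)
  codons <- sense_codons()
  for (rep in 1:20) {
    a <- paste(sample(codons, 10, replace = TRUE), collapse = "")
    b <- paste(sample(codons, 10, replace = TRUE), collapse = "")
    ab <- ng_pair(a, b); ba <- ng_pair(b, a)
    expect_equal(ab[c("S", "N", "Sd", "Nd")], ba[c("S", "N", "Sd", "Nd")])
    expect_equal(ab$S + ab$N, 3 * ab$codons_compared)
    # Sd + Nd equals the pathway-averaged number of differing positions
    ca <- substring(a, seq(1, 28, 3), seq(3, 30, 3))
    cb <- substring(b, seq(1, 28, 3), seq(3, 30, 3))
    keep <- !(ca %in% c("TAA", "TAG", "TGA")) &
      !(cb %in% c("TAA", "TAG", "TGA"))
    ndiff <- sum(mapply(function(x, y)
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]), ca[keep],
      cb[keep]))
    expect_equal(ab$Sd + ab$Nd, ndiff)
  }
})

test_that("two-difference codon pairs match exhaustive path enumeration", {
  codons <- sense_codons()
  checked <- 0L
  for (c1 in codons) for (c2 in codons) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(pos) != 2L || c1 >= c2) next
    # oracle: both orderings, skipping stop intermediates
    paths <- list(pos, rev(pos))
    res <- list()
    for (path in paths) {
      cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
      for (p in path) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (nxt %in% c("TAA", "TAG", "TGA")) { ok <- FALSE; break }
        if (aa_of(nxt) == aa_of(cur)) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) res[[length(res) + 1L]] <- c(sd, nd)
    }
    if (!length(res)) next  # both pathways blocked; convention-dependent
    want <- colMeans(do.call(rbind, res))
    got <- ng_pair(c1, c2)
    if (!isTRUE(all.equal(c(got$Sd, got$Nd), unname(want))))
      stop("pathway mismatch for ", c1, "/", c2)
    checked <- checked + 1L
  }
  expect_gt(checked, 500L)
})

test_that("allele sequences apply SNVs and mark deletions", {
  g <- plus_gene()   # ATGAAACCCGGGTTTTGGTAA
  vs <- list(
    acc1 = variant_row("chrT", 13, "A", "G", "snv"),     # CDS 3 A->G
    acc2 = variant_row("chrT", 28, "NN", "", "deletion") # CDS 10,11
  )
  seqs <- allele_sequences(g, vs)
  expect_equal(unname(substr(seqs["acc1"], 4, 4)), "G")
  expect_equal(unname(substr(seqs["acc2"], 11, 12)), "--")
  expect_equal(nchar(seqs), c(acc1 = 21L, acc2 = 21L))
  # minus strand: genome alt complemented into transcript space
  gm <- minus_gene()
  gpos <- cds_to_genome(gm, 3)
  vm <- list(accm = variant_row("chrT", gpos, "T", "C", "snv"))
  sm <- allele_sequences(gm, vm)
  expect_equal(unname(substr(sm["accm"], 4, 4)), "G")
})

test_that("group stats: identical groups give dxy equal to pi", {
  g <- long_gene()
  set.seed(8)
  L <- nchar(g$cds_sequence)
  mk_var <- function(n) {
    cpos <- sample(3:(L - 4), n)
    data.frame(chrom = "chrL", pos = cpos, ref = "N",
               alt = vapply(cpos, function(p)
                 sample(setdiff(c("A", "C", "G", "T"),
                                substr(g$cds_sequence, p + 1, p + 1)), 1),
                 ""),
               vclass = "snv")[order(cpos), ]
  }
  vs <- list(a1 = mk_var(3), a2 = mk_var(3), a3 = mk_var(3),
             a4 = mk_var(3))
  seqs <- allele_sequences(g, vs)
  gs <- group_stats(seqs, c("a1", "a2"), c("a1", "a2"))
  expect_equal(gs$within1$pi, gs$within2$pi)
  # all-synonymous differences -> Ka = 0 in every pair
  syn <- c(a = g$cds_sequence,
           b = paste0("ATGAAG", substr(g$cds_sequence, 7, L)))  # AAA->AAG
  gs2 <- group_stats(syn, c("a", "b"))
  expect_equal(gs2$within1$Ka, 0)
  expect_gt(gs2$within1$Ks, 0)
})

test_that("paired divergence test detects Dxy above pi", {
  set.seed(6)
  pi_w <- runif(20, 0, 0.01)
  dxy <- pi_w + 0.005 + rnorm(20, sd = 0.001)
  ht <- paired_divergence_test(dxy, pi_w)
  expect_lt(ht$p.value, 0.001)
  expect_gt(mean(dxy - pi_w), 0)
  expect_error(paired_divergence_test(1, 2), "2 loci")
})

test_that("representative haplotype is the most frequent disrupted one", {
  seqs <- c(x1 = "AAA", x2 = "AAC", x3 = "AAC", x4 = "AAA", x5 = "AAC")
  rep_car <- pick_representative(seqs, c("x1", "x2", "x3", "x5"))
  expect_equal(sort(rep_car), c("x2", "x3", "x5"))
  expect_error(pick_representative(seqs, character(0)), "disrupted")
})

test_that("Tajima's D reproduces the hand-computed n=4 example", {
  seqs <- c("AAAAAAAAAA", "AAAAAAAAAA", "AAAAAAAAAA", "CCCAAAAAAA")
  td <- tajimas_d(seqs)
  expect_equal(td$S, 3L)
  expect_equal(td$theta_pi, 1.5)
  expect_equal(td$theta_w, 3 / (11 / 6), tolerance = 1e-12)
  expect_equal(td$D, -0.7544, tolerance = 1e-3)
  # no segregating sites -> NaN
  expect_true(is.nan(tajimas_d(rep("ACGT", 4))$D))
  expect_error(tajimas_d(c("AA", "AA", "AA")), "4")
})

test_that("balanced intermediate-frequency variants give positive D", {
  seqs <- c("AAAAA", "AAAAA", "CCCCC", "CCCCC")
  expect_gt(tajimas_d(seqs)$D, 0)
})

test_that("mean Tajima's D is near zero under the neutral coalescent", {
  set.seed(4)
  ds <- vapply(1:200, function(i) {
    m <- sim_neutral_sample(20, theta = 8)
    if (ncol(m) == 0) return(NA_real_)
    tajimas_d(m)$D
  }, 0)
  expect_lt(abs(mean(ds, na.rm = TRUE)), 0.15)
})
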