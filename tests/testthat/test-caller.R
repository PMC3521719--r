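# Disrupted-allele calling: coordinate mapping, the frameshift set rule,
# premature stops, upper-most classification.

test_that("coding_indels maps indels onto the spliced CDS (plus strand)", {
  g <- plus_gene()
  expect_equal(nrow(coding_indels(g, variant_row("chrT", 12, "A", "T",
                                                 "snv"))), 0L)
  # 1-bp insertion inside exon 2 at genome 30 -> CDS 9 + (30-27) = 12
  ins <- coding_indels(g, variant_row("chrT", 30, "", "A", "insertion"))
  expect_equal(ins$cds_position, 12)
  expect_equal(ins$signed_length, 1)
  # 5-bp deletion [24,29): 3 intron bases + coding 27,28 -> -2 at CDS 9
  del <- coding_indels(g, variant_row("chrT", 24, "NNNNN", "", "deletion"))
  expect_equal(del$signed_length, -2)
  expect_equal(del$cds_position, 9)
  # insertion at an exon boundary is not coding
  expect_equal(nrow(coding_indels(
    g, variant_row("chrT", 27, "", "A", "insertion"))), 0L)
})

test_that("coding_indels respects transcript orientation on minus strand", {
  g <- minus_gene()
  # insertion between genome 32|33 in exon [30,39): transcript positions
  # of bases 33 and 32 are 5 and 6 -> first affected CDS offset 6
  ins <- coding_indels(g, variant_row("chrT", 33, "", "AA", "insertion"))
  expect_equal(ins$cds_position, 6)
  expect_equal(ins$signed_length, 2)
  # deletion of genome [31,34): 5'-most deleted base in transcript order
  # is genome 33 -> CDS 5; three coding bases removed
  del <- coding_indels(g, variant_row("chrT", 31, "NNN", "", "deletion"))
  expect_equal(del$cds_position, 5)
  expect_equal(del$signed_length, -3)
})

test_that("deletion spanning the whole gene is a frameshift at 0", {
  g <- plus_gene()
  ind <- coding_indels(g, variant_row("chrT", 5, strrep("N", 40), "",
                                      "deletion"))
  expect_true(attr(ind, "whole_gene_deletion"))
  ev <- detect_frameshift(ind)
  expect_equal(ev$cds_position, 0)
})

test_that("frameshift rule: net length and the 300-bp three-indel set", {
  # single 1-bp insertion: net 1 -> frameshift at its position
  ev <- detect_frameshift(indel_df(42, 1))
  expect_equal(ev$cds_position, 42)
  # three 1-bp deletions, net -3, span 20 <= 300 -> intact
  expect_null(detect_frameshift(indel_df(c(10, 20, 30), c(-1, -1, -1))))
  # same but span 390 > 300 -> frameshift at the first member
  ev <- detect_frameshift(indel_df(c(10, 50, 400), c(-1, -1, -1)))
  expect_equal(ev$cds_position, 10)
  # compensating +1/-1 pair: net 0, fewer than 3 members -> intact
  expect_null(detect_frameshift(indel_df(c(10, 400), c(1, -1))))
  # in-frame indels never disrupt
  expect_null(detect_frameshift(indel_df(c(10, 500), c(3, -6))))
  # four frame-disrupting members (net 6): only one window of three
  # consecutive members needs to exceed the span
  ev <- detect_frameshift(indel_df(c(10, 12, 14, 350), c(1, 1, 2, 2)))
  expect_equal(ev$cds_position, 12)   # window (12,14,350) spans 338
  expect_null(detect_frameshift(indel_df(numeric(), numeric())))
})

test_that("premature stops are found at the stop codon start", {
  g <- long_gene()
  expect_null(detect_premature_stop(g, no_variants()))
  # TGG codon 5 (CDS 12..14), G->A at CDS 14 creates TGA
  ev <- detect_premature_stop(g, variant_row("chrL", 14, "G", "A", "snv"))
  expect_equal(ev$cds_position, 12)
  expect_equal(ev$cds_position / 300, 0.04)
  # a change in the terminal (annotated stop) codon is not a call
  expect_null(detect_premature_stop(
    g, variant_row("chrL", 298, "A", "G", "snv")))
  # synonymous change -> intact
  expect_null(detect_premature_stop(
    g, variant_row("chrL", 5, "A", "G", "snv")))
})

test_that("premature stop detection is strand-aware", {
  g <- minus_gene()  # CDS ATGAAACCCGGGTTTTGGTAA; TGG codon 6 at CDS 15..17
  # third base of TGG is CDS 17 -> genome position on minus strand
  gpos <- cds_to_genome(g, 17)
  # transcript base G -> A makes TGA; genome alt is complement T
  ev <- detect_premature_stop(g, variant_row("chrT", gpos, "C", "T", "snv"))
  expect_equal(ev$cds_position, 15)
})

test_that("brute-force translation oracle agrees on random SNV sets", {
  set.seed(99)
  sim <- small_sim(seed = 31)
  genes <- sim$ref$genes[1:15]
  for (g in genes) {
    L <- nchar(g$cds_sequence)
    # random SNVs at 5 coding positions
    cpos <- sample(0:(L - 1), 5)
    gpos <- cds_to_genome(g, cpos)
    ref_tx <- substring(g$cds_sequence, cpos + 1, cpos + 1)
    alt_tx <- vapply(ref_tx, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    ref_g <- if (g$strand == "-")
      unname(psiscan:::.COMPLEMENT[ref_tx]) else ref_tx
    alt_g <- if (g$strand == "-")
      unname(psiscan:::.COMPLEMENT[alt_tx]) else alt_tx
    v <- data.frame(chrom = g$chromosome, pos = gpos, ref = ref_g,
                    alt = alt_g, vclass = "snv")
    v <- v[order(v$pos), ]
    ev <- detect_premature_stop(g, v)
    # oracle: mutate, translate with Biostrings, first internal stop
    s <- strsplit(g$cds_sequence, "")[[1]]
    s[cpos + 1] <- alt_tx
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(paste(s, collapse = "")))), "")[[1]]
    internal <- which(aa[-length(aa)] == "*")
    if (length(internal)) {
      expect_equal(ev$cds_position, (internal[1] - 1) * 3)
    } else {
      expect_null(ev)
    }
  }
})

test_that("the upper-most disruptive mutation classifies the allele", {
  g <- long_gene()
  # nonsense at CDS 12 (codon 5) plus 1-bp insertion at CDS ~50
  v <- rbind(variant_row("chrL", 14, "G", "A", "snv"),
             variant_row("chrL", 50, "", "T", "insertion"))
  res <- call_allele(g, v)
  expect_equal(res$verdict, "disrupted")
  expect_equal(nrow(res$events), 2L)
  expect_equal(res$primary_event$kind, "premature_stop")
  expect_equal(res$primary_event$cds_position, 12)
  # frameshift upstream of the stop wins
  v2 <- rbind(variant_row("chrL", 14, "G", "A", "snv"),
              variant_row("chrL", 5, "", "T", "insertion"))
  res2 <- call_allele(g, v2)
  expect_equal(res2$primary_event$kind, "frameshift")
  expect_equal(res2$primary_event$cds_position, 5)
  expect_equal(call_allele(g, no_variants())$verdict, "intact")
})

test_that("criterion sets are nested and bins count loci per accession", {
  sim <- small_sim(seed = 13)
  tbl <- call_loci(sim$ref$genes, sim$variants$variant_sets)
  s1 <- psi_loci(tbl, "first_third")
  s2 <- psi_loci(tbl, "first_two_thirds")
  s3 <- psi_loci(tbl, "whole_orf")
  expect_true(all(s1 %in% s2))
  expect_true(all(s2 %in% s3))
  # bins overlap across accessions, so bin counts can exceed the total
  expect_true(sum(tbl$bin_counts) >= length(s3))
  # a locus disrupted early in one accession and late in another counts
  # in both bins
  calls <- tbl$calls
  multi <- calls[calls$locus %in% names(which(table(calls$locus) > 1)), ]
  if (nrow(multi)) {
    expect_true(all(multi$bin %in% c("0-1/3", "1/3-2/3", "2/3-1")))
  }
})

test_that("calling the reference against itself yields no pseudogenes", {
  sim <- small_sim(seed = 17)
  empty <- stats::setNames(
    replicate(3, no_variants(), simplify = FALSE),
    c("ref1", "ref2", "ref3"))
  tbl <- call_loci(sim$ref$genes, empty)
  expect_equal(nrow(tbl$calls), 0L)
  expect_equal(sum(tbl$psi$whole_orf), 0L)
})

test_that("relative-position ties at bin edges fall in the lower bin", {
  expect_equal(psiscan:::.bin_of(c(0, 1 / 3, 1 / 3 + 1e-9, 2 / 3, 0.99)),
               c("0-1/3", "0-1/3", "1/3-2/3", "1/3-2/3", "2/3-1"))
})
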