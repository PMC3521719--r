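# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction, nucleotide
# diversity, between-group divergence and Tajima's D.

.STOPS <- c("TAA", "TAG", "TGA")
.NUC <- c("A", "C", "G", "T")

.codon_aa <- function(codon) translate_cds(codon)

# memo caches: per-codon site counts and per-codon-pair pathway diffs
.ng_cache <- new.env(parent = emptyenv())

#' Nei-Gojobori synonymous/nonsynonymous site counts of one codon
#'
#' For each of the three positions, the fraction of the three possible
#' single-base changes that are synonymous; changes creating a stop codon
#' count as nonsynonymous.
#'
#' @param codon Sense codon (A/C/G/T, not a stop).
#' @return Named numeric vector `s`, `n` with `s + n = 3`.
#' @export
ng_site_counts <- function(codon) {
  codon <- toupper(codon)
  if (codon %in% .STOPS) stop("stop codon has no site counts")
  key <- paste0("s_", codon)
  hit <- .ng_cache[[key]]
  if (!is.null(hit)) return(hit)
  aa <- .codon_aa(codon)
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(.NUC, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (!(mut %in% .STOPS) && identical(.codon_aa(mut), aa))
        s <- s + 1 / 3
    }
  }
  res <- c(s = s, n = 3 - s)
  .ng_cache[[key]] <- res
  res
}

# differences between two codons: pathway-averaged (Sd, Nd), excluding
# pathways through stop codons (all pathways used if every one is blocked)
.codon_path_diffs <- function(c1, c2) {
  key <- paste0("d_", c1, c2)
  hit <- .ng_cache[[key]]
  if (!is.null(hit)) return(hit)
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(as.character(k),
                  "1" = list(pos),
                  "2" = list(pos, rev(pos)),
                  "3" = {
                    p <- list()
                    for (i in 1:3) for (j in setdiff(1:3, i))
                      p[[length(p) + 1L]] <- pos[c(i, j, setdiff(1:3, c(i, j)))]
                    p
                  })
  tally <- function(path) {
    cur <- c1
    sd <- 0; nd <- 0
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% .STOPS) return(NULL)
      if (identical(.codon_aa(nxt), .codon_aa(cur))) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, tally))
  if (!length(res)) {
    # all pathways pass through stops; fall back to counting through them
    tally_all <- function(path) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in path) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (nxt %in% .STOPS || cur %in% .STOPS ||
              !identical(.codon_aa(nxt), .codon_aa(cur))) nd <- nd + 1
        else sd <- sd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    res <- lapply(perms, tally_all)
  }
  out <- colMeans(do.call(rbind, res))
  .ng_cache[[key]] <- out
  out
}

.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 3 / 4) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori pairwise Ka/Ks with Jukes-Cantor correction
#'
#' Codons containing gaps (`-`), ambiguity codes, or a stop codon in either
#' sequence are skipped.  Site counts are averaged over the two sequences;
#' observed differences are averaged over all mutational pathways not
#' passing through stop codons.  The Jukes-Cantor correction
#' `K = -(3/4) ln(1 - 4p/3)` is applied to pS and pN.
#'
#' @param cds_a,cds_b Equal-length coding sequences (length a multiple
#'   of 3).
#' @return List `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `ka_ks`
#'   (NA when Ks is 0 or a correction is undefined), `codons_compared`.
#' @export
ng_pair <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) stop("sequences differ in length")
  L <- nchar(cds_a)
  if (L %% 3L != 0L) stop("length not a multiple of 3")
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; used <- 0L
  starts <- seq(1L, L - 2L, 3L)
  cod_a <- substring(cds_a, starts, starts + 2L)
  cod_b <- substring(cds_b, starts, starts + 2L)
  clean <- !grepl("[^ACGT]", cod_a) & !grepl("[^ACGT]", cod_b) &
    !(cod_a %in% .STOPS) & !(cod_b %in% .STOPS)
  for (i in which(clean)) {
    ca <- cod_a[i]; cb <- cod_b[i]
    sa <- ng_site_counts(ca); sb <- ng_site_counts(cb)
    S <- S + (sa["s"] + sb["s"]) / 2
    N <- N + (sa["n"] + sb["n"]) / 2
    if (ca != cb) {
      d <- .codon_path_diffs(ca, cb)
      Sd <- Sd + d["sd"]; Nd <- Nd + d["nd"]
    }
    used <- used + 1L
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- .jc_correct(pS)
  Ka <- .jc_correct(pN)
  ka_ks <- if (is.na(Ks) || is.na(Ka) || Ks == 0) NA_real_ else Ka / Ks
  list(S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd),
       pS = unname(pS), pN = unname(pN), Ks = unname(Ks),
       Ka = unname(Ka), ka_ks = ka_ks, codons_compared = used)
}

#' Reference-frame allele sequences of a gene across accessions
#'
#' Each accession's allele is the intact reference CDS with its SNVs
#' substituted (strand-aware) and deleted coding bases replaced by `-`;
#' inserted bases are not represented, so all alleles stay aligned to the
#' reference frame and indel columns can be dropped pairwise.
#'
#' @param gene A [gene_model()].
#' @param variant_sets Named list of accession variant data frames.
#' @param accessions Accessions to materialise (default all).
#' @return Named character vector of allele sequences (reference length).
#' @export
allele_sequences <- function(gene, variant_sets,
                             accessions = names(variant_sets)) {
  ref <- strsplit(gene$cds_sequence, "")[[1]]
  iv <- gene$cds_intervals
  out <- vapply(accessions, function(acc) {
    v <- variant_sets[[acc]]
    v <- v[v$chrom == gene$chromosome, , drop = FALSE]
    s <- ref
    for (i in seq_len(nrow(v))) {
      if (v$vclass[i] == "snv") {
        cpos <- genome_to_cds(gene, v$pos[i])
        if (is.na(cpos)) next
        b <- v$alt[i]
        if (gene$strand == "-") b <- unname(.COMPLEMENT[b])
        s[cpos + 1L] <- b
      } else if (v$vclass[i] == "deletion") {
        del <- c(v$pos[i], v$pos[i] + nchar(v$ref[i]))
        gpos <- del[1L]:(del[2L] - 1L)
        cpos <- genome_to_cds(gene, gpos)
        cpos <- cpos[!is.na(cpos)]
        if (length(cpos)) s[cpos + 1L] <- "-"
      }
      # insertions are not representable in the reference frame
    }
    paste(s, collapse = "")
  }, "")
  out
}

.pairwise_site_diff <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  ok <- x %in% .NUC & y %in% .NUC
  n <- sum(ok)
  if (!n) return(NA_real_)
  sum(x[ok] != y[ok]) / n
}

#' Within- and between-group divergence statistics
#'
#' Averages [ng_pair()] and raw per-site difference (pi / Dxy, no
#' correction) over all pairs within each group and across groups.
#'
#' @param seqs Named character vector of aligned allele sequences.
#' @param group1,group2 Names of sequences in each group (group2 may be
#'   empty for a single-group summary).
#' @return List with `within1`, `within2`, `between`, each `NULL` or a
#'   list `pi`, `Ka`, `Ks`, `ka_ks`, `n_pairs` (means over defined pairs).
#' @export
group_stats <- function(seqs, group1, group2 = character(0)) {
  pair_summary <- function(pairs) {
    if (!nrow(pairs)) return(NULL)
    pi_v <- ka <- ks <- kk <- numeric(0)
    for (r in seq_len(nrow(pairs))) {
      a <- seqs[[pairs[r, 1L]]]; b <- seqs[[pairs[r, 2L]]]
      pi_v <- c(pi_v, .pairwise_site_diff(a, b))
      ngp <- ng_pair(a, b)
      ka <- c(ka, ngp$Ka); ks <- c(ks, ngp$Ks); kk <- c(kk, ngp$ka_ks)
    }
    list(pi = mean(pi_v, na.rm = TRUE), Ka = mean(ka, na.rm = TRUE),
         Ks = mean(ks, na.rm = TRUE), ka_ks = mean(kk, na.rm = TRUE),
         n_pairs = nrow(pairs))
  }
  within_pairs <- function(g) {
    if (length(g) < 2L) return(matrix(character(0), ncol = 2L))
    t(utils::combn(g, 2L))
  }
  between_pairs <- if (length(group2))
    as.matrix(expand.grid(group1, group2, stringsAsFactors = FALSE))
  else matrix(character(0), ncol = 2L)
  list(within1 = pair_summary(within_pairs(group1)),
       within2 = pair_summary(within_pairs(group2)),
       between = pair_summary(between_pairs))
}

#' Paired test that between-group divergence exceeds within-group diversity
#'
#' Paired two-sided t-test of per-locus Dxy against per-locus pi — the
#' locus-level support for a "divergence exceeds diversity" claim.
#'
#' @param dxy,pi_within Equal-length numeric vectors, one value per locus.
#' @return `htest` object from [stats::t.test()] (paired).
#' @export
paired_divergence_test <- function(dxy, pi_within) {
  ok <- !is.na(dxy) & !is.na(pi_within)
  if (sum(ok) < 2L) stop("need at least 2 loci with defined values")
  stats::t.test(dxy[ok], pi_within[ok], paired = TRUE)
}

#' Representative disrupted allele of a pseudogene locus
#'
#' Groups disrupted carriers by identical allele sequence and returns the
#' haplotype with the highest carrier count (ties broken by sequence
#' order); lower-frequency disrupted haplotypes are excluded.
#'
#' @param seqs Named character vector of allele sequences.
#' @param disrupted_ids Names of accessions called disrupted.
#' @return Character vector of carrier accessions of the representative
#'   haplotype.
#' @export
pick_representative <- function(seqs, disrupted_ids) {
  if (!length(disrupted_ids)) stop("no disrupted accessions")
  hap <- seqs[disrupted_ids]
  tab <- sort(table(hap), decreasing = TRUE)
  disrupted_ids[hap == names(tab)[1L]]
}

#' Tajima's D and diversity summaries from aligned sequences
#'
#' Standard Tajima (1989) computation: theta-pi from mean pairwise
#' differences, theta-W from segregating sites, D from their normalized
#' difference.  Columns containing non-ACGT characters in any sequence are
#' dropped.
#'
#' @param sequences Character vector (n >= 4) of equal-length sequences,
#'   or a 0/1 matrix (rows = sequences) of biallelic sites.
#' @return List `n_sequences`, `S` (segregating sites), `theta_pi`
#'   (mean pairwise differences), `theta_w`, `pi_per_site`, `D` (NaN when
#'   S = 0).
#' @export
tajimas_d <- function(sequences) {
  if (is.matrix(sequences)) {
    m <- sequences
    sites <- ncol(m)
  } else {
    n0 <- length(sequences)
    if (n0 < 4L) stop("need at least 4 sequences")
    chars <- do.call(rbind, strsplit(sequences, ""))
    keep <- apply(chars, 2L, function(col) all(col %in% .NUC))
    chars <- chars[, keep, drop = FALSE]
    sites <- ncol(chars)
    m <- matrix(0L, nrow = nrow(chars), ncol = sites)
    for (j in seq_len(sites)) {
      m[, j] <- as.integer(chars[, j] != chars[1L, j])
    }
  }
  n <- nrow(m)
  if (n < 4L) stop("need at least 4 sequences")
  freq <- colSums(m)
  seg <- freq > 0L & freq < n
  S <- sum(seg)
  # mean pairwise differences
  theta_pi <- sum(freq[seg] * (n - freq[seg])) / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  theta_w <- S / a1
  D <- if (S == 0L) NaN else
    (theta_pi - theta_w) / sqrt(e1 * S + e2 * S * (S - 1))
  list(n_sequences = n, S = S, theta_pi = theta_pi, theta_w = theta_w,
       pi_per_site = if (sites > 0) theta_pi / sites else NA_real_,
       D = D)
}

#' Simulate a neutral coalescent sample of binary haplotypes
#'
#' Standard n-coalescent with infinite-sites mutation: exponential
#' coalescence times, mutations placed uniformly on total branch length,
#' derived-allele carriers are the leaves below the mutated branch.  Used
#' to calibrate the null distribution of Tajima's D.
#'
#' @param n Sample size.
#' @param theta Scaled mutation rate (4Nmu per locus).
#' @return 0/1 matrix, rows = haplotypes, columns = segregating sites
#'   (may have zero columns).
#' @export
sim_neutral_sample <- function(n, theta) {
  # lineages: list of leaf sets; accumulate branch "exposure" per lineage
  lineages <- as.list(seq_len(n))
  exposure <- list()          # leaf sets with their branch lengths
  k <- n
  while (k > 1L) {
    t_k <- stats::rexp(1L, rate = k * (k - 1L) / 2)
    for (ln in lineages) exposure[[length(exposure) + 1L]] <-
      list(leaves = ln, len = t_k)
    pick <- sample.int(k, 2L)
    merged <- c(lineages[[pick[1L]]], lineages[[pick[2L]]])
    lineages <- c(lineages[-pick], list(merged))
    k <- k - 1L
  }
  # merge exposures of identical leaf sets
  lens <- vapply(exposure, `[[`, 0, "len")
  total <- sum(lens)
  n_mut <- stats::rpois(1L, theta / 2 * total)
  if (n_mut == 0L) return(matrix(0L, nrow = n, ncol = 0L))
  picked <- sample.int(length(exposure), n_mut, replace = TRUE,
                       prob = lens)
  m <- matrix(0L, nrow = n, ncol = n_mut)
  for (j in seq_len(n_mut)) {
    carriers <- exposure[[picked[j]]]$leaves
    if (length(carriers) == n) next   # root branch: not polymorphic
    m[carriers, j] <- 1L
  }
  m[, colSums(m) > 0L & colSums(m) < n, drop = FALSE]
}
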