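# Per-accession and per-locus summaries, accumulation curve with log fit,
# and the equal-probability randomization null for shared pseudogenes.

#' Per-accession pseudogene counts
#'
#' @param table A `psi_table` from [call_loci()].
#' @return List with `counts` (named integer vector per accession),
#'   `mean`, `sd` (sample standard deviation).
#' @export
per_accession_counts <- function(table) {
  counts <- table(factor(table$calls$accession, levels = table$accessions))
  counts <- stats::setNames(as.integer(counts), table$accessions)
  list(counts = counts, mean = mean(counts),
       sd = stats::sd(counts))
}

#' Disrupted-allele frequency summary over pseudogene loci
#'
#' @param table A `psi_table`.
#' @param criterion Optional criterion overriding the table's own.
#' @return List with `mean_k` (mean disrupted-allele count per pseudogene
#'   locus), `mean_k_pct` (mean k as a percentage of accessions),
#'   `spectrum` (table of k), `frac_shared` (fraction with k >= 2), and
#'   `frac_1_10` (fraction with 1 <= k <= 10).  Empty list when there are
#'   no pseudogene loci.
#' @export
allele_frequency_summary <- function(table, criterion = NULL) {
  loci <- psi_loci(table, criterion)
  if (!length(loci)) return(list())
  k <- table$k[loci]
  list(mean_k = mean(k),
       mean_k_pct = 100 * mean(k) / length(table$accessions),
       spectrum = table(k),
       frac_shared = mean(k >= 2),
       frac_1_10 = mean(k >= 1 & k <= 10))
}

#' Fit Y = a ln(X) + b by ordinary least squares
#'
#' @param x Sample sizes (X >= 1).
#' @param y Responses.
#' @return List `a`, `b`, `r_squared`.
#' @export
fit_log_curve <- function(x, y) {
  if (length(x) < 3L) stop("need at least 3 points for a log fit")
  fit <- stats::lm(y ~ log(x))
  list(a = unname(stats::coef(fit)[2L]), b = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared)
}

#' Pseudogene accumulation curve and logarithmic fit
#'
#' For each sample size k, the mean (over random accession orderings) of
#' the number of distinct pseudogene loci among the first k accessions,
#' then an ordinary least-squares fit of Y on ln X.
#'
#' @param table A `psi_table`.
#' @param reps Number of random orderings to average (default 100).
#' @param seed RNG seed.
#' @param criterion Optional criterion overriding the table's own.
#' @return List of class `accumulation_fit`: `curve` (data frame `k`,
#'   `mean_loci`), `a`, `b`, `r_squared` (NULL when fewer than 3
#'   accessions).
#' @export
accumulation_curve <- function(table, reps = 100L, seed = 1L,
                               criterion = NULL) {
  stopifnot(reps >= 1L)
  set.seed(seed)
  loci <- psi_loci(table, criterion)
  n <- length(table$accessions)
  calls <- table$calls[table$calls$locus %in% loci, , drop = FALSE]
  acc_index <- stats::setNames(seq_len(n), table$accessions)
  by_locus <- split(acc_index[calls$accession], calls$locus)
  curves <- matrix(0, nrow = reps, ncol = n)
  for (r in seq_len(reps)) {
    perm <- sample.int(n)                      # perm[i] = rank of accession i
    rank_of <- integer(n)
    rank_of[perm] <- seq_len(n)
    first <- vapply(by_locus, function(a) min(rank_of[a]), 0)
    curves[r, ] <- cumsum(tabulate(first, nbins = n))
  }
  curve <- data.frame(k = seq_len(n), mean_loci = colMeans(curves))
  fit <- if (n >= 3L) fit_log_curve(curve$k, curve$mean_loci) else
    list(a = NULL, b = NULL, r_squared = NULL)
  structure(list(curve = curve, a = fit$a, b = fit$b,
                 r_squared = fit$r_squared),
            class = "accumulation_fit")
}

#' Predict pseudogene loci from the logarithmic accumulation model
#'
#' Evaluates Y = a ln(X) + b.
#'
#' @param a Slope of ln X.
#' @param b Intercept.
#' @param X Sample size (>= 1), vectorised.
#' @return List `raw` (Y) and `rounded` (nearest integer).
#' @export
predict_loci <- function(a, b, X) {
  if (any(X < 1)) stop("X must be >= 1")
  y <- a * log(X) + b
  list(raw = y, rounded = round(y))
}

.pairwise_shared <- function(sets, denom = c("jaccard", "mean_size")) {
  denom <- match.arg(denom)
  n <- length(sets)
  m <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    d <- if (denom == "jaccard") length(union(sets[[i]], sets[[j]]))
      else mean(c(length(sets[[i]]), length(sets[[j]])))
    m[i, j] <- m[j, i] <- if (d == 0) 0 else inter / d
  }
  m
}

#' Randomization null for the shared-pseudogene proportion
#'
#' Under equal pseudogenization probability at every gene, each accession's
#' observed pseudogene count is redrawn uniformly without replacement from
#' the gene universe; the mean pairwise shared proportion over replicates
#' forms the null.  The observed value is computed identically from the
#' real calls.
#'
#' @param table A `psi_table` (used for the observed sets), or `NULL` when
#'   only the null is wanted.
#' @param counts Named per-accession pseudogene counts; defaults to the
#'   observed counts from `table`.
#' @param n_genes Size of the gene universe.
#' @param reps Number of randomization replicates (default 1000).
#' @param seed RNG seed.
#' @param denom Shared-proportion denominator: `"jaccard"` (intersection
#'   over union, default) or `"mean_size"`.
#' @return List of class `shared_stats`: `observed_matrix`, `observed_mean`
#'   (mean over distinct pairs; NA without a table), `null_mean`,
#'   `null_means` (per replicate), `p_value` (fraction of null replicates
#'   >= observed), `reps`, `seed`.
#' @export
shared_null <- function(table = NULL, counts = NULL, n_genes = NULL,
                        reps = 1000L, seed = 1L,
                        denom = c("jaccard", "mean_size")) {
  denom <- match.arg(denom)
  if (reps < 100L) warning("fewer than 100 replicates: unstable null")
  if (is.null(counts)) counts <- per_accession_counts(table)$counts
  if (is.null(n_genes)) n_genes <- length(table$loci)
  if (any(counts > n_genes)) stop("a count exceeds n_genes")
  set.seed(seed)
  n <- length(counts)
  off_diag <- upper.tri(matrix(0, n, n))
  null_means <- vapply(seq_len(reps), function(r) {
    sets <- lapply(counts, function(k) sample.int(n_genes, k))
    mean(.pairwise_shared(sets, denom)[off_diag])
  }, 0)
  obs_matrix <- NULL
  obs_mean <- NA_real_
  if (!is.null(table)) {
    sets <- lapply(table$accessions, function(a)
      table$calls$locus[table$calls$accession == a])
    obs_matrix <- .pairwise_shared(sets, denom)
    dimnames(obs_matrix) <- list(table$accessions, table$accessions)
    obs_mean <- mean(obs_matrix[off_diag])
  }
  structure(list(observed_matrix = obs_matrix, observed_mean = obs_mean,
                 null_mean = mean(null_means), null_means = null_means,
                 p_value = if (is.na(obs_mean)) NA_real_ else
                   mean(null_means >= obs_mean),
                 reps = reps, seed = seed, denom = denom),
            class = "shared_stats")
}
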