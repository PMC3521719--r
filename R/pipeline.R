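# One-config orchestration of the full survey: call -> summary /
# landscape / clusters / families / molevol / domains / tree, with a run
# manifest for byte-identical re-runs.

.log_stage <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the full pseudogene survey pipeline
#'
#' Stages run in dependency order; any stage can be skipped via
#' `config$stages`.  All randomness derives from `config$seed`.  The
#' manifest records inputs, seed, stage list, output checksums and the
#' package version, allowing a byte-identical re-run.
#'
#' @param config Path to a YAML file or a named list with elements:
#'   `genome`, `gff3`, `variants` (directory of TSVs or a VCF file),
#'   `variants_dialect` (`"tsv1001"`/`"vcf"`), optional `domains` (TSV),
#'   optional `centromere_midpoints` (named list), `criterion`,
#'   `window_bp`, `min_identity`, `min_coverage`, `cluster_gap`, `reps`,
#'   `seed`, `out` (output directory), `stages` (character vector).
#' @return The manifest (named list), invisibly written to
#'   `<out>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(criterion = "whole_orf", window_bp = 1e6,
                   min_identity = 0.70, min_coverage = 0.50,
                   cluster_gap = 9L, reps = 100L, seed = 1L,
                   region_span = 4e6, molevol_max_loci = 50L,
                   variants_dialect = "tsv1001",
                   stages = c("call", "summary", "landscape", "clusters",
                              "families", "molevol", "domains", "tree"))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (req in c("genome", "gff3", "variants", "out"))
    if (is.null(config[[req]]))
      stop("config is missing required entry '", req, "'")
  for (p in c("genome", "gff3", "variants"))
    if (!file.exists(config[[p]]))
      stop("input path for '", p, "' does not exist: ", config[[p]])
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
    p
  }

  .log_stage("io", "reading annotation and variants")
  genes <- read_annotation(config$gff3, config$genome)
  chrom_len <- attr(genes, "chromosome_lengths")
  variant_sets <- read_variants(config$variants, config$variants_dialect)
  domain_table <- if (!is.null(config$domains))
    read_domain_table(config$domains) else NULL

  params <- caller_params(criterion = config$criterion)
  stages_run <- character(0)
  tbl <- NULL

  if ("call" %in% config$stages) {
    .log_stage("call", length(genes), " genes x ", length(variant_sets),
               " accessions")
    tbl <- call_loci(genes, variant_sets, params)
    emit(tbl$calls, "calls.tsv")
    stages_run <- c(stages_run, "call")
  }
  if (is.null(tbl)) stop("stage 'call' is required by all later stages")

  fam <- NULL
  if ("families" %in% config$stages) {
    .log_stage("families", "pairwise similarity families")
    fam <- build_families(genes, min_identity = config$min_identity,
                          min_coverage = config$min_coverage)
    emit(fam$families, "families.tsv")
    stages_run <- c(stages_run, "families")
  }
  if ("summary" %in% config$stages) {
    .log_stage("summary", "per-accession counts and accumulation curve")
    pac <- per_accession_counts(tbl)
    emit(data.frame(accession = names(pac$counts), psi_count = pac$counts),
         "counts.tsv")
    afs <- allele_frequency_summary(tbl)
    if (length(afs))
      emit(data.frame(k = as.integer(names(afs$spectrum)),
                      n_loci = as.integer(afs$spectrum)), "spectrum.tsv")
    acc <- accumulation_curve(tbl, reps = config$reps, seed = config$seed)
    emit(acc$curve, "accumulation.tsv")
    sh <- shared_null(tbl, reps = max(100L, config$reps),
                      seed = config$seed)
    fitj <- file.path(out, "fit.json")
    jsonlite::write_json(
      list(a = acc$a, b = acc$b, r_squared = acc$r_squared,
           mean_per_accession = pac$mean, sd_per_accession = pac$sd,
           mean_k = if (length(afs)) afs$mean_k else NA,
           shared_observed = sh$observed_mean,
           shared_null = sh$null_mean, shared_p = sh$p_value),
      fitj, auto_unbox = TRUE, digits = NA, null = "null")
    written <- c(written, fitj)
    stages_run <- c(stages_run, "summary")
  }
  if ("landscape" %in% config$stages) {
    .log_stage("landscape", "window statistics")
    strata <- if (!is.null(fam)) fam$stratum else NULL
    win <- window_stats(genes, tbl, chrom_len,
                        window_bp = config$window_bp, strata = strata)
    emit(win, "windows.tsv")
    dc <- density_correlation(win)
    emit(data.frame(stratum = "all", r = dc$r, p = dc$p_value,
                    n_windows = dc$n_windows), "correlations.tsv")
    mids <- if (!is.null(config$centromere_midpoints))
      unlist(config$centromere_midpoints)[names(chrom_len)]
    else chrom_len / 2
    span <- min(config$region_span, min(chrom_len) / 3)
    regions <- build_regions(chrom_len, mids, span = span)
    rc <- region_compare(genes, tbl, regions$centromere, regions$telomere)
    emit(rc$means, "region_means.tsv")
    emit(rc$tests, "region_tests.tsv")
    stages_run <- c(stages_run, "landscape")
  }
  if ("clusters" %in% config$stages) {
    .log_stage("clusters", "chains of nearby pseudogene loci")
    cl <- find_clusters(genes, psi_loci(tbl),
                        max_intervening_genes = config$cluster_gap)
    emit(data.frame(locus = names(cl$stratum), stratum = cl$stratum),
         "clusters.tsv")
    stages_run <- c(stages_run, "clusters")
  }
  if ("molevol" %in% config$stages) {
    psi <- utils::head(sort(psi_loci(tbl)), config$molevol_max_loci)
    .log_stage("molevol", "Ka/Ks and diversity for ", length(psi),
               " pseudogene loci")
    rows <- lapply(psi, function(locus) {
      g <- genes[[locus]]
      seqs <- allele_sequences(g, variant_sets)
      disrupted <- tbl$calls$accession[tbl$calls$locus == locus]
      intact <- setdiff(names(seqs), disrupted)
      rep_car <- pick_representative(seqs, disrupted)
      gs <- group_stats(seqs, rep_car, intact)
      td <- if (length(intact) >= 4L)
        tajimas_d(seqs[intact])$D else NA_real_
      data.frame(
        locus = locus, n_disrupted = length(disrupted),
        pi_disrupted = gs$within1$pi %||% NA_real_,
        ka_between = gs$between$Ka %||% NA_real_,
        ks_between = gs$between$Ks %||% NA_real_,
        kaks_between = gs$between$ka_ks %||% NA_real_,
        dxy = gs$between$pi %||% NA_real_,
        tajima_d_intact = td)
    })
    if (length(rows)) emit(do.call(rbind, rows), "molevol.tsv")
    stages_run <- c(stages_run, "molevol")
  }
  if ("domains" %in% config$stages && !is.null(domain_table)) {
    .log_stage("domains", "domain-family bias")
    dstats <- family_psi_stats(domain_table, tbl)
    emit(as.data.frame(dstats), "domain_stats.tsv")
    if (nrow(dstats) >= 2L) {
      part <- partition_regions(dstats)
      emit(data.frame(domain_name = names(part$region),
                      region = as.character(part$region)),
           "domain_regions.tsv")
    }
    stages_run <- c(stages_run, "domains")
  }
  if ("tree" %in% config$stages && length(tbl$accessions) >= 3L &&
        length(psi_loci(tbl)) >= 1L) {
    .log_stage("tree", "presence/absence neighbor joining")
    pm <- presence_matrix(tbl)
    nwk <- nj_tree(hamming_distance(pm))$newick
    p <- file.path(out, "tree.nwk")
    writeLines(nwk, p)
    written <- c(written, p)
    stages_run <- c(stages_run, "tree")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("psiscan")),
    seed = config$seed,
    criterion = config$criterion,
    stages = stages_run,
    inputs = lapply(config[c("genome", "gff3", "variants")], function(p) {
      files <- if (dir.exists(p)) list.files(p, full.names = TRUE) else p
      list(path = p, md5 = unname(tools::md5sum(files)))
    }),
    outputs = lapply(stats::setNames(written, basename(written)),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
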