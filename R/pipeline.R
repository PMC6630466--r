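## Pipeline orchestration: scan -> classify -> frequencies/Fst -> filters ->
## joins -> association, with ranked report tables and an exclusion log.

#' Pipeline run configuration
#'
#' @param utrs,mirnas,vcf,panel File paths for the four mandatory inputs.
#' @param expression,interactions,latitude Optional metadata file paths.
#' @param site_types Site types counted as targets.
#' @param expression_threshold Minimum expression; `NA` means the median of
#'   the expression table (top-50 percent rule).
#' @param freq_lower,freq_upper Global target-allele frequency window
#'   (inclusive).
#' @param fst_estimator `"hudson"`, `"weir_cockerham"` or
#'   `"wright_variance"`.
#' @param fst_threshold Differentiation threshold for the ranked table.
#' @param pfst_threshold Empirical P threshold for the experimental table.
#' @param null_fst_file Optional file of genome-wide null Fst values (one
#'   per line); when absent the null is simulated under Balding-Nichols
#'   with F set to the genome-wide estimate from the classified SNPs.
#' @param n_null Size of the simulated null.
#' @param excluded_populations Populations left out of the latitude model.
#' @param rng_seed Seed for the simulated null.
#' @param out_dir Output directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(utrs, mirnas, vcf, panel,
                       expression = NULL, interactions = NULL,
                       latitude = NULL,
                       site_types = default_site_types(),
                       expression_threshold = NA_real_,
                       freq_lower = 0.01, freq_upper = 0.99,
                       fst_estimator = "hudson",
                       fst_threshold = 0.7,
                       pfst_threshold = 0.05,
                       null_fst_file = NULL, n_null = 999L,
                       excluded_populations = default_excluded_populations(),
                       rng_seed = 1L,
                       out_dir = tempfile("mirpopvar_run_")) {
  stopifnot(freq_lower < freq_upper, fst_threshold >= 0, fst_threshold <= 1,
            pfst_threshold >= 0, pfst_threshold <= 1)
  structure(list(utrs = utrs, mirnas = mirnas, vcf = vcf, panel = panel,
                 expression = expression, interactions = interactions,
                 latitude = latitude, site_types = site_types,
                 expression_threshold = expression_threshold,
                 freq_lower = freq_lower, freq_upper = freq_upper,
                 fst_estimator = fst_estimator,
                 fst_threshold = fst_threshold,
                 pfst_threshold = pfst_threshold,
                 null_fst_file = null_fst_file, n_null = as.integer(n_null),
                 excluded_populations = excluded_populations,
                 rng_seed = as.integer(rng_seed), out_dir = out_dir),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' Flat `key=value` text, one key per line; list-valued fields are
#' comma-joined. `read_run_config(write_run_config(cfg, p))` round-trips
#' bit-exactly.
#'
#' @param config A [run_config()].
#' @param path Output file.
#' @return `path` (write) or the restored `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  enc <- function(v) {
    if (is.null(v) || length(v) == 0L) return("")
    if (length(v) > 1L) return(paste(v, collapse = ","))
    if (is.na(v)) return("NA")
    format(v, digits = 17)
  }
  keys <- names(unclass(config))
  writeLines(paste0(keys, "=", vapply(config[keys], enc, character(1))), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  vals <- setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, character(1), 1L))
  num <- function(x) if (identical(x, "NA")) NA_real_ else as.numeric(x)
  run_config(
    utrs = vals$utrs, mirnas = vals$mirnas, vcf = vals$vcf,
    panel = vals$panel,
    expression = if (nzchar(vals$expression)) vals$expression,
    interactions = if (nzchar(vals$interactions)) vals$interactions,
    latitude = if (nzchar(vals$latitude)) vals$latitude,
    site_types = strsplit(vals$site_types, ",")[[1L]],
    expression_threshold = num(vals$expression_threshold),
    freq_lower = as.numeric(vals$freq_lower),
    freq_upper = as.numeric(vals$freq_upper),
    fst_estimator = vals$fst_estimator,
    fst_threshold = as.numeric(vals$fst_threshold),
    pfst_threshold = as.numeric(vals$pfst_threshold),
    null_fst_file = if (nzchar(vals$null_fst_file)) vals$null_fst_file,
    n_null = as.integer(vals$n_null),
    excluded_populations = strsplit(vals$excluded_populations, ",")[[1L]],
    rng_seed = as.integer(vals$rng_seed),
    out_dir = vals$out_dir)
}

## Classify every SNP x expressed family; returns pairs plus exclusion log.
.classify_all <- function(utrs, snps, families, site_types, log) {
  pairs <- NULL
  for (si in seq_len(nrow(snps))) {
    snp <- snps[si, ]
    ui <- match(snp$utr_id, utrs$utr_id)
    if (is.na(ui)) {
      log <- c(log, sprintf("exclude snp=%s reason=utr_not_found utr=%s",
                            snp$snp_id, snp$utr_id))
      next
    }
    utr <- utrs[ui, ]
    for (fi in seq_len(nrow(families))) {
      fam <- list(family_key = families$family_key[fi],
                  mirnas = strsplit(families$mirnas[fi], ",")[[1L]])
      pr <- classify_pair(utr, snp, fam, site_types)
      if (!is.null(pr)) pairs <- rbind(pairs, pr)
    }
  }
  list(pairs = pairs, log = log)
}

## Per-super-population frequency columns + counts for every pair.
.pair_frequencies <- function(pairs, vcf_data, panel) {
  counts_list <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    dose <- vcf_data$alt_dose[pairs$snp_id[i], ]
    called <- vcf_data$ploidy_called[pairs$snp_id[i], ]
    pf <- pop_frequencies(dose, panel, called = called,
                          target_allele_is_alt = pairs$target_allele[i] == pairs$alt[i])
    sp <- pf[pf$super_pop != "global", , drop = FALSE]
    for (s in sp$super_pop)
      pairs[i, s] <- sp$freq[sp$super_pop == s]
    pairs$global_freq[i] <- pf$freq[pf$super_pop == "global"]
    counts_list[[i]] <- cbind(target = sp$target_count, total = sp$total_count)
  }
  list(pairs = pairs, counts = counts_list)
}

#' Per-class, per-super-population frequency summaries
#'
#' Groups target/near-target pairs by polarization class and emits the long
#'-format frequency table needed to draw the class-wise violin/box figure:
#' one row per (pair, super-population) with the target allele frequency.
#'
#' @param pairs Pair table with per-super-population frequency columns.
#' @return data.frame with columns `polarization`, `snp_id`, `super_pop`,
#'   `freq` (empty, with a warning, when no polarized pairs exist).
#' @export
summarize_classes <- function(pairs) {
  sps <- intersect(SUPER_POPS, names(pairs))
  pol <- pairs[!is.na(pairs$polarization) &
                 pairs$polarization != "unpolarized", , drop = FALSE]
  if (nrow(pol) == 0L) {
    .warnf("no polarized pairs to summarize")
    return(data.frame(polarization = character(), snp_id = character(),
                      super_pop = character(), freq = numeric()))
  }
  out <- do.call(rbind, lapply(sps, function(s)
    data.frame(polarization = pol$polarization, snp_id = pol$snp_id,
               super_pop = s, freq = pol[[s]], stringsAsFactors = FALSE)))
  out[order(out$polarization, out$snp_id, out$super_pop), , drop = FALSE]
}

## Deterministic table formatting so re-runs are byte-identical.
.write_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits, format = "f"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes scan, classification, frequency/Fst computation, the filter
#' cascade (expression, frequency window, differentiation, experimental
#' evidence) and the class summaries, writing the report bundle to
#' `config$out_dir`: `table1.tsv` (pairs above the Fst threshold, descending
#' Fst), `table2.tsv` (experimentally detected pairs below the empirical P
#' threshold), `fig1_data.tsv` (per-class frequency vectors), `fig3_data.tsv`
#' (Fst histogram), `pairs_all.tsv`, `run_log.txt` and a provenance copy of
#' the configuration (`run_config.txt`).
#'
#' @param config A [run_config()].
#' @return List with the pair table (`pairs`), `table1`, `table2`,
#'   `fig1_data`, `fig3_report`, `latitude_fits` (when latitude metadata was
#'   supplied), `log` (character vector) and `paths`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  utrs <- read_utr_fasta(config$utrs)
  mirnas <- read_mirna_fasta(config$mirnas)
  if (!is.null(config$expression)) {
    expr <- read_expression(config$expression)
    thr <- if (is.na(config$expression_threshold)) NULL
           else config$expression_threshold
    n0 <- nrow(mirnas)
    mirnas <- suppressWarnings(filter_expressed(mirnas, expr, thr))
    if (n0 > nrow(mirnas))
      log <- c(log, sprintf("exclude mirnas=%d reason=below_expression_threshold",
                            n0 - nrow(mirnas)))
  }
  families <- group_families(mirnas)
  vcf_data <- read_snp_vcf(config$vcf)
  if (vcf_data$n_excluded > 0L)
    log <- c(log, sprintf("exclude vcf_records=%d reason=not_biallelic_snv",
                          vcf_data$n_excluded))
  panel <- read_panel(config$panel)

  cl <- .classify_all(utrs, vcf_data$snps, families, config$site_types, log)
  log <- cl$log
  pairs <- cl$pairs
  empty_cols <- c("snp_id", "utr_id", "gene", "mirnas", "site_type",
                  "target_allele", "polarization", "target_in_reference",
                  SUPER_POPS, "global_freq", "fst", "p_fst")
  if (is.null(pairs) || nrow(pairs) == 0L) {
    .warnf("no target/near-target pairs found")
    empty <- as.data.frame(setNames(rep(list(character()), length(empty_cols)),
                                    empty_cols))
    for (f in c("table1.tsv", "table2.tsv", "fig1_data.tsv", "fig3_data.tsv",
                "pairs_all.tsv"))
      .write_tsv(empty, file.path(config$out_dir, f))
    writeLines(log, file.path(config$out_dir, "run_log.txt"))
    write_run_config(config, file.path(config$out_dir, "run_config.txt"))
    return(list(pairs = empty, table1 = empty, table2 = empty,
                fig1_data = empty, fig3_report = NULL, latitude_fits = NULL,
                log = log, paths = config$out_dir))
  }
  log <- c(log, sprintf("pairs_classified=%d", nrow(pairs)))

  pairs$global_freq <- NA_real_
  pf <- .pair_frequencies(pairs, vcf_data, panel)
  pairs <- pf$pairs

  n0 <- nrow(pairs)
  keep <- pairs$global_freq >= config$freq_lower &
    pairs$global_freq <= config$freq_upper
  if (any(!keep))
    log <- c(log, sprintf("exclude pairs=%d reason=outside_frequency_window",
                          sum(!keep)))
  pairs <- pairs[keep, , drop = FALSE]
  counts <- pf$counts[keep]

  pairs$fst <- vapply(counts, fst_estimate, numeric(1),
                      estimator = config$fst_estimator)

  ## empirical P against a genome-wide null (supplied or simulated)
  null_fst <- NULL
  if (!is.null(config$null_fst_file)) {
    null_fst <- as.numeric(readLines(config$null_fst_file))
  } else if (nrow(pairs) > 0L) {
    f_hat <- fst_genomewide(counts, "hudson")
    f_hat <- min(0.9, max(0.01, f_hat))
    set.seed(config$rng_seed)
    totals <- counts[[1L]][, "total"]
    null_fst <- vapply(seq_len(config$n_null), function(i) {
      p <- simulate_frequencies(.draw_pbar(), f_hat, length(totals))
      tc <- rbinom(length(totals), totals, p)
      fst_estimate(cbind(tc, totals), config$fst_estimator)
    }, numeric(1))
    log <- c(log, sprintf("null_fst=simulated n=%d F=%.4f", config$n_null, f_hat))
  }
  pairs$p_fst <- if (is.null(null_fst)) NA_real_ else
    vapply(pairs$fst, empirical_pfst, numeric(1), null_values = null_fst)

  report_cols <- c("mirnas", "gene", "snp_id", "site_type", "target_allele",
                   "polarization", "target_in_reference",
                   "EAS", "AMR", "AFR", "EUR", "SAS", "global_freq",
                   "fst", "p_fst")
  for (s in SUPER_POPS) if (!s %in% names(pairs)) pairs[[s]] <- NA_real_

  table1 <- differentiation_filter(pairs, config$fst_threshold)[, report_cols]
  table1$fst <- pmax(0, table1$fst)   # clamp negatives in the report only

  if (!is.null(config$interactions)) {
    pairs <- join_interactions(pairs, read_interactions(config$interactions))
  } else {
    pairs$experimentally_detected <- FALSE
  }
  t2 <- pairs[pairs$experimentally_detected &
                !is.na(pairs$p_fst) & pairs$p_fst < config$pfst_threshold, ,
              drop = FALSE]
  table2 <- t2[order(-t2$fst, t2$snp_id), c(report_cols, "experimentally_detected")]
  table2$fst <- pmax(0, table2$fst)

  fig1 <- summarize_classes(pairs)
  fig3 <- fst_distribution_report(pairs$fst, threshold = 0.3)
  log <- c(log, sprintf("fst_at_or_above_0.3=%d of=%d", fig3$count, fig3$total))

  latitude_fits <- NULL
  if (!is.null(config$latitude)) {
    geo <- read_latitude_table(config$latitude, config$excluded_populations)
    latitude_fits <- .fit_latitudes(pairs, vcf_data, panel, geo)
  }

  paths <- list(
    table1 = file.path(config$out_dir, "table1.tsv"),
    table2 = file.path(config$out_dir, "table2.tsv"),
    fig1 = file.path(config$out_dir, "fig1_data.tsv"),
    fig3 = file.path(config$out_dir, "fig3_data.tsv"),
    pairs = file.path(config$out_dir, "pairs_all.tsv"),
    log = file.path(config$out_dir, "run_log.txt"),
    config = file.path(config$out_dir, "run_config.txt"))
  .write_tsv(table1, paths$table1)
  .write_tsv(table2, paths$table2)
  .write_tsv(fig1, paths$fig1)
  .write_tsv(fig3$histogram, paths$fig3)
  .write_tsv(pairs, paths$pairs)
  writeLines(log, paths$log)
  write_run_config(config, paths$config)

  list(pairs = pairs, table1 = table1, table2 = table2, fig1_data = fig1,
       fig3_report = fig3, latitude_fits = latitude_fits, log = log,
       paths = paths)
}

## Latitude model per pair: per-sampled-population target frequencies
## regressed on absolute centroid latitude, excluded populations removed.
.fit_latitudes <- function(pairs, vcf_data, panel, geo) {
  inc <- geo[!geo$excluded, , drop = FALSE]
  fits <- list()
  for (i in seq_len(nrow(pairs))) {
    dose <- vcf_data$alt_dose[pairs$snp_id[i], ]
    called <- vcf_data$ploidy_called[pairs$snp_id[i], ]
    pop <- panel$pop[match(names(dose), panel$sample)]
    tgt <- if (pairs$target_allele[i] == pairs$alt[i])
      ifelse(is.na(dose), 0L, dose) else called - ifelse(is.na(dose), 0L, dose)
    tc <- tapply(tgt, pop, sum); tot <- tapply(called, pop, sum)
    freq <- tc / tot
    rec <- data.frame(population = names(freq), freq = as.numeric(freq))
    rec <- merge(rec, inc, by = "population")
    if (nrow(rec) < 3L) next
    fits[[pairs$snp_id[i]]] <- fit_latitude_model(rec)
  }
  fits
}
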