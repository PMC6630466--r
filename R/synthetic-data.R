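## Ground-truthed synthetic fixtures: UTRs with planted seed-match sites,
## SNPs whose alleles create or destroy those sites, Balding-Nichols
## population structure, ancestral-allele annotation, and the side tables
## (panel, latitude, expression, interactions) the pipeline consumes.

#' Built-in mature microRNA set for simulations
#'
#' A small set of human mature sequences (miRBase), including two let-7
#' members that share a seed (exercising family grouping) and one decoy that
#' the default expression table leaves below the expression threshold.
#'
#' @return data.frame with columns `name`, `mature_seq`.
#' @export
default_sim_mirnas <- function() {
  data.frame(
    name = c("let-7a-5p", "let-7b-5p", "miR-24-3p", "miR-155-5p",
             "miR-122-5p", "miR-9999-3p"),
    mature_seq = c("UGAGGUAGUAGGUUGUAUAGUU",
                   "UGAGGUAGUAGGUUGUGUGGUU",
                   "UGGCUCAGUUCAGCAGGAACAG",
                   "UUAAUGCUAAUCGUGAUAGGGGUU",
                   "UGGAGUGUGACAAUGGUGUUUG",
                   "UACGUACGUACGUACGUACGUA"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Collects every knob of the fixture generator. Defaults describe a small
#' but structured study: 10 sampled populations (2 per super-population),
#' 30 diploids each, Balding-Nichols differentiation F = 0.15, and planted
#' SNP classes covering site-disrupting, site-creating and site-neutral
#' variants plus a latitude-graded subset.
#'
#' @param rng_seed Integer seed; the same seed yields byte-identical
#'   fixtures.
#' @param n_utrs,utr_length Number and length of background UTR sequences.
#' @param mirnas data.frame (`name`, `mature_seq`); default
#'   [default_sim_mirnas()].
#' @param unexpressed Names of miRNAs given near-zero expression.
#' @param n_pops,samples_per_pop Sampled populations (assigned round-robin
#'   to the five super-populations) and diploid samples per population.
#' @param F Balding-Nichols differentiation parameter in (0,1).
#' @param n_disrupting,n_creating,n_neutral Planted SNP counts per class:
#'   disrupting = reference allele is the target allele, creating = the
#'   alternate allele completes the site, neutral = neither allele affects
#'   any family's site status.
#' @param p_ancestral_target Probability that the ancestral allele of a pair
#'   SNP is the target allele.
#' @param p_ancestral_unknown Probability that the ancestral annotation is
#'   missing (tests unpolarized handling).
#' @param fig1_contrast If `TRUE`, pair SNPs whose target allele is
#'   ancestral get high African / low non-African target frequencies and
#'   derived-target SNPs the reverse, emulating the out-of-Africa loss/gain
#'   pattern; if `FALSE` all SNPs use exchangeable Balding-Nichols draws.
#' @param lat_effect List: `n` pair SNPs whose per-population target
#'   frequency follows `intercept + slope * |latitude| + N(0, noise_sd)`.
#' @param site_types Site types planted (most-specific first).
#' @return Object of class `sim_config` (a list).
#' @export
sim_config <- function(rng_seed = 20190622L,
                       n_utrs = 30L, utr_length = 300L,
                       mirnas = default_sim_mirnas(),
                       unexpressed = "miR-9999-3p",
                       n_pops = 10L, samples_per_pop = 30L,
                       F = 0.15,
                       n_disrupting = 15L, n_creating = 10L, n_neutral = 20L,
                       p_ancestral_target = 0.5,
                       p_ancestral_unknown = 0,
                       fig1_contrast = TRUE,
                       lat_effect = list(n = 2L, slope = -0.01,
                                         intercept = 0.8, noise_sd = 0.02),
                       site_types = c("8mer", "7mer-m8", "7mer-A1")) {
  if (F <= 0 || F >= 1) .stopf("F must lie in (0, 1)")
  if (p_ancestral_unknown < 0 || p_ancestral_unknown > 1)
    .stopf("p_ancestral_unknown must lie in [0, 1]")
  structure(list(rng_seed = as.integer(rng_seed), n_utrs = n_utrs,
                 utr_length = utr_length, mirnas = mirnas,
                 unexpressed = unexpressed, n_pops = n_pops,
                 samples_per_pop = samples_per_pop, F = F,
                 n_disrupting = n_disrupting, n_creating = n_creating,
                 n_neutral = n_neutral,
                 p_ancestral_target = p_ancestral_target,
                 p_ancestral_unknown = p_ancestral_unknown,
                 fig1_contrast = fig1_contrast, lat_effect = lat_effect,
                 site_types = site_types),
            class = "sim_config")
}

#' Balding-Nichols subpopulation allele frequencies
#'
#' Each population's frequency is an independent draw from
#' `Beta(p_bar (1-F)/F, (1-p_bar)(1-F)/F)`: expectation `p_bar`, variance
#' `F p_bar (1-p_bar)`, expected Fst approximately F.
#'
#' @param p_bar Ancestral allele frequency in (0,1).
#' @param F Differentiation parameter in (0,1).
#' @param n_pops Number of populations.
#' @return Numeric vector of length `n_pops`.
#' @export
simulate_frequencies <- function(p_bar, F, n_pops) {
  if (p_bar <= 0 || p_bar >= 1) .stopf("p_bar must lie in (0, 1)")
  if (F <= 0 || F >= 1) .stopf("F must lie in (0, 1)")
  k <- (1 - F) / F
  rbeta(n_pops, p_bar * k, (1 - p_bar) * k)
}

## Ancestral p_bar draw: truncated Beta(0.8, 0.8) on [0.05, 0.95], chosen to
## populate the 0.01-0.99 analysis window with common variants.
.draw_pbar <- function(n = 1L) {
  x <- rbeta(n, 0.8, 0.8)
  pmin(0.95, pmax(0.05, x))
}

.random_dna <- function(n_len) {
  paste(sample(c("A", "C", "G", "T"), n_len, replace = TRUE), collapse = "")
}

## Population layout: pops assigned round-robin to the five super-populations,
## latitudes drawn from plausible per-super-population ranges.
.sim_pops <- function(config) {
  sp <- rep(SUPER_POPS, length.out = config$n_pops)
  lat_range <- list(AFR = c(-10, 15), AMR = c(-15, 35), EAS = c(20, 42),
                    EUR = c(38, 62), SAS = c(6, 28))
  lat <- vapply(sp, function(s) runif(1, lat_range[[s]][1], lat_range[[s]][2]),
                numeric(1))
  lon <- runif(config$n_pops, -90, 120)
  data.frame(pop = sprintf("POP%02d", seq_len(config$n_pops)),
             super_pop = sp, latitude = round(unname(lat), 3),
             longitude = round(lon, 3), stringsAsFactors = FALSE)
}

## True per-population target-allele frequencies for one pair SNP, honouring
## the fig1 contrast and latitude-effect settings.
.pair_freqs <- function(config, pops, anc_is_target, lat_snp) {
  if (lat_snp) {
    le <- config$lat_effect
    f <- le$intercept + le$slope * abs(pops$latitude) +
      rnorm(nrow(pops), 0, le$noise_sd)
    return(pmin(0.98, pmax(0.02, f)))
  }
  if (config$fig1_contrast) {
    means <- if (anc_is_target) ifelse(pops$super_pop == "AFR", 0.70, 0.15)
             else ifelse(pops$super_pop == "AFR", 0.20, 0.60)
    ## mild within-group scatter around the super-population mean
    k <- (1 - 0.05) / 0.05
    return(vapply(means, function(m) rbeta(1, m * k, (1 - m) * k), numeric(1)))
  }
  simulate_frequencies(.draw_pbar(), config$F, nrow(pops))
}

## Candidate substitutions that toggle a planted site off, verified with the
## scanner itself used in reverse.
.pick_disruption <- function(site_seq_utr, pos0_candidates, motifs, site_types,
                             other_motifs) {
  for (pos in sample(pos0_candidates)) {
    refb <- substr(site_seq_utr, pos + 1L, pos + 1L)
    for (altb in sample(setdiff(c("A", "C", "G", "T"), refb))) {
      cand <- site_seq_utr
      substr(cand, pos + 1L, pos + 1L) <- altb
      ok <- nrow(.sites_at(cand, pos, motifs, site_types)) == 0L
      if (!ok) next
      clash <- any(vapply(other_motifs, function(m)
        nrow(.sites_at(cand, pos, m, site_types)) > 0L ||
        nrow(.sites_at(site_seq_utr, pos, m, site_types)) > 0L, logical(1)))
      if (!clash) return(list(pos = pos, alt = altb))
    }
  }
  NULL
}

#' Plant target/near-target SNPs into synthetic UTRs
#'
#' Generates random background UTRs, embeds exact seed-match motifs at
#' recorded non-overlapping positions, and derives SNP specifications whose
#' two alleles verifiably differ in site status — the scanner itself is used
#' in reverse as the planting oracle: every disrupting/creating substitution
#' is checked to abolish (or be the only way to form) all allowed site types
#' for every simulated family, and every neutral SNP is checked to leave site
#' status unchanged on both alleles.
#'
#' @param config A [sim_config()] object.
#' @return List with `utrs` (data.frame `utr_id`, `gene`, `seq`; sequences
#'   carry the reference allele), `mirnas`, `families`, `pops`, and `truth`
#'   (one row per planted SNP: ids, class, family, site type, target allele,
#'   ancestral allele, polarization, latitude flag, and true per-population
#'   target/alt frequencies).
#' @export
plant_target_pairs <- function(config) {
  set.seed(config$rng_seed)
  mirnas <- config$mirnas
  mirnas$seed <- vapply(mirnas$mature_seq, derive_seed, character(1),
                        USE.NAMES = FALSE)
  mirnas$family_key <- mirnas$seed
  expressed <- mirnas[!(mirnas$name %in% config$unexpressed), , drop = FALSE]
  families <- group_families(expressed)
  fam_keys <- unique(mirnas$family_key)
  motifs_by_fam <- lapply(setNames(fam_keys, fam_keys), site_motifs)
  all_motifs <- motifs_by_fam
  pops <- .sim_pops(config)
  utrs <- data.frame(
    utr_id = sprintf("UTR%03d", seq_len(config$n_utrs)),
    gene = sprintf("GENE%03d", seq_len(config$n_utrs)),
    seq = vapply(seq_len(config$n_utrs), function(i)
      .random_dna(config$utr_length), character(1)),
    stringsAsFactors = FALSE)

  n_pairs <- config$n_disrupting + config$n_creating
  classes <- c(rep("disrupting", config$n_disrupting),
               rep("creating", config$n_creating),
               rep("neutral", config$n_neutral))
  lat_idx <- if (n_pairs > 0 && config$lat_effect$n > 0)
    seq_len(min(config$lat_effect$n, n_pairs)) else integer(0)

  occupied <- lapply(seq_len(config$n_utrs), function(i) integer(0))
  truth <- NULL
  snp_no <- 0L

  place_site <- function(utr_i, fam_row) {
    ## returns list(start, site_type, motif) for a fresh non-overlapping slot
    motifs <- site_motifs(fam_row$family_key)
    stype <- sample(config$site_types, 1L)
    motif <- motifs[[stype]]
    len <- nchar(motif)
    for (attempt in 1:100) {
      s <- sample.int(config$utr_length - len - 2L, 1L) + 1L  # 0-based, inside
      span <- (s - 8L):(s + len + 7L)
      if (any(span %in% occupied[[utr_i]])) next
      return(list(start = s, site_type = stype, motif = motif, len = len))
    }
    NULL
  }

  for (i in seq_along(classes)) {
    cls <- classes[i]
    placed <- FALSE
    for (attempt in 1:200) {
      utr_i <- sample.int(config$n_utrs, 1L)
      if (cls == "neutral") {
        seq <- utrs$seq[utr_i]
        pos <- sample.int(config$utr_length, 1L) - 1L
        if (any((pos - 8L):(pos + 8L) %in% occupied[[utr_i]])) next
        refb <- substr(seq, pos + 1L, pos + 1L)
        altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
        alt_seq <- seq
        substr(alt_seq, pos + 1L, pos + 1L) <- altb
        neutral_ok <- all(vapply(all_motifs, function(m) {
          (nrow(.sites_at(seq, pos, m, config$site_types)) > 0L) ==
            (nrow(.sites_at(alt_seq, pos, m, config$site_types)) > 0L)
        }, logical(1)))
        if (!neutral_ok) next
        snp_no <- snp_no + 1L
        anc <- if (runif(1) < config$p_ancestral_unknown) "unknown"
               else sample(c(refb, altb), 1L)
        p_alt <- simulate_frequencies(.draw_pbar(), config$F, nrow(pops))
        truth <- rbind(truth, data.frame(
          snp_id = sprintf("rs%06d", 100000L + snp_no),
          utr_id = utrs$utr_id[utr_i], gene = utrs$gene[utr_i],
          pos = pos, ref = refb, alt = altb, class = "neutral",
          family_key = NA_character_, site_type = NA_character_,
          target_allele = NA_character_, ancestral = anc,
          polarization = NA_character_, lat_snp = FALSE,
          t(setNames(p_alt, paste0("freq_", pops$pop))),
          stringsAsFactors = FALSE))
        occupied[[utr_i]] <- c(occupied[[utr_i]], (pos - 8L):(pos + 8L))
        placed <- TRUE
        break
      }
      fam_i <- ((i - 1L) %% nrow(families)) + 1L
      fam <- families[fam_i, ]
      slot <- place_site(utr_i, fam)
      if (is.null(slot)) next
      with_site <- utrs$seq[utr_i]
      substr(with_site, slot$start + 1L, slot$start + slot$len) <- slot$motif
      ## skip slots whose flanks accidentally complete other sites
      motifs <- site_motifs(fam$family_key)
      core_pos <- slot$start:(slot$start + slot$len - 1L)
      other <- motifs_by_fam[setdiff(names(motifs_by_fam), fam$family_key)]
      pick <- .pick_disruption(with_site, core_pos, motifs,
                               config$site_types, other)
      if (is.null(pick)) next
      ## target allele = base of the intact motif at the chosen position
      target_b <- substr(with_site, pick$pos + 1L, pick$pos + 1L)
      nontarget_b <- pick$alt
      without_site <- with_site
      substr(without_site, pick$pos + 1L, pick$pos + 1L) <- nontarget_b
      if (cls == "disrupting") {      # reference carries the target allele
        ref_seq <- with_site; refb <- target_b; altb <- nontarget_b
      } else {                        # alt allele completes the site
        ref_seq <- without_site; refb <- nontarget_b; altb <- target_b
      }
      ## confirm the pair with the classifier itself
      pr <- classify_pair(list(utr_id = utrs$utr_id[utr_i], seq = ref_seq),
                          list(snp_id = "tmp", pos = pick$pos,
                               ref = refb, alt = altb),
                          fam, config$site_types)
      if (is.null(pr) || pr$target_allele != target_b) next
      snp_no <- snp_no + 1L
      anc <- if (runif(1) < config$p_ancestral_unknown) "unknown"
             else if (runif(1) < config$p_ancestral_target) target_b
             else nontarget_b
      anc_is_target <- anc == target_b
      lat_snp <- i %in% lat_idx
      p_target <- .pair_freqs(config, pops,
                              anc_is_target = isTRUE(anc_is_target), lat_snp)
      p_alt <- if (altb == target_b) p_target else 1 - p_target
      pol <- polarize(list(ancestral = anc, target_allele = target_b,
                           nontarget_allele = nontarget_b,
                           target_in_reference = cls == "disrupting"))
      utrs$seq[utr_i] <- ref_seq
      occupied[[utr_i]] <- c(occupied[[utr_i]],
                             (slot$start - 8L):(slot$start + slot$len + 7L))
      truth <- rbind(truth, data.frame(
        snp_id = sprintf("rs%06d", 100000L + snp_no),
        utr_id = utrs$utr_id[utr_i], gene = utrs$gene[utr_i],
        pos = pick$pos, ref = refb, alt = altb, class = cls,
        family_key = fam$family_key, site_type = pr$site_type,
        target_allele = target_b, ancestral = anc,
        polarization = pol, lat_snp = lat_snp,
        t(setNames(p_alt, paste0("freq_", pops$pop))),
        stringsAsFactors = FALSE))
      placed <- TRUE
      break
    }
    if (!placed)
      .stopf("capacity error: could not place planted SNP %d (%s) after 200 attempts",
             i, cls)
  }
  if (!is.null(truth)) {
    truth <- truth[order(truth$utr_id, truth$pos), , drop = FALSE]
    rownames(truth) <- NULL
  }
  list(utrs = utrs, mirnas = mirnas, families = families, pops = pops,
       truth = truth)
}

## VCF 4.2 text writer for the simulated genotypes.
.write_vcf <- function(truth, gt, samples, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mirpopvar-simulator",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(truth)), function(i) {
    aa <- if (truth$ancestral[i] == "unknown") "." else truth$ancestral[i]
    paste(c(truth$utr_id[i], truth$pos[i] + 1L, truth$snp_id[i],
            truth$ref[i], truth$alt[i], ".", "PASS", paste0("AA=", aa),
            "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

.write_fasta <- function(names, seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(names)) {
    writeLines(paste0(">", names[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Emit fixture files for a simulated study
#'
#' Samples diploid genotypes (Hardy-Weinberg binomial within populations)
#' from the true per-population alt-allele frequencies and writes every file
#' the pipeline consumes: UTR FASTA, mature miRNA FASTA, VCF (with INFO/AA),
#' panel TSV, latitude TSV (the first population gets two collection points,
#' exercising the centroid), expression TSV, interaction TSV, and the ground
#' truth TSV extended with realized per-super-population counts.
#'
#' @param sim Result of [plant_target_pairs()].
#' @param config The same [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return List with `paths` (named file paths) and `truth` (ground truth
#'   including realized `count_`/`total_` columns per super-population).
#' @export
emit_fixtures <- function(sim, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$rng_seed + 1L)
  pops <- sim$pops
  truth <- sim$truth
  samples <- unlist(lapply(seq_len(nrow(pops)), function(i)
    sprintf("%s_S%03d", pops$pop[i], seq_len(config$samples_per_pop))))
  sample_pop <- rep(pops$pop, each = config$samples_per_pop)
  sample_sp <- rep(pops$super_pop, each = config$samples_per_pop)
  freq_cols <- paste0("freq_", pops$pop)

  gt <- matrix("", nrow(truth), length(samples))
  for (i in seq_len(nrow(truth))) {
    p_alt <- as.numeric(truth[i, freq_cols])
    p_s <- p_alt[match(sample_pop, pops$pop)]
    a1 <- rbinom(length(samples), 1L, p_s)
    a2 <- rbinom(length(samples), 1L, p_s)
    gt[i, ] <- paste0(a1, "|", a2)
    alt_n <- a1 + a2
    for (sp in SUPER_POPS) {
      sel <- sample_sp == sp
      alt_count <- sum(alt_n[sel])
      total <- 2L * sum(sel)
      tgt <- if (!is.na(truth$target_allele[i]) &&
                 truth$target_allele[i] == truth$ref[i])
        total - alt_count else alt_count
      truth[i, paste0("count_", sp)] <- tgt
      truth[i, paste0("total_", sp)] <- total
    }
  }

  paths <- list(
    utrs = file.path(out_dir, "utrs.fa"),
    mirnas = file.path(out_dir, "mirnas.fa"),
    vcf = file.path(out_dir, "snps.vcf"),
    panel = file.path(out_dir, "panel.tsv"),
    latitude = file.path(out_dir, "latitude.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    interactions = file.path(out_dir, "interactions.tsv"),
    truth = file.path(out_dir, "ground_truth.tsv"))

  .write_fasta(paste0(sim$utrs$utr_id, "|", sim$utrs$gene), sim$utrs$seq,
               paths$utrs)
  .write_fasta(sim$mirnas$name, sim$mirnas$mature_seq, paths$mirnas)
  .write_vcf(truth, gt, samples, paths$vcf)
  utils::write.table(data.frame(sample = samples, pop = sample_pop,
                                super_pop = sample_sp),
                     paths$panel, sep = "\t", quote = FALSE, row.names = FALSE)

  ## latitude table: first population split into two collection points whose
  ## mean reproduces its latitude
  lat <- data.frame(population = pops$pop, latitude = pops$latitude,
                    longitude = pops$longitude)
  lat2 <- rbind(
    data.frame(population = pops$pop[1],
               latitude = round(pops$latitude[1] + c(-2, 2), 3),
               longitude = round(pops$longitude[1] + c(-1, 1), 3)),
    lat[-1, ])
  utils::write.table(lat2, paths$latitude, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  expr <- data.frame(name = sim$mirnas$name,
                     expression = ifelse(sim$mirnas$name %in% config$unexpressed,
                                         0.1, round(runif(nrow(sim$mirnas), 50, 150), 2)))
  utils::write.table(expr, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  ## interactions: high-throughput evidence for a deterministic half of the
  ## planted pairs (first mature of the family), plus luciferase-only noise
  pair_rows <- truth[truth$class != "neutral", , drop = FALSE]
  inter <- NULL
  if (nrow(pair_rows) > 0L) {
    fam_first <- setNames(
      vapply(strsplit(sim$families$mirnas, ","), `[`, character(1), 1L),
      sim$families$family_key)
    flagged <- seq_len(nrow(pair_rows)) %% 2L == 1L
    inter <- data.frame(
      mirna = fam_first[pair_rows$family_key],
      gene = pair_rows$gene,
      evidence_methods = ifelse(flagged,
                                sample(c("HITS-CLIP", "PAR-CLIP", "PAR-CLIP;HITS-CLIP"),
                                       nrow(pair_rows), replace = TRUE),
                                "Luciferase reporter assay"),
      stringsAsFactors = FALSE)
  }
  inter <- rbind(inter, data.frame(mirna = "miR-122-5p", gene = "GENE999",
                                   evidence_methods = "Western blot"))
  utils::write.table(inter, paths$interactions, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  num_cols <- c(freq_cols)
  truth_out <- truth
  truth_out[num_cols] <- lapply(truth_out[num_cols], function(x)
    formatC(x, digits = 6, format = "f"))
  utils::write.table(truth_out, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(paths = paths, truth = truth)
}

#' Generate a complete fixture set in one call
#'
#' Convenience wrapper: [plant_target_pairs()] then [emit_fixtures()].
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return List with `sim` (planting result), `truth` (with realized
#'   counts), `paths`.
#' @export
simulate_fixtures <- function(config, out_dir) {
  sim <- plant_target_pairs(config)
  em <- emit_fixtures(sim, config, out_dir)
  list(sim = sim, truth = em$truth, paths = em$paths)
}
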