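## Target/near-target pairs: intersect biallelic SNPs with UTR seed sites,
## decide which allele forms the site, and polarize against ancestral and
## reference alleles.

POLARIZATION_CLASSES <- c("ancestral_target_lost", "derived_target_gained",
                          "ancestral_target_in_ref", "derived_nontarget_in_ref",
                          "unpolarized")

#' Substitute one allele into a UTR sequence
#'
#' @param utr UTR record (list/row with `utr_id`, `seq`) or plain string.
#' @param snp SNP record (list/row with `snp_id`, `pos` 0-based, `ref`, `alt`).
#' @param allele The base to place at `pos`; must be the SNP's ref or alt.
#' @return The UTR sequence with position `pos` set to `allele`.
#' @export
apply_allele <- function(utr, snp, allele) {
  seq <- if (is.character(utr)) utr else utr$seq
  if (!allele %in% c(snp$ref, snp$alt))
    .stopf("allele %s is neither ref nor alt of %s", allele, snp$snp_id)
  at <- substr(seq, snp$pos + 1L, snp$pos + 1L)
  if (at != snp$ref)
    .stopf("reference mismatch for %s: UTR has %s at pos %d, VCF REF is %s",
           snp$snp_id, at, snp$pos, snp$ref)
  substr(seq, snp$pos + 1L, snp$pos + 1L) <- allele
  seq
}

## Sites of one family overlapping a position, on an allele-substituted UTR.
.sites_at <- function(seq, pos, motifs, site_types) {
  sites <- .scan_seed(seq, motifs)
  sites <- sites[sites$site_type %in% site_types, , drop = FALSE]
  sites[sites$start <= pos & pos < sites$end, , drop = FALSE]
}

#' Classify a SNP as a target/near-target pair for one seed family
#'
#' Both allele-substituted sequences are scanned for the family's motifs,
#' restricted to sites whose half-open interval contains the SNP position. A
#' pair exists iff exactly one allele carries at least one overlapping site of
#' an allowed type; that allele is the target allele, and its most-specific
#' overlapping site (leftmost on ties) supplies the site type and coordinates.
#' SNPs where both or neither allele forms a site return `NULL` (for the
#' both-sites case the site merely changes type, which is not a
#' target/near-target pair).
#'
#' @param utr UTR record with `utr_id`, `seq`, optionally `gene`.
#' @param snp SNP record with `snp_id`, `pos` (0-based), `ref`, `alt`,
#'   optionally `ancestral` (base or `"unknown"`).
#' @param family List/row with `family_key` (the seed) and optionally `mirnas`.
#' @param site_types Allowed site types (default [default_site_types()]).
#' @return One-row data.frame describing the pair, or `NULL`.
#' @export
classify_pair <- function(utr, snp, family,
                          site_types = default_site_types()) {
  motifs <- site_motifs(family$family_key)
  ref_seq <- apply_allele(utr, snp, snp$ref)  # validates reference consistency
  alt_seq <- apply_allele(utr, snp, snp$alt)
  ref_sites <- .sites_at(ref_seq, snp$pos, motifs, site_types)
  alt_sites <- .sites_at(alt_seq, snp$pos, motifs, site_types)
  ref_has <- nrow(ref_sites) > 0L
  alt_has <- nrow(alt_sites) > 0L
  if (ref_has == alt_has) return(NULL)
  target_allele <- if (ref_has) snp$ref else snp$alt
  sites <- if (ref_has) ref_sites else alt_sites
  sites <- sites[order(match(sites$site_type, SITE_TYPES), sites$start), ,
                 drop = FALSE]
  best <- sites[1L, ]
  anc <- snp$ancestral
  if (is.null(anc) || is.na(anc)) anc <- "unknown"
  pair <- data.frame(
    snp_id = snp$snp_id,
    utr_id = utr$utr_id,
    gene = if (!is.null(utr$gene)) utr$gene else NA_character_,
    family_key = family$family_key,
    mirnas = if (!is.null(family$mirnas)) paste(family$mirnas, collapse = ",") else NA_character_,
    site_type = best$site_type,
    site_start = best$start,
    site_end = best$end,
    pos = snp$pos,
    ref = snp$ref,
    alt = snp$alt,
    ancestral = anc,
    target_allele = target_allele,
    nontarget_allele = if (ref_has) snp$alt else snp$ref,
    target_in_reference = ref_has,
    stringsAsFactors = FALSE)
  pair$polarization <- polarize(pair)
  pair
}

#' Polarize a target/near-target pair
#'
#' Truth table over (ancestral allele is target?, target allele in reference?):
#' ancestral target absent from the reference is an ancestral target lost in
#' the reference lineage; a derived target present in the reference is a
#' gained site; the two concordant cells are the unremarkable classes; an
#' unknown ancestral allele leaves the pair unpolarized.
#'
#' @param pair One-row data.frame from [classify_pair()] (fields
#'   `ancestral`, `target_allele`, `nontarget_allele`, `target_in_reference`).
#' @return One of `"ancestral_target_lost"`, `"derived_target_gained"`,
#'   `"ancestral_target_in_ref"`, `"derived_nontarget_in_ref"`,
#'   `"unpolarized"`.
#' @export
polarize <- function(pair) {
  anc <- pair$ancestral
  if (is.null(anc) || is.na(anc) ||
      !anc %in% c(pair$target_allele, pair$nontarget_allele))
    return("unpolarized")
  anc_is_target <- anc == pair$target_allele
  in_ref <- isTRUE(pair$target_in_reference)
  if (anc_is_target && !in_ref) "ancestral_target_lost"
  else if (!anc_is_target && in_ref) "derived_target_gained"
  else if (anc_is_target && in_ref) "ancestral_target_in_ref"
  else "derived_nontarget_in_ref"
}

#' Filter pairs by global target-allele frequency
#'
#' Retains segregating pairs whose pooled (global) target-allele frequency
#' lies in `[lower, upper]`, boundaries inclusive.
#'
#' @param pairs data.frame with a `global_freq` column.
#' @param lower,upper Frequency window (defaults 0.01 and 0.99).
#' @return The retained rows.
#' @export
frequency_filter <- function(pairs, lower = 0.01, upper = 0.99) {
  if (nrow(pairs) == 0L) return(pairs)
  if (any(is.na(pairs$global_freq)))
    .stopf("global target-allele frequency undefined for %d pair(s)",
           sum(is.na(pairs$global_freq)))
  pairs[pairs$global_freq >= lower & pairs$global_freq <= upper, , drop = FALSE]
}

#' Flag pairs with high-throughput experimental support
#'
#' A pair is experimentally detected iff some member of its seed family and
#' its gene co-occur in an interaction row whose evidence set intersects
#' the high-throughput crosslinking assays (PAR-CLIP, HITS-CLIP).
#'
#' @param pairs data.frame with `mirnas` (comma-joined) and `gene` columns.
#' @param interactions data.frame with columns `mirna`, `gene`,
#'   `evidence_methods` (separator `,` `;` or `|` for multiple methods).
#' @param methods Evidence methods counting as high-throughput.
#' @return `pairs` with a logical `experimentally_detected` column added.
#' @export
join_interactions <- function(pairs, interactions,
                              methods = c("PAR-CLIP", "HITS-CLIP")) {
  if (!all(c("mirna", "gene", "evidence_methods") %in% names(interactions)))
    .stopf("interaction table must have columns mirna, gene, evidence_methods")
  ev <- strsplit(interactions$evidence_methods, "[,;|]\\s*")
  ht <- vapply(ev, function(e) length(intersect(trimws(e), methods)) > 0L,
               logical(1))
  key <- paste(interactions$mirna[ht], interactions$gene[ht], sep = "\r")
  pairs$experimentally_detected <- vapply(seq_len(nrow(pairs)), function(i) {
    members <- strsplit(pairs$mirnas[i], ",", fixed = TRUE)[[1L]]
    any(paste(members, pairs$gene[i], sep = "\r") %in% key)
  }, logical(1))
  pairs
}

#' Read an interaction table
#'
#' miRTarBase-like TSV with columns `mirna`, `gene`, `evidence_methods`.
#'
#' @param path TSV file with header.
#' @return data.frame.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna", "gene", "evidence_methods")
  if (!all(need %in% names(df)))
    .stopf("malformed interaction table %s: need columns %s", path,
           paste(need, collapse = ", "))
  df
}

#' Read biallelic SNVs from a VCF
#'
#' Keeps biallelic single-nucleotide records only; indels and multi-allelic
#' records are excluded and counted. The ancestral allele is read from INFO
#' key `AA` (1000 Genomes dialect), upper-cased; values other than ref or alt
#' become `"unknown"`. VCF positions are 1-based; the returned `pos` is
#' 0-based on the UTR (conversion happens here, exactly once).
#'
#' @param path VCF 4.x file (plain text or gzipped) with GT genotypes.
#' @return List with `snps` (data.frame: `snp_id`, `utr_id`, `pos`, `ref`,
#'   `alt`, `ancestral`), `alt_dose` (SNP x sample matrix of alt-allele
#'   dosages, NA for missing genotypes), `ploidy_called` (matrix of called
#'   allele numbers per genotype), and `n_excluded` (non-SNV/multi-allelic
#'   record count).
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  if (nrow(fix) == 0L) {
    return(list(snps = data.frame(snp_id = character(), utr_id = character(),
                                  pos = integer(), ref = character(),
                                  alt = character(), ancestral = character()),
                alt_dose = matrix(integer(), 0, 0),
                ploidy_called = matrix(integer(), 0, 0), n_excluded = 0L))
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_excluded <- sum(!snv)
  aa <- toupper(vcfR::extract.info(v, "AA"))
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- which(snv)
  if (length(keep) == 0L) {
    return(list(snps = data.frame(snp_id = character(), utr_id = character(),
                                  pos = integer(), ref = character(),
                                  alt = character(), ancestral = character()),
                alt_dose = matrix(integer(), 0, ncol(gt)),
                ploidy_called = matrix(integer(), 0, ncol(gt)),
                n_excluded = n_excluded))
  }
  gt <- gt[keep, , drop = FALSE]
  ## dosage of the alt allele; handles phased and unphased separators
  alleles <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(c(NA_integer_, NA_integer_))
    a <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1L]]))
    length(a) <- 2L
    a
  })
  ## alleles has dim c(2, n_snp, n_sample)
  alt_dose <- apply(alleles, c(2, 3), function(a) {
    if (all(is.na(a))) NA_integer_ else sum(a == 1L, na.rm = TRUE)
  })
  called <- apply(alleles, c(2, 3), function(a) sum(!is.na(a)))
  snps <- data.frame(
    snp_id = fix[keep, "ID"],
    utr_id = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]) - 1L,
    ref = ref[keep],
    alt = alt[keep],
    ancestral = ifelse(is.na(aa[keep]) | !(aa[keep] == ref[keep] | aa[keep] == alt[keep]),
                       "unknown", aa[keep]),
    stringsAsFactors = FALSE)
  rownames(alt_dose) <- snps$snp_id
  rownames(called) <- snps$snp_id
  colnames(alt_dose) <- colnames(gt)
  colnames(called) <- colnames(gt)
  list(snps = snps, alt_dose = alt_dose, ploidy_called = called,
       n_excluded = n_excluded)
}

#' Read a sample panel
#'
#' 1000 Genomes panel dialect: TSV with columns `sample`, `pop`, `super_pop`.
#'
#' @param path TSV file with header.
#' @return data.frame with those three columns.
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "pop", "super_pop")
  if (!all(need %in% names(df)))
    .stopf("panel %s must have columns %s", path, paste(need, collapse = ", "))
  df[, need]
}
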