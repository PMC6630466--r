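## Seed-match scanning: mature microRNA seeds, canonical site motifs, and
## exact-match site detection on 3'UTR sequences.

#' Extract the seed of a mature microRNA
#'
#' The seed is the heptamer at positions 2-8 (1-based) of the mature sequence;
#' it is the primary determinant of canonical target recognition and defines
#' seed-family membership.
#'
#' @param mature_seq Mature microRNA sequence, RNA alphabet (A/C/G/U),
#'   5' to 3', at least 8 nt.
#' @return A 7-nt RNA string.
#' @examples
#' derive_seed("UGAGGUAGUAGGUUGUAUAGUU")  # let-7a-5p -> "GAGGUAG"
#' @export
derive_seed <- function(mature_seq) {
  if (length(mature_seq) != 1L || is.na(mature_seq))
    .stopf("mature_seq must be a single sequence")
  if (!.is_rna(mature_seq))
    .stopf("mature sequence contains non-RNA characters: %s", mature_seq)
  if (nchar(mature_seq) < 8L)
    .stopf("mature sequence shorter than 8 nt: %s", mature_seq)
  substr(mature_seq, 2L, 8L)
}

#' Canonical site motifs for a seed
#'
#' Maps a 7-nt seed to the DNA motifs its canonical site types match on the
#' mRNA-sense UTR sequence. The 7mer-m8 motif is the DNA reverse complement of
#' the full seed; the 6mer motif drops the m8-pairing base from its 5' end;
#' 7mer-A1 and 8mer append a literal adenosine opposite mature position 1
#' (a positional A in the UTR, not a complementarity requirement).
#'
#' @param seed 7-nt RNA seed (see [derive_seed()]).
#' @return Named character vector with elements `8mer`, `7mer-m8`, `7mer-A1`,
#'   `6mer` (DNA alphabet).
#' @examples
#' site_motifs("GAGGUAG")
#' @export
site_motifs <- function(seed) {
  if (length(seed) != 1L || !.is_rna(seed) || nchar(seed) != 7L)
    .stopf("seed must be a 7-nt RNA string, got: %s", seed)
  m8 <- .dna_revcomp(.rna_to_dna(seed))       # 7mer-m8: full seed match
  core <- substr(m8, 2L, 7L)                  # 6mer: seed positions 2-7
  c("8mer"    = paste0(m8, "A"),
    "7mer-m8" = m8,
    "7mer-A1" = paste0(core, "A"),
    "6mer"    = core)
}

## Anchor-based scan shared by find_seed_sites and classify_pair.
## An anchor is the start of the 6mer core match; each anchor is classified to
## its single most-specific type (8mer > 7mer-m8 > 7mer-A1 > 6mer) depending on
## whether the base 5' of the core pairs seed position 8 and whether the base
## 3' of the core is an A. Returns 0-based half-open coordinates.
.scan_seed <- function(seq, motifs) {
  n <- nchar(seq)
  core <- motifs[["6mer"]]
  if (n < nchar(core)) {
    return(data.frame(start = integer(), end = integer(),
                      site_type = character(), stringsAsFactors = FALSE))
  }
  hits <- Biostrings::matchPattern(Biostrings::DNAString(core),
                                   Biostrings::DNAString(seq))
  anchors <- Biostrings::start(hits)  # 1-based core starts
  if (length(anchors) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      site_type = character(), stringsAsFactors = FALSE))
  }
  m8_base <- substr(motifs[["7mer-m8"]], 1L, 1L)
  left  <- ifelse(anchors > 1L, substring(seq, anchors - 1L, anchors - 1L), "")
  right <- ifelse(anchors + 6L <= n, substring(seq, anchors + 6L, anchors + 6L), "")
  has_m8 <- left == m8_base
  has_a1 <- right == "A"
  type <- ifelse(has_m8 & has_a1, "8mer",
          ifelse(has_m8, "7mer-m8",
          ifelse(has_a1, "7mer-A1", "6mer")))
  start0 <- ifelse(has_m8, anchors - 2L, anchors - 1L)  # to 0-based
  len <- ifelse(type == "8mer", 8L, ifelse(type == "6mer", 6L, 7L))
  data.frame(start = as.integer(start0), end = as.integer(start0 + len),
             site_type = type, stringsAsFactors = FALSE)
}

#' Find canonical seed-match sites in a UTR
#'
#' Scans a UTR sequence (DNA alphabet, mRNA sense) for exact occurrences of a
#' microRNA's seed-match motifs. Overlapping sites are all reported, but each
#' seed-core anchor is reported once, as its most-specific site type
#' (precedence 8mer > 7mer-m8 > 7mer-A1 > 6mer); the `site_types` argument then
#' filters the report. Windows containing N never match.
#'
#' @param utr A list or one-row data.frame with fields `utr_id` and `seq`
#'   (DNA alphabet A/C/G/T/N), or a plain string (then `utr_id` is `"utr"`).
#' @param mirna A list or one-row data.frame with fields `name` and either
#'   `seed` or `mature_seq`; `family_key` defaults to the seed.
#' @param site_types Site types to report (subset of
#'   `c("8mer","7mer-m8","7mer-A1","6mer")`).
#' @return data.frame with columns `utr_id`, `start`, `end` (0-based,
#'   half-open), `site_type`, `family_key`, `mirnas`, sorted by
#'   (`start`, `site_type`).
#' @examples
#' mir <- list(name = "let-7a-5p", mature_seq = "UGAGGUAGUAGGUUGUAUAGUU")
#' find_seed_sites("AAACTACCTCAAAA", mir, "8mer")
#' @export
find_seed_sites <- function(utr, mirna, site_types = default_site_types()) {
  if (is.character(utr)) utr <- list(utr_id = "utr", seq = utr)
  bad <- setdiff(site_types, SITE_TYPES)
  if (length(bad)) .stopf("unknown site type(s): %s", paste(bad, collapse = ", "))
  seq <- toupper(utr$seq)
  if (nchar(seq) > 0L && !.is_dna(seq))
    .stopf("UTR %s contains non-DNA characters", utr$utr_id)
  seed <- if (!is.null(mirna$seed)) mirna$seed else derive_seed(mirna$mature_seq)
  fam <- if (!is.null(mirna$family_key)) mirna$family_key else seed
  mirnas <- if (!is.null(mirna$mirnas)) mirna$mirnas else mirna$name
  sites <- .scan_seed(seq, site_motifs(seed))
  sites <- sites[sites$site_type %in% site_types, , drop = FALSE]
  sites <- sites[order(sites$start, match(sites$site_type, SITE_TYPES)), ,
                 drop = FALSE]
  data.frame(utr_id = rep(utr$utr_id, nrow(sites)),
             sites,
             family_key = rep(fam, nrow(sites)),
             mirnas = rep(paste(mirnas, collapse = ","), nrow(sites)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Group mature microRNAs into seed families
#'
#' Mature microRNAs sharing the same seed target the same sites and are
#' analysed as one family; reports list every family member.
#'
#' @param mirnas data.frame with columns `name` and `mature_seq` (RNA).
#' @return data.frame with one row per family: `family_key` (the seed),
#'   `mirnas` (comma-joined member names, input order preserved), `n_members`.
#' @export
group_families <- function(mirnas) {
  if (anyDuplicated(mirnas$name))
    .stopf("duplicate mature microRNA name(s): %s",
           paste(unique(mirnas$name[duplicated(mirnas$name)]), collapse = ", "))
  seeds <- vapply(mirnas$mature_seq, derive_seed, character(1), USE.NAMES = FALSE)
  keys <- unique(seeds)
  members <- lapply(keys, function(k) mirnas$name[seeds == k])
  data.frame(family_key = keys,
             mirnas = vapply(members, paste, character(1), collapse = ","),
             n_members = lengths(members),
             stringsAsFactors = FALSE)
}

#' Restrict to highly expressed microRNAs
#'
#' @param mirnas data.frame with a `name` column.
#' @param expression Named numeric vector or two-column data.frame
#'   (name, expression) of non-negative expression values.
#' @param threshold Minimum expression retained; `NULL` uses the median of the
#'   supplied table (top-50 percent rule).
#' @return The rows of `mirnas` whose expression is `>= threshold`; microRNAs
#'   absent from the table are dropped with a warning.
#' @export
filter_expressed <- function(mirnas, expression, threshold = NULL) {
  if (is.data.frame(expression))
    expression <- setNames(as.numeric(expression[[2L]]), expression[[1L]])
  if (any(expression < 0, na.rm = TRUE))
    .stopf("negative expression values are invalid")
  if (is.null(threshold)) threshold <- stats::median(expression)
  missing <- setdiff(mirnas$name, names(expression))
  if (length(missing))
    .warnf("dropping %d microRNA(s) absent from the expression table: %s",
           length(missing), paste(missing, collapse = ", "))
  keep <- mirnas$name %in% names(expression) &
    expression[mirnas$name] >= threshold
  keep[is.na(keep)] <- FALSE
  mirnas[keep, , drop = FALSE]
}

#' Read mature microRNAs from FASTA
#'
#' miRBase mature dialect: header is the mature name, sequence in RNA alphabet.
#'
#' @param path FASTA file.
#' @return data.frame with columns `name`, `mature_seq`, `seed`, `family_key`.
#' @export
read_mirna_fasta <- function(path) {
  ss <- Biostrings::readRNAStringSet(path)
  nm <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  seqs <- as.character(ss)
  seeds <- vapply(seqs, derive_seed, character(1), USE.NAMES = FALSE)
  data.frame(name = nm, mature_seq = unname(seqs), seed = seeds,
             family_key = seeds, stringsAsFactors = FALSE)
}

#' Read UTR sequences from FASTA
#'
#' Headers follow the `utr_id|gene` convention; sequences are the transcript
#' sense strand, DNA alphabet.
#'
#' @param path FASTA file.
#' @return data.frame with columns `utr_id`, `gene`, `seq`.
#' @export
read_utr_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  parts <- strsplit(hdr, "|", fixed = TRUE)
  data.frame(utr_id = vapply(parts, `[`, character(1), 1L),
             gene = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, character(1)),
             seq = toupper(unname(as.character(ss))),
             stringsAsFactors = FALSE)
}

#' Read a two-column expression table
#'
#' @param path TSV with columns mature name and expression value (no header or
#'   header line starting with `name`).
#' @return Named numeric vector.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (is.character(df[[2L]][1L]) && is.na(suppressWarnings(as.numeric(df[[2L]][1L]))))
    df <- df[-1L, , drop = FALSE]
  setNames(as.numeric(df[[2L]]), df[[1L]])
}

#' Write seed sites as BED6
#'
#' 0-based half-open coordinates; name column is `family_key:site_type`,
#' score 0, strand `+` (UTRs are already transcript-sense).
#'
#' @param sites data.frame as returned by [find_seed_sites()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(sites$utr_id, sites$start, sites$end,
                    paste0(sites$family_key, ":", sites$site_type),
                    0L, "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
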