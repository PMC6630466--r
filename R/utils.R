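## Internal helpers shared across modules.

#' @importFrom stats median qnorm pnorm psignrank qsignrank rbeta rbinom rnorm
#'   runif setNames var lm coef pf pt
#' @importFrom utils read.delim write.table head
NULL

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.is_rna <- function(x) grepl("^[ACGU]+$", x)
.is_dna <- function(x) grepl("^[ACGTN]+$", x)

## U->T mapping for motif construction; motifs are DNA-alphabet.
.rna_to_dna <- function(x) chartr("U", "T", x)

.dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

SUPER_POPS <- c("AFR", "AMR", "EAS", "EUR", "SAS")

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Default target site-type set
#'
#' The canonical "target" classes used when deciding whether an allele forms a
#' site: 8mer, 7mer-m8 and 7mer-A1. The weaker 6mer class is opt-in.
#'
#' @return Character vector of site types.
#' @export
default_site_types <- function() c("8mer", "7mer-m8", "7mer-A1")
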