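## Per-population target-allele frequencies and Fst estimation.
##
## Fst is made explicit and configurable here: Wright's variance ratio on
## frequencies, Hudson's (1992) two-population estimator from allele counts
## (extended to k populations as a ratio of averages over pairs), and the
## Weir & Cockerham (1984) theta-hat variance-component estimator.

#' Per-super-population target-allele frequencies for one SNP
#'
#' Aggregates genotype allele counts sample -> population -> super-population.
#' Missing genotypes contribute to neither numerator nor denominator; the
#' global frequency is the pooled count ratio, not a mean of frequencies.
#'
#' @param alt_dose Named integer vector: alt-allele dosage per sample
#'   (NA = missing genotype).
#' @param called Named integer vector: number of called alleles per sample
#'   (2 for a diploid call, 0 for missing). Defaults to 2 wherever
#'   `alt_dose` is non-missing.
#' @param panel Panel data.frame ([read_panel()]).
#' @param target_allele_is_alt Logical; if `FALSE` the target allele is the
#'   reference allele and dosages are complemented.
#' @param unknown_samples `"drop"` (default; drop with a warning) or
#'   `"error"` for samples absent from the panel.
#' @return data.frame with one row per super-population (plus a `global`
#'   row): `super_pop`, `target_count`, `total_count`, `freq` (NA when no
#'   alleles were called).
#' @export
pop_frequencies <- function(alt_dose, panel, called = NULL,
                            target_allele_is_alt = TRUE,
                            unknown_samples = c("drop", "error")) {
  unknown_samples <- match.arg(unknown_samples)
  samples <- names(alt_dose)
  if (is.null(samples)) .stopf("alt_dose must be named by sample")
  if (is.null(called)) called <- ifelse(is.na(alt_dose), 0L, 2L)
  unknown <- setdiff(samples, panel$sample)
  if (length(unknown)) {
    if (unknown_samples == "error")
      .stopf("sample(s) absent from panel: %s", paste(unknown, collapse = ", "))
    .warnf("dropping %d sample(s) absent from panel", length(unknown))
    keep <- samples %in% panel$sample
    alt_dose <- alt_dose[keep]; called <- called[keep]; samples <- samples[keep]
  }
  sp <- panel$super_pop[match(samples, panel$sample)]
  dose <- ifelse(is.na(alt_dose), 0L, alt_dose)
  target <- if (target_allele_is_alt) dose else called - dose
  tc <- tapply(target, sp, sum)
  tot <- tapply(called, sp, sum)
  sps <- sort(unique(sp))
  out <- data.frame(super_pop = sps,
                    target_count = as.integer(tc[sps]),
                    total_count = as.integer(tot[sps]),
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(super_pop = "global",
                               target_count = sum(out$target_count),
                               total_count = sum(out$total_count)))
  out$freq <- ifelse(out$total_count > 0, out$target_count / out$total_count, NA)
  out
}

#' Wright's variance-ratio Fst from population frequencies
#'
#' `var(p) / (pbar (1 - pbar))` with the plain mean and population variance
#' (equal weights, divisor k) over the supplied frequencies; 0 by convention
#' when the mean frequency is 0 or 1.
#'
#' @param freqs Numeric vector of per-population allele frequencies
#'   (at least 2 defined values).
#' @return Fst in `[0, 1]`.
#' @export
fst_wright <- function(freqs) {
  freqs <- freqs[!is.na(freqs)]
  if (length(freqs) < 2L) .stopf("need >= 2 defined population frequencies")
  pbar <- mean(freqs)
  if (pbar <= 0 || pbar >= 1) return(0)
  mean((freqs - pbar)^2) / (pbar * (1 - pbar))
}

## Hudson's pairwise numerator/denominator from allele counts with
## sample-size correction; counts = matrix with columns target, total.
.hudson_nd <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  c(num, den)
}

#' Hudson's Fst estimator from allele counts
#'
#' The 1992 two-population estimator `1 - Hw/Hb` with sample-size correction;
#' for more than two populations the value is the ratio of the averaged
#' numerator to the averaged denominator over all population pairs. Negative
#' estimates are preserved.
#'
#' @param counts Matrix or data.frame, one row per population, columns
#'   `target` (target-allele count) and `total` (called allele count), or a
#'   two-column layout in that order.
#' @return List with `value`, and `num`/`den` components (reusable for
#'   multi-locus ratio-of-averages aggregation via [fst_genomewide()]).
#' @export
fst_hudson <- function(counts) {
  counts <- as.matrix(counts)
  tc <- counts[, 1L]; tot <- counts[, 2L]
  if (nrow(counts) < 2L) .stopf("need >= 2 populations")
  if (any(tot < 2)) .stopf("each population needs a total allele count >= 2")
  p <- tc / tot
  k <- nrow(counts)
  nd <- c(0, 0)
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k))
    nd <- nd + .hudson_nd(p[i], tot[i], p[j], tot[j])
  nd <- nd / choose(k, 2L)
  list(value = nd[1L] / nd[2L], num = nd[1L], den = nd[2L])
}

#' Weir & Cockerham (1984) theta-hat from allele counts
#'
#' Variance components a (among populations), b (among individuals within
#' populations) and c (within individuals) for one biallelic locus across k
#' populations with unequal sample sizes; theta = a / (a + b + c).
#' Heterozygote proportions default to their Hardy-Weinberg expectation
#' `2 p (1 - p)` per population when observed values are not supplied, which
#' is the only option when the input is allele counts rather than genotypes.
#'
#' @param counts As in [fst_hudson()] (allele counts; individuals are
#'   `total / 2` diploids per population).
#' @param het Optional numeric vector of observed heterozygote proportions
#'   per population.
#' @return List with `value`, `a`, `b`, `c` (components reusable for
#'   multi-locus ratio-of-sums aggregation).
#' @export
fst_weir_cockerham <- function(counts, het = NULL) {
  counts <- as.matrix(counts)
  tc <- counts[, 1L]; tot <- counts[, 2L]
  if (nrow(counts) < 2L) .stopf("need >= 2 populations")
  if (any(tot < 2)) .stopf("each population needs a total allele count >= 2")
  r <- nrow(counts)
  n <- tot / 2                         # diploid sample sizes
  p <- tc / tot
  if (is.null(het)) het <- 2 * p * (1 - p)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * het) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  list(value = if (denom == 0) 0 else a / denom, a = a, b = b, c = cc)
}

#' Multi-locus Fst by ratio of averages
#'
#' Aggregates per-locus estimator components (Hudson numerator/denominator or
#' Weir-Cockerham variance components) as the recommended ratio of averages,
#' rather than averaging per-locus ratios.
#'
#' @param counts_list List of per-locus count matrices (see [fst_hudson()]).
#' @param estimator `"hudson"` or `"weir_cockerham"`.
#' @return Single genome-wide Fst value.
#' @export
fst_genomewide <- function(counts_list, estimator = c("hudson", "weir_cockerham")) {
  estimator <- match.arg(estimator)
  if (estimator == "hudson") {
    parts <- vapply(counts_list, function(cn) {
      f <- fst_hudson(cn); c(f$num, f$den)
    }, numeric(2))
    sum(parts[1L, ]) / sum(parts[2L, ])
  } else {
    parts <- vapply(counts_list, function(cn) {
      f <- fst_weir_cockerham(cn); c(f$a, f$a + f$b + f$c)
    }, numeric(2))
    sum(parts[1L, ]) / sum(parts[2L, ])
  }
}

#' Per-locus Fst under a named estimator
#'
#' @param counts Count matrix as in [fst_hudson()].
#' @param estimator One of `"hudson"`, `"weir_cockerham"`,
#'   `"wright_variance"`.
#' @return Numeric Fst value (negative estimates preserved for the
#'   count-based estimators).
#' @export
fst_estimate <- function(counts,
                         estimator = c("hudson", "weir_cockerham",
                                       "wright_variance")) {
  estimator <- match.arg(estimator)
  switch(estimator,
         hudson = fst_hudson(counts)$value,
         weir_cockerham = fst_weir_cockerham(counts)$value,
         wright_variance = {
           counts <- as.matrix(counts)
           fst_wright(counts[, 1L] / counts[, 2L])
         })
}

#' Empirical upper-tail P-value for an observed Fst
#'
#' Add-one empirical percentile against a genome-wide or simulated null:
#' `P = (1 + #(null >= observed)) / (N + 1)`. Always in `(0, 1]` and monotone
#' non-increasing in the observed value.
#'
#' @param observed Observed Fst.
#' @param null_values Non-empty numeric vector of null Fst values.
#' @return Empirical P-value.
#' @export
empirical_pfst <- function(observed, null_values) {
  null_values <- null_values[!is.na(null_values)]
  if (length(null_values) == 0L) .stopf("null Fst distribution is empty")
  (1 + sum(null_values >= observed)) / (length(null_values) + 1)
}

#' Retain highly differentiated results
#'
#' Strict inequality `Fst > threshold`; output ordered by descending Fst
#' (ties broken by SNP id when present).
#'
#' @param results data.frame with an `fst` column (optionally `snp_id`).
#' @param fst_threshold Differentiation threshold (default 0.7).
#' @return The retained rows, descending in Fst.
#' @export
differentiation_filter <- function(results, fst_threshold = 0.7) {
  keep <- results[!is.na(results$fst) & results$fst > fst_threshold, ,
                  drop = FALSE]
  ord <- if ("snp_id" %in% names(keep)) order(-keep$fst, keep$snp_id)
         else order(-keep$fst)
  keep[ord, , drop = FALSE]
}
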