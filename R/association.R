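## Association analyses: target allele frequency vs sampling latitude, and
## the paired African-vs-European frequency-shift test.

#' Default list of recently migrated populations
#'
#' Populations sampled far from their ancestral geography are excluded from
#' the latitude regression by default; the list is overridable.
#'
#' @return Character vector of population codes.
#' @export
default_excluded_populations <- function() {
  c("CHD", "CEU", "ASW", "ACB", "GIH", "STU", "ITU")
}

#' Absolute latitude of the centroid of collection points
#'
#' Plate carree centroid: arithmetic mean of latitudes (and longitudes) of
#' the collection points, then the absolute value of the mean latitude.
#' Antipodal or hemisphere-symmetric points cancel — a documented limitation
#' of the planar centroid.
#'
#' @param points data.frame or matrix with latitude in the first column and
#'   longitude in the second (decimal degrees), one row per collection point.
#' @return Absolute centroid latitude in degrees.
#' @export
centroid_latitude <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) .stopf("need at least one collection point")
  if (any(abs(points[, 1L]) > 90)) .stopf("latitude outside [-90, 90]")
  abs(mean(points[, 1L]))
}

#' Read population latitude metadata
#'
#' TSV with columns `population`, `latitude`, `longitude`; multiple rows per
#' population are reduced to their centroid. Populations on the exclusion
#' list are flagged, not removed, so callers can report them.
#'
#' @param path TSV file with header.
#' @param excluded Population codes to flag as excluded
#'   (default [default_excluded_populations()]).
#' @return data.frame with `population`, `effective_latitude` (absolute
#'   centroid latitude), `excluded`.
#' @export
read_latitude_table <- function(path, excluded = default_excluded_populations()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("population", "latitude", "longitude")
  if (!all(need %in% names(df)))
    .stopf("latitude table %s must have columns %s", path,
           paste(need, collapse = ", "))
  pops <- unique(df$population)
  lat <- vapply(pops, function(p) {
    centroid_latitude(df[df$population == p, c("latitude", "longitude")])
  }, numeric(1))
  data.frame(population = pops, effective_latitude = unname(lat),
             excluded = pops %in% excluded, stringsAsFactors = FALSE)
}

#' Linear model of target allele frequency on absolute latitude
#'
#' Ordinary least squares `frequency = intercept + slope * |latitude|` over
#' the included populations; reports the adjusted R-squared and the
#' two-sided t-test p-value for the slope.
#'
#' @param records data.frame with columns `effective_latitude` and `freq`
#'   (one row per included population; excluded populations must already be
#'   removed).
#' @return List with `slope`, `intercept`, `slope_se`, `r2`, `r2_adjusted`,
#'   `p_value`, `n`.
#' @export
fit_latitude_model <- function(records) {
  n <- nrow(records)
  if (n < 3L) .stopf("need >= 3 populations for the latitude model")
  if (length(unique(records$effective_latitude)) < 2L)
    .stopf("degenerate design: all latitudes identical")
  fit <- stats::lm(freq ~ effective_latitude, data = records)
  sm <- summary(fit)
  co <- sm$coefficients
  list(slope = unname(co["effective_latitude", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       slope_se = unname(co["effective_latitude", "Std. Error"]),
       r2 = sm$r.squared,
       r2_adjusted = sm$adj.r.squared,
       p_value = unname(co["effective_latitude", "Pr(>|t|)"]),
       n = n)
}

## Exact two-sided signed-rank p-value via the null CDF (no ties, no zeros).
.signrank_p_exact <- function(w, n) {
  p_lo <- psignrank(w, n)
  p_hi <- psignrank(w - 1, n, lower.tail = FALSE)
  min(1, 2 * min(p_lo, p_hi))
}

## Normal approximation with continuity and tie correction (two-sided).
.signrank_p_approx <- function(w, n, ranks) {
  mu <- n * (n + 1) / 4
  tie_tab <- table(ranks)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Paired Wilcoxon signed-rank shift test with Hodges-Lehmann estimate
#'
#' Two-sided signed-rank test on the paired differences `b - a`, with the
#' Hodges-Lehmann pseudomedian (median of the Walsh averages of the
#' differences) as the shift estimate and a distribution-inversion confidence
#' interval. Zero differences are dropped before ranking (Wilcoxon's original
#' policy) and counted. The exact null distribution is used for `n <=
#' exact_n_max` without ties; otherwise a normal approximation with
#' continuity and tie correction.
#'
#' @param a,b Aligned numeric vectors (e.g. African and European target
#'   allele frequencies per site); differences are `b - a`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param exact_n_max Largest n for which the exact null is used (default 25).
#' @return List with `n_pairs` (after zero removal), `n_zeros`, `statistic`
#'   (V, the positive-rank sum), `p_value`, `shift_median`, `ci95` (length-2
#'   vector), `method` (`"exact"` or `"approx"`).
#' @export
paired_shift_test <- function(a, b, conf_level = 0.95, exact_n_max = 25L) {
  if (length(a) != length(b)) .stopf("paired vectors must have equal length")
  d <- b - a
  d <- d[!is.na(d)]
  n_zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    .stopf("undefined test: no non-zero paired differences remain")
  ranks <- rank(abs(d))
  w <- sum(ranks[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- n <= exact_n_max && !ties
  p <- if (exact) .signrank_p_exact(w, n) else .signrank_p_approx(w, n, ranks)
  walsh <- sort(c(outer(d, d, "+")[lower.tri(diag(n), diag = TRUE)] / 2))
  hl <- stats::median(walsh)
  m <- n * (n + 1) / 2
  alpha <- 1 - conf_level
  qu <- if (exact) qsignrank(alpha / 2, n)
        else floor(m / 2 + qnorm(alpha / 2) *
                   sqrt(n * (n + 1) * (2 * n + 1) / 24))
  if (qu <= 0) qu <- 1
  ql <- m - qu
  ci <- c(walsh[qu], walsh[min(m, ql + 1)])
  list(n_pairs = n, n_zeros = n_zeros, statistic = w, p_value = p,
       shift_median = hl, ci95 = ci,
       method = if (exact) "exact" else "approx")
}

#' Summarize an Fst distribution against a threshold
#'
#' Counts values at or above the threshold (inclusive), the corresponding
#' fraction, and histogram data for plotting the distribution. Values are
#' clamped to `[0, 1]` first (negative estimator noise).
#'
#' @param fst_values Non-empty numeric vector of Fst values.
#' @param threshold Inclusive threshold (default 0.3).
#' @param bin_width Histogram bin width (default 0.05).
#' @return List with `count`, `total`, `fraction`, `histogram`
#'   (data.frame: `bin_low`, `bin_high`, `count`).
#' @export
fst_distribution_report <- function(fst_values, threshold = 0.3,
                                    bin_width = 0.05) {
  fst_values <- fst_values[!is.na(fst_values)]
  if (length(fst_values) == 0L) .stopf("empty Fst vector")
  x <- pmin(1, pmax(0, fst_values))
  count <- sum(x >= threshold)
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  h <- hist(x, breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  list(count = count, total = length(x), fraction = count / length(x),
       histogram = data.frame(bin_low = h$breaks[-length(h$breaks)],
                              bin_high = h$breaks[-1L],
                              count = h$counts))
}

#' @importFrom graphics hist
NULL
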