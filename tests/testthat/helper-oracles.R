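## Independent oracles used across the suite. Each re-derives the quantity by
## the most naive route available (window-by-window comparison, literal
## textbook formulas, exhaustive enumeration) and never calls the package
## code path it checks.

## Naive seed-site scan: compare every window against every motif string,
## then resolve per-anchor precedence (anchor = start of the 6mer core).
oracle_scan <- function(seq, seed, site_types) {
  motifs <- c("8mer"    = paste0(dna_rc(chartr("U", "T", seed)), "A"),
              "7mer-m8" = dna_rc(chartr("U", "T", seed)),
              "7mer-A1" = paste0(substr(dna_rc(chartr("U", "T", seed)), 2, 7), "A"),
              "6mer"    = substr(dna_rc(chartr("U", "T", seed)), 2, 7))
  cand <- NULL
  for (ty in names(motifs)) {
    m <- motifs[[ty]]
    L <- nchar(m)
    if (nchar(seq) < L) next
    starts <- 0:(nchar(seq) - L)
    hits <- starts[substring(seq, starts + 1, starts + L) == m]
    for (s in hits) {
      anchor <- if (ty %in% c("8mer", "7mer-m8")) s + 1 else s
      cand <- rbind(cand, data.frame(start = s, end = s + L, site_type = ty,
                                     anchor = anchor))
    }
  }
  if (is.null(cand)) {
    return(data.frame(start = integer(), end = integer(),
                      site_type = character()))
  }
  prec <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
  out <- NULL
  for (a in unique(cand$anchor)) {
    grp <- cand[cand$anchor == a, ]
    best <- grp[order(match(grp$site_type, prec))[1], ]
    if (best$site_type %in% site_types)
      out <- rbind(out, best[, c("start", "end", "site_type")])
  }
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(),
                      site_type = character()))
  }
  out <- out[order(out$start, match(out$site_type, prec)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Reverse complement without Biostrings (independent route).
dna_rc <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
random_seed7 <- function() paste(sample(c("A", "C", "G", "U"), 7, replace = TRUE),
                                 collapse = "")

## Hudson two-population closed form (direct evaluation of 1 - Hw/Hb with
## the finite-sample correction).
oracle_hudson2 <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num / den
}

## Literal transcription of the 1984 variance components for one biallelic
## locus, heterozygosity at Hardy-Weinberg expectation.
oracle_wc <- function(target, total) {
  r <- length(target)
  ni <- total / 2
  pi <- target / total
  hi <- 2 * pi * (1 - pi)
  nbar <- sum(ni) / r
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi) / (r * nbar)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

## Exact signed-rank test by exhaustive enumeration over all sign
## assignments, plus the Hodges-Lehmann estimate from all Walsh averages.
oracle_signrank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  w_obs <- sum(ranks[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% ranks)
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  walsh <- sort(c(outer(d, d, "+")[lower.tri(diag(n), diag = TRUE)] / 2))
  list(p = min(1, 2 * min(p_lo, p_hi)), hl = median(walsh))
}

## Ordinary least squares by explicit normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

## Small complete fixture set shared by pipeline-level tests (cached per run).
shared_fixtures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(rng_seed = 7L)
      cache <<- c(simulate_fixtures(cfg, file.path(tempdir(), "mirpopvar_fx")),
                  list(config = cfg))
    }
    cache
  }
})

fixture_run_config <- function(fx, out_dir, ...) {
  run_config(utrs = fx$paths$utrs, mirnas = fx$paths$mirnas,
             vcf = fx$paths$vcf, panel = fx$paths$panel,
             expression = fx$paths$expression, expression_threshold = 1,
             interactions = fx$paths$interactions,
             latitude = fx$paths$latitude,
             out_dir = out_dir, rng_seed = 11L, ...)
}
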