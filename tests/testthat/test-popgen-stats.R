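test_that("pop_frequencies aggregates counts by super-population and pools", {
  panel <- data.frame(sample = c("a1", "a2", "e1", "e2"),
                      pop = c("P1", "P1", "P2", "P2"),
                      super_pop = c("AFR", "AFR", "EUR", "EUR"))
  dose <- c(a1 = 1L, a2 = 2L, e1 = 1L, e2 = 0L)
  pf <- pop_frequencies(dose, panel)
  expect_equal(pf$freq[pf$super_pop == "AFR"], 0.75)   # 3 of 4 alleles
  expect_equal(pf$freq[pf$super_pop == "EUR"], 0.25)
  expect_equal(pf$freq[pf$super_pop == "global"], 0.5) # pooled 4/8
  ## counts conserve: super-population counts sum to the pooled counts
  sp <- pf[pf$super_pop != "global", ]
  expect_equal(sum(sp$target_count), pf$target_count[pf$super_pop == "global"])
  ## missing genotypes leave the denominator
  dose2 <- c(a1 = NA, a2 = NA, e1 = 1L, e2 = 1L)
  pf2 <- pop_frequencies(dose2, panel)
  expect_true(is.na(pf2$freq[pf2$super_pop == "AFR"]))
  ## target allele = reference complements dosages
  pf3 <- pop_frequencies(dose, panel, target_allele_is_alt = FALSE)
  expect_equal(pf3$freq[pf3$super_pop == "AFR"], 0.25)
  ## unknown samples: drop+warn default, strict error mode
  dose4 <- c(a1 = 1L, zz = 2L)
  expect_warning(pop_frequencies(dose4, panel), "absent from panel")
  expect_error(pop_frequencies(dose4, panel, unknown_samples = "error"),
               "absent from panel")
})

test_that("Wright variance Fst matches direct arithmetic", {
  ## five printed super-population target-allele frequencies of a strongly
  ## differentiated SNP; oracle = direct variance-over-heterozygosity
  p <- c(0.0079, 0.0476, 0.6838, 0.0050, 0.1176)
  pb <- sum(p) / 5
  oracle <- (sum((p - pb)^2) / 5) / (pb * (1 - pb))
  expect_equal(fst_wright(p), oracle, tolerance = 1e-12)
  expect_equal(fst_wright(p), 0.469899, tolerance = 1e-6)
  expect_equal(fst_wright(c(0.3, 0.3, 0.3)), 0)
  expect_equal(fst_wright(c(1, 0)), 1)
  expect_equal(fst_wright(c(0, 0, 0)), 0)   # fixed: 0 by convention
  expect_error(fst_wright(c(0.5)), ">= 2")
})

test_that("Hudson estimator honours its closed form and limits", {
  expect_equal(fst_hudson(cbind(c(100, 0), c(100, 100)))$value, 1)
  same <- fst_hudson(cbind(c(30, 30), c(100, 100)))$value
  expect_lte(same, 0)                        # unbiased: at most 0
  got <- fst_hudson(cbind(c(6838, 50), c(10000, 10000)))$value
  expect_equal(got, oracle_hudson2(0.6838, 10000, 0.005, 10000),
               tolerance = 1e-12)
  expect_equal(got, 0.6756202, tolerance = 1e-7)  # frozen oracle value
  expect_error(fst_hudson(cbind(c(1, 1), c(1, 2))), "total")
  ## multi-population value = ratio of pair-averaged components
  cn <- cbind(c(10, 40, 70), c(100, 100, 100))
  f3 <- fst_hudson(cn)
  prs <- list(c(1, 2), c(1, 3), c(2, 3))
  nd <- sapply(prs, function(ij) {
    p <- cn[ij, 1] / cn[ij, 2]
    c((p[1] - p[2])^2 - p[1] * (1 - p[1]) / (cn[ij[1], 2] - 1) -
        p[2] * (1 - p[2]) / (cn[ij[2], 2] - 1),
      p[1] * (1 - p[2]) + p[2] * (1 - p[1]))
  })
  expect_equal(f3$value, mean(nd[1, ]) / mean(nd[2, ]), tolerance = 1e-12)
})

test_that("Weir-Cockerham theta equals the textbook variance components", {
  expect_lt(abs(fst_weir_cockerham(cbind(c(50, 50), c(100, 100)))$value), 0.02)
  expect_equal(fst_weir_cockerham(cbind(c(1000, 0), c(1000, 1000)))$value, 1)
  set.seed(106)
  for (i in 1:25) {
    tot <- sample(c(40, 60, 120, 200), 3, replace = TRUE)
    tc <- sapply(tot, function(n) sample.int(n - 1, 1))
    got <- fst_weir_cockerham(cbind(tc, tot))$value
    expect_equal(got, oracle_wc(tc, tot), tolerance = 1e-12)
  }
})

test_that("estimators agree at the analytic limits", {
  ## identical populations: Wright is exactly 0; the unbiased count-based
  ## estimators approach 0 from below as sample size grows
  expect_equal(fst_wright(c(0.4, 0.4, 0.4)), 0, tolerance = 1e-12)
  big <- cbind(c(2e9, 2e9), c(4e9, 4e9))
  expect_lt(abs(fst_hudson(big)$value), 1e-9)
  expect_lt(abs(fst_weir_cockerham(big)$value), 1e-9)
  ## fixed opposite alleles: Hudson and Weir-Cockerham exactly 1
  opp <- cbind(c(100, 0), c(100, 100))
  expect_equal(fst_hudson(opp)$value, 1, tolerance = 1e-9)
  expect_equal(fst_weir_cockerham(opp)$value, 1, tolerance = 1e-9)
})

test_that("empirical_pfst is an add-one upper-tail percentile", {
  null999 <- seq_len(999) / 1000
  expect_equal(empirical_pfst(2, null999), 1 / 1000)   # above all null values
  expect_equal(empirical_pfst(0, null999), 1)          # at or below the minimum
  ## direct counting: 500 of 999 null values sit at or above the median
  expect_equal(empirical_pfst(median(null999), null999), (1 + 500) / 1000)
  ## monotone non-increasing, bounded in (0, 1]
  set.seed(107)
  null <- runif(500)
  obs <- sort(runif(50))
  p <- vapply(obs, empirical_pfst, numeric(1), null_values = null)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= 1))
  ## inserting the observed value into its own null keeps P >= 1/(N+1)
  expect_gte(empirical_pfst(0.9, c(null, 0.9)), 1 / (length(null) + 2))
  expect_error(empirical_pfst(0.5, numeric(0)), "empty")
})

test_that("differentiation_filter keeps strict exceedances in descending order", {
  res <- data.frame(snp_id = c("s1", "s2", "s3"),
                    fst = c(0.69, 0.8239, 0.7074))
  out <- differentiation_filter(res, 0.7)
  expect_identical(out$snp_id, c("s2", "s3"))
  expect_equal(out$fst, c(0.8239, 0.7074))   # descending, as ranked tables
  expect_equal(nrow(differentiation_filter(res, 0.9)), 0L)
  all_pos <- differentiation_filter(res, 0)
  expect_equal(nrow(all_pos), 3L)
  expect_equal(nrow(differentiation_filter(res[0, ], 0.7)), 0L)
})

test_that("genome-wide ratio-of-averages recovers the simulated F", {
  set.seed(108)
  counts <- lapply(1:400, function(i) {
    p <- simulate_frequencies(runif(1, 0.1, 0.9), 0.15, 5)
    tc <- rbinom(5, 200, p)
    cbind(tc, 200)
  })
  expect_lt(abs(fst_genomewide(counts, "hudson") - 0.15), 0.04)
  expect_lt(abs(fst_genomewide(counts, "weir_cockerham") - 0.15), 0.04)
})
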