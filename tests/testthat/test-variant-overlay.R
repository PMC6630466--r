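let7_fam <- list(family_key = "GAGGUAG", mirnas = "let-7a-5p")

test_that("apply_allele substitutes a single base and checks the reference", {
  utr <- list(utr_id = "u", seq = "AAACTACCTCAAAA")
  snp <- list(snp_id = "rs1", pos = 6L, ref = "C", alt = "G")
  expect_identical(apply_allele(utr, snp, "G"), "AAACTAGCTCAAAA")
  expect_identical(apply_allele(utr, snp, "C"), utr$seq)
  bad <- list(snp_id = "rs2", pos = 0L, ref = "C", alt = "G")
  expect_error(apply_allele(utr, bad, "G"), "reference mismatch.*rs2")
  expect_error(apply_allele(utr, snp, "T"), "neither ref nor alt")
})

test_that("classify_pair detects a site toggled by the SNP base", {
  utr <- list(utr_id = "u", gene = "g", seq = "AAACTACCTCAAAA")
  snp <- list(snp_id = "rs1", pos = 6L, ref = "C", alt = "G")
  pr <- classify_pair(utr, snp, let7_fam)
  expect_identical(pr$target_allele, "C")
  expect_identical(pr$nontarget_allele, "G")
  expect_identical(pr$site_type, "8mer")
  expect_equal(pr$site_start, 3L)
  expect_equal(pr$site_end, 11L)
  expect_true(pr$target_in_reference)
  ## SNP away from any motif window on both alleles
  far <- list(snp_id = "rs2", pos = 13L, ref = "A", alt = "G")
  expect_null(classify_pair(utr, far, let7_fam))
})

test_that("classify_pair returns none when both alleles keep an overlapping site", {
  ## frozen case found by brute-force search over substitutions in planted
  ## motif contexts: both alleles carry an allowed site containing pos
  utr <- list(utr_id = "u", seq = "ATCCCTACCTACCTCAACTGTATA")
  snp <- list(snp_id = "rsB", pos = 10L, ref = "A", alt = "C")
  ref_sites <- nrow(find_seed_sites(utr$seq, list(name = "m", seed = "GAGGUAG")))
  expect_gt(ref_sites, 0)
  expect_null(classify_pair(utr, snp, let7_fam))
})

test_that("classify_pair equals full-rescan brute force on random fixtures", {
  set.seed(104)
  checked <- 0
  for (i in 1:300) {
    seed <- random_seed7()
    motifs <- site_motifs(seed)
    bg <- random_dna(60)
    s <- sample(10:40, 1)
    seq <- bg
    substr(seq, s + 1, s + 8) <- motifs[["8mer"]]
    pos <- s + sample(0:7, 1) - 1 + sample(0:2, 1)  # in or near the site
    pos <- max(0, min(nchar(seq) - 1, pos))
    refb <- substr(seq, pos + 1, pos + 1)
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    utr <- list(utr_id = "u", seq = seq)
    snp <- list(snp_id = "rs", pos = pos, ref = refb, alt = altb)
    got <- classify_pair(utr, snp, list(family_key = seed))
    ## oracle: full rescans of both allele sequences, overlap filter by hand
    alt_seq <- seq; substr(alt_seq, pos + 1, pos + 1) <- altb
    ov <- function(sq) {
      st <- oracle_scan(sq, seed, default_site_types())
      st[st$start <= pos & pos < st$end, , drop = FALSE]
    }
    r <- ov(seq); a <- ov(alt_seq)
    if ((nrow(r) > 0) == (nrow(a) > 0)) {
      expect_null(got)
    } else {
      checked <- checked + 1
      expect_identical(got$target_allele, if (nrow(r) > 0) refb else altb)
      best <- (if (nrow(r) > 0) r else a)
      best <- best[order(match(best$site_type,
                               c("8mer", "7mer-m8", "7mer-A1", "6mer")),
                         best$start), ]
      expect_identical(got$site_type, best$site_type[1])
      expect_equal(got$site_start, best$start[1])
    }
  }
  expect_gt(checked, 100)  # the construction must actually exercise pairs
})

test_that("relabeling ref and alt flips reference status, not the target allele", {
  set.seed(105)
  for (i in 1:50) {
    seed <- random_seed7()
    motifs <- site_motifs(seed)
    seq <- random_dna(50)
    s <- sample(5:35, 1)
    substr(seq, s + 1, s + 8) <- motifs[["8mer"]]
    pos <- s + sample(0:7, 1)
    refb <- substr(seq, pos + 1, pos + 1)
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    fam <- list(family_key = seed)
    p1 <- classify_pair(list(utr_id = "u", seq = seq),
                        list(snp_id = "rs", pos = pos, ref = refb, alt = altb),
                        fam)
    swapped <- seq; substr(swapped, pos + 1, pos + 1) <- altb
    p2 <- classify_pair(list(utr_id = "u", seq = swapped),
                        list(snp_id = "rs", pos = pos, ref = altb, alt = refb),
                        fam)
    expect_identical(is.null(p1), is.null(p2))
    if (!is.null(p1)) {
      expect_identical(p1$target_allele, p2$target_allele)
      expect_identical(p1$target_in_reference, !p2$target_in_reference)
    }
  }
  succeed()
})

test_that("polarize covers the 2x2 grid plus unknown, mutually exclusively", {
  grid <- expand.grid(anc_is_target = c(TRUE, FALSE),
                      in_ref = c(TRUE, FALSE))
  got <- apply(grid, 1, function(g) {
    polarize(list(ancestral = if (g[["anc_is_target"]]) "C" else "G",
                  target_allele = "C", nontarget_allele = "G",
                  target_in_reference = g[["in_ref"]]))
  })
  expect_setequal(got, c("ancestral_target_in_ref", "derived_target_gained",
                         "ancestral_target_lost", "derived_nontarget_in_ref"))
  expect_equal(anyDuplicated(got), 0L)
  expect_identical(polarize(list(ancestral = "unknown", target_allele = "C",
                                 nontarget_allele = "G",
                                 target_in_reference = TRUE)), "unpolarized")
  ## Fig-1-style rows
  expect_identical(polarize(list(ancestral = "C", target_allele = "C",
                                 nontarget_allele = "G",
                                 target_in_reference = FALSE)),
                   "ancestral_target_lost")
  expect_identical(polarize(list(ancestral = "G", target_allele = "C",
                                 nontarget_allele = "G",
                                 target_in_reference = TRUE)),
                   "derived_target_gained")
})

test_that("frequency_filter applies the inclusive 0.01-0.99 window", {
  pairs <- data.frame(snp_id = c("a", "b", "c", "d"),
                      global_freq = c(0.5, 0.005, 0.01, 0.995))
  kept <- frequency_filter(pairs)
  expect_identical(kept$snp_id, c("a", "c"))  # boundaries inclusive
  expect_error(frequency_filter(data.frame(snp_id = "x", global_freq = NA)),
               "undefined")
})

test_that("join_interactions flags only high-throughput-evidence rows", {
  pairs <- data.frame(snp_id = c("rs13432040", "rs2"),
                      mirnas = c("miR-561-5p,miR-24-3p", "miR-9-5p"),
                      gene = c("CASP10", "OTHER"))
  inter <- data.frame(mirna = c("miR-24-3p", "miR-9-5p", "miR-1-3p"),
                      gene = c("CASP10", "OTHER", "CASP10"),
                      evidence_methods = c("HITS-CLIP", "Luciferase reporter",
                                           "PAR-CLIP"))
  out <- join_interactions(pairs, inter)
  expect_identical(out$experimentally_detected, c(TRUE, FALSE))
})

test_that("read_snp_vcf keeps biallelic SNVs and converts coordinates once", {
  d <- withr::local_tempdir()
  vcf <- file.path(d, "t.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    "UTR1\t7\trs1\tC\tG\t.\tPASS\tAA=C\tGT\t0|1\t1|1",
    "UTR1\t9\trs2\tA\tAT\t.\tPASS\tAA=A\tGT\t0|0\t0|1",    # indel: dropped
    "UTR1\t11\trs3\tA\tC,G\t.\tPASS\tAA=A\tGT\t0|1\t0|2",  # multi-allelic
    "UTR2\t3\trs4\tT\tA\t.\tPASS\tAA=G\tGT\t.|.\t0|1"      # AA not ref/alt
  ), vcf)
  v <- read_snp_vcf(vcf)
  expect_identical(v$snps$snp_id, c("rs1", "rs4"))
  expect_equal(v$n_excluded, 2L)
  expect_equal(v$snps$pos, c(6L, 2L))        # 1-based VCF -> 0-based UTR
  expect_identical(v$snps$ancestral, c("C", "unknown"))
  expect_equal(unname(v$alt_dose["rs1", ]), c(1L, 2L))
  expect_true(is.na(v$alt_dose["rs4", "S1"]))
  expect_equal(unname(v$ploidy_called["rs4", ]), c(0L, 2L))
})
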