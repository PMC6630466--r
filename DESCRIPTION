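Package: mirpopvar
Title: Population Variation at MicroRNA Target Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects canonical microRNA seed-match sites in 3'UTR sequences,
    classifies biallelic SNPs into target/near-target allele pairs, polarizes
    them against ancestral and reference alleles, and quantifies population
    differentiation of the target allele (Fst under several estimators,
    empirical P-values against a null distribution). Includes the two
    association analyses used in studies of target-site variation across
    human populations: an ordinary least-squares model of target allele
    frequency on absolute sampling latitude, and a paired Wilcoxon
    signed-rank shift test (with Hodges-Lehmann pseudomedian and
    distribution-inversion confidence interval) between African and European
    target allele frequencies. A synthetic-data generator produces
    ground-truthed fixtures (UTR FASTA, mature microRNA FASTA, VCF with
    Balding-Nichols population structure and ancestral-allele annotation,
    sample panel, latitude, expression and interaction tables) so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
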