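test_that("degenerate pairs are flagged non-testable", {
  cfg <- small_config(n = 200, seed = 2)
  co <- small_cohort(cfg)
  g1 <- co$geno$genotypes[, 1]
  res <- test_pair(g1, rep(0L, length(g1)), co$covars, co$labels)
  expect_false(res$testable)
  expect_true(is.na(res$p12))
  single <- test_single(rep(1L, length(g1)), co$covars, co$labels)
  expect_false(single$testable)
})

test_that("interaction test is symmetric in the two SNPs", {
  cfg <- small_config(n = 500, seed = 12, b12 = 0.5)
  co <- small_cohort(cfg)
  g1 <- co$geno$genotypes[, "geneA_snp01"]
  g2 <- co$geno$genotypes[, "geneB_snp01"]
  r12 <- test_pair(g1, g2, co$covars, co$labels, marginals = FALSE)
  r21 <- test_pair(g2, g1, co$covars, co$labels, marginals = FALSE)
  expect_equal(r12$b12, r21$b12, tolerance = 1e-9)
  expect_equal(r12$p12, r21$p12, tolerance = 1e-9)
})

test_that("cross-gene scan enumerates all pairs in stable order", {
  cfg <- small_config(n = 300, seed = 14)
  co <- small_cohort(cfg)
  sc <- cross_gene_scan(co$geno, "geneA", "geneB", co$covars, co$labels)
  expect_equal(nrow(sc), 6 * 2)
  expect_equal(sc$rsid1, rep(sort(unique(sc$rsid1)), each = 2))
  expect_error(cross_gene_scan(co$geno, "geneA",
                               c("geneA_snp01", "geneB_snp01"),
                               co$covars, co$labels), "overlap")
  # empty gene set
  sc0 <- cross_gene_scan(co$geno, character(0), "geneB", co$covars,
                         co$labels)
  expect_equal(nrow(sc0), 0)
})

test_that("fixed-SNP scan equals per-pair calls and skips itself", {
  cfg <- small_config(n = 400, seed = 15, b12 = 0.4)
  co <- small_cohort(cfg)
  fs <- fixed_snp_scan(co$geno, "geneB_snp01", co$covars, co$labels)
  expect_equal(nrow(fs), ncol(co$geno$genotypes) - 1)
  expect_false("geneB_snp01" %in% fs$rsid2)
  k <- which(fs$rsid2 == "geneA_snp01")
  direct <- test_pair(co$geno$genotypes[, "geneB_snp01"],
                      co$geno$genotypes[, "geneA_snp01"],
                      co$covars, co$labels, marginals = FALSE)
  expect_equal(fs$b12[k], direct$b12, tolerance = 1e-10)
  expect_equal(fs$p12[k], direct$p12, tolerance = 1e-10)
  expect_error(fixed_snp_scan(co$geno, "rs_missing", co$covars,
                              co$labels), "rs_missing")
})

test_that("missing genotypes reduce n_used (complete-case per pair)", {
  cfg <- small_config(n = 500, seed = 16, missing_rate = 0.05)
  co <- small_cohort(cfg)
  g1 <- co$geno$genotypes[, 1]
  g2 <- co$geno$genotypes[, "geneB_snp01"]
  res <- test_pair(g1, g2, co$covars, co$labels, marginals = FALSE)
  expect_equal(res$n_used, sum(!is.na(g1) & !is.na(g2)))
  expect_lt(res$n_used, length(g1))
})

test_that("wald and lrt p-values agree asymptotically", {
  cfg <- small_config(n = 6142, seed = 18)
  co <- small_cohort(cfg)
  ratios <- c()
  set.seed(1)
  picks <- expand.grid(a = paste0("geneA_snp0", 1:6),
                       b = paste0("geneB_snp0", 1:2),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(picks))) {
    g1 <- co$geno$genotypes[, picks$a[k]]
    g2 <- co$geno$genotypes[, picks$b[k]]
    lrt <- test_pair(g1, g2, co$covars, co$labels,
                     cfg = scan_config(test = "lrt"), marginals = FALSE)
    wld <- test_pair(g1, g2, co$covars, co$labels,
                     cfg = scan_config(test = "wald"), marginals = FALSE)
    ratios <- c(ratios, abs(log10(lrt$p12 / wld$p12)))
  }
  expect_lt(median(ratios), 0.1)
})

test_that("a strong planted main effect is detected", {
  hits <- 0
  for (s in 1:20) {
    genes <- list(gene_spec("g", maf = 0.3))
    cfg <- sim_config(n_individuals = 6142, genes = genes,
                      main_effects = c(g_snp01 = 1.0),
                      interaction_effects = NULL, seed = 100 + s)
    co <- small_cohort(cfg)
    res <- test_single(co$geno$genotypes[, 1], co$covars, co$labels)
    hits <- hits + (res$p < 0.05)
  }
  expect_equal(hits, 20)
})

test_that("sex-stratified scan subsets and drops the sex covariate", {
  cfg <- small_config(n = 800, seed = 20)
  co <- small_cohort(cfg)
  sc_f <- sex_stratified_scan(co$geno, "geneA", "geneB", co$covars,
                              co$labels, sex = 1)
  n_female <- sum(co$covars$sex[match(names(co$labels),
                                      co$covars$individual_id)] == 1)
  expect_equal(unique(sc_f$n_used), n_female)
  expect_equal(nrow(sc_f), 12)
})
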