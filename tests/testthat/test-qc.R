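test_that("snp_stats handles fixed and trivial columns", {
  g <- cbind(a = c(0L, 0L, 0L), b = c(0L, 1L, 2L), c = c(NA, NA, NA))
  meta <- data.frame(rsid = c("a", "b", "c"), gene = "g", chrom = 1,
                     pos = 1:3, ea = "A", nea = "C", minor_allele = "A")
  st <- snp_stats(genotype_matrix(g, meta))
  expect_equal(st$maf, c(0, 0.5, NA))
  expect_equal(st$call_rate, c(1, 1, 0))
  expect_equal(st$defined, c(TRUE, TRUE, FALSE))
})

test_that("estimated MAF of a simulated rare SNP is unbiased", {
  cfg <- sim_config(n_individuals = 10000,
                    genes = list(gene_spec("g", maf = 0.06)),
                    interaction_effects = NULL, seed = 21)
  st <- snp_stats(simulate_genotypes(cfg))
  ci <- binom_ci99(20000, 0.06) / 20000
  expect_gte(st$maf, ci[1])
  expect_lte(st$maf, ci[2])
})

test_that("HWE exact test: conventions and enumeration oracle", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 42), 1)
  # modal heterozygote count has P = 1 by construction
  # (all configurations are at most as probable as the mode)
  hs <- seq.int(20 %% 2, 20, by = 2)
  pr <- vapply(hs, function(h) {
    factorial(50) / (factorial((20 - h) / 2) * factorial(h) *
                       factorial((80 - h) / 2)) * 2^h
  }, 0)
  h_mode <- hs[which.max(pr)]
  expect_equal(hwe_exact_test((20 - h_mode) / 2, h_mode,
                              (80 - h_mode) / 2), 1)
  expect_equal(hwe_exact_test(5, 10, 5), hwe_oracle(5, 10, 5))
  expect_equal(hwe_exact_test(40, 4, 6), hwe_oracle(40, 4, 6))
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("individual filters drop high-missingness and duplicates", {
  set.seed(31)
  n <- 60
  g <- matrix(rbinom(n * 40, 2, 0.3), n, 40)
  g[1, 1:10] <- NA              # 25% missing
  g[5, ] <- g[4, ]              # planted duplicate
  ids <- sprintf("i%02d", 1:n)
  meta <- data.frame(rsid = sprintf("s%02d", 1:40), gene = "g",
                     chrom = 1, pos = 1:40, ea = "A", nea = "C",
                     minor_allele = "A")
  gm <- genotype_matrix(g, meta, ids)
  pcs <- as.data.frame(matrix(rnorm(n * 5), n,
                              dimnames = list(NULL, paste0("PC", 1:5))))
  res <- individual_filters(gm, pcs)
  expect_true("i01" %in% res$dropped_missing)
  expect_identical(res$dropped_duplicate, "i05")  # first copy kept
  expect_false("i04" %in% res$dropped_duplicate)
  expect_false("i01" %in% res$kept)
})

test_that("clean homogeneous data passes individual filters untouched", {
  # enough SNPs that no two individuals share a genotype vector
  genes <- list(gene_spec("g", maf = rep(0.3, 60), blocks = rep(1, 60)))
  cfg <- sim_config(n_individuals = 200, genes = genes,
                    interaction_effects = NULL, seed = 6)
  gm <- simulate_genotypes(cfg)
  pcs <- simulate_covariates(cfg)[paste0("PC", 1:5)]
  res <- individual_filters(gm, pcs)
  expect_identical(res$kept, gm$individual_ids)
})

test_that("ancestry outliers beyond 8 SD are dropped", {
  cfg <- small_config(n = 200, seed = 6)
  co <- small_cohort(cfg)
  pcs <- co$covars[paste0("PC", 1:5)]
  pcs$PC1[7] <- 200
  res <- individual_filters(co$geno, pcs)
  expect_identical(res$dropped_ancestry, co$geno$individual_ids[7])
})

test_that("sex-mismatch check is a stub with warning", {
  cfg <- small_config(n = 50, seed = 6)
  co <- small_cohort(cfg)
  expect_warning(
    individual_filters(co$geno, co$covars[paste0("PC", 1:5)],
                       reported_sex = co$covars$sex),
    "sex-chromosome")
})

test_that("union QC keeps what either protocol keeps", {
  cfg <- small_config(n = 400, seed = 17)
  co <- small_cohort(cfg)
  pcs <- co$covars[paste0("PC", 1:5)]
  # identical protocols: union equals the single-protocol result
  u1 <- union_qc(co$geno, pcs, qc_thresholds(), qc_thresholds())
  single_snps <- snp_stats(co$geno)
  pass <- with(single_snps, maf >= 0.01 & call_rate >= 0.95 &
                 hwe_p >= 1e-7)
  expect_setequal(u1$report$kept_snps, single_snps$rsid[pass])

  # protocol B passes everything -> everything retained
  lax <- qc_thresholds(ind_missing_max = 1, het_outlier_sd = 1e6,
                       ancestry_outlier_sd = 1e6, maf_min = 0,
                       snp_missing_max = 1, hwe_p_min = 1e-300)
  u2 <- union_qc(co$geno, pcs, qc_thresholds(maf_min = 0.49), lax)
  expect_setequal(u2$report$kept_snps, co$geno$snp_meta$rsid)

  # a SNP failing A's MAF filter but passing B's is retained
  strictA <- qc_thresholds(maf_min = 0.22)   # drops the MAF-0.2 block
  u3 <- union_qc(co$geno, pcs, strictA, qc_thresholds())
  failing_a <- setdiff(co$geno$snp_meta$rsid, u3$report$protocolA$snps)
  expect_true(length(failing_a) > 0)
  expect_true(all(failing_a %in% u3$report$kept_snps))

  # union monotonicity
  expect_true(all(u3$report$protocolA$snps %in% u3$report$kept_snps))
  expect_true(all(u3$report$protocolB$snps %in% u3$report$kept_snps))
  expect_true(all(u3$report$protocolA$individuals$kept %in%
                    u3$report$kept_individuals))
})

test_that("qc report accounting is consistent", {
  cfg <- small_config(n = 300, seed = 23, missing_rate = 0.02)
  co <- small_cohort(cfg)
  u <- union_qc(co$geno, co$covars[paste0("PC", 1:5)])
  rc <- u$report$removal_counts
  expect_equal(rc[["individuals_removed"]],
               u$report$n_individuals_in -
                 length(u$report$kept_individuals))
  expect_equal(rc[["snps_removed"]],
               u$report$n_snps_in - length(u$report$kept_snps))
  expect_equal(dim(u$genotypes$genotypes),
               c(length(u$report$kept_individuals),
                 length(u$report$kept_snps)))
})
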