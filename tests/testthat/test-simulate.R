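test_that("config validation rejects impossible targets", {
  expect_error(gene_spec("g", maf = c(0, 0.1)), "MAF")
  expect_error(gene_spec("g", maf = 0.6), "MAF")
  expect_error(gene_spec("g", maf = c(0.1, 0.2), blocks = c(1, 2)),
               "sum")
  expect_error(gene_spec("g", maf = c(0.1, 0.2), r2 = 1.2), "R\\^2")
  expect_error(sim_config(n_individuals = 0), "n_individuals")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
})

test_that("unattainable within-block R2 is rejected with the bound", {
  genes <- list(gene_spec("g", maf = c(0.05, 0.4), blocks = 2, r2 = 0.9))
  cfg <- sim_config(n_individuals = 50, genes = genes,
                    interaction_effects = NULL)
  err <- tryCatch(simulate_genotypes(cfg), error = identity)
  expect_match(conditionMessage(err), "unattainable")
  expect_match(conditionMessage(err), "maximum attainable")
  # the stated bound matches the comonotone-coupling formula
  expect_lt(max_attainable_r2(0.05, 0.4), 0.9)
})

test_that("perfect LD at equal MAF yields identical genotype columns", {
  genes <- list(gene_spec("g", maf = c(0.3, 0.3, 0.3), blocks = 3,
                          r2 = 1))
  cfg <- sim_config(n_individuals = 300, genes = genes,
                    interaction_effects = NULL, seed = 5)
  gm <- simulate_genotypes(cfg)
  expect_identical(gm$genotypes[, 1], gm$genotypes[, 2],
                   ignore_attr = TRUE)
  expect_identical(gm$genotypes[, 1], gm$genotypes[, 3],
                   ignore_attr = TRUE)
})

test_that("perfect LD at unequal MAF is rejected", {
  genes <- list(gene_spec("g", maf = c(0.2, 0.3), blocks = 2, r2 = 1))
  cfg <- sim_config(n_individuals = 50, genes = genes,
                    interaction_effects = NULL)
  expect_error(simulate_genotypes(cfg), "unattainable")
})

test_that("empirical MAF converges to target (99% binomial CI)", {
  genes <- list(gene_spec("g", maf = 0.14))
  cfg <- sim_config(n_individuals = 50000, genes = genes,
                    interaction_effects = NULL, seed = 11)
  gm <- simulate_genotypes(cfg)
  count <- sum(gm$genotypes[, 1])
  expect_within_binom_ci99(count, 2 * 50000, 0.14)
})

test_that("realized within-block R2 tracks the target; cross-block ~ 0", {
  genes <- list(gene_spec("g", maf = c(0.2, 0.3, 0.1, 0.1),
                          blocks = c(2, 2), r2 = c(0.3, 0.6)))
  cfg <- sim_config(n_individuals = 10000, genes = genes,
                    interaction_effects = NULL, seed = 3)
  g <- simulate_genotypes(cfg)$genotypes
  expect_lt(abs(cor(g[, 1], g[, 2])^2 - 0.3), 0.05)
  expect_lt(abs(cor(g[, 3], g[, 4])^2 - 0.6), 0.05)
  expect_lt(cor(g[, 1], g[, 3])^2, 0.01)
  expect_lt(cor(g[, 2], g[, 4])^2, 0.01)
})

test_that("generation is deterministic given config and seed", {
  cfg <- small_config(n = 150, seed = 42, missing_rate = 0.05)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  c1 <- simulate_covariates(cfg)
  expect_identical(c1, simulate_covariates(cfg))
  t1 <- simulate_trait(g1, c1, cfg)
  expect_identical(t1, simulate_trait(g1, c1, cfg))
})

test_that("missingness is applied at the configured rate", {
  cfg <- small_config(n = 2000, seed = 9, missing_rate = 0.05)
  gm <- simulate_genotypes(cfg)
  n_miss <- sum(is.na(gm$genotypes))
  expect_within_binom_ci99(n_miss, length(gm$genotypes), 0.05)
})

test_that("covariates follow their Bernoulli prevalences", {
  cfg <- sim_config(n_individuals = 6142,
                    genes = list(gene_spec("g", maf = 0.2)),
                    covariates = list(education = 0.94, smoking = 1.0,
                                      sex = 0.569),
                    interaction_effects = NULL, seed = 2)
  cv <- simulate_covariates(cfg)
  expect_true(all(cv$smoking == 1))
  expect_within_binom_ci99(sum(cv$sex), 6142, 0.569)
  expect_within_binom_ci99(sum(cv$education), 6142, 0.94)
  expect_equal(colMeans(cv[paste0("PC", 1:5)]), rep(0, 5),
               tolerance = 0.15, ignore_attr = TRUE)
})

test_that("null trait model gives 50% cases; extreme intercept gives none", {
  cfg <- sim_config(n_individuals = 4000,
                    genes = list(gene_spec("g", maf = 0.2)),
                    intercept = 0, interaction_effects = NULL,
                    covariate_effects = numeric(0), seed = 8)
  co <- simulate_cohort(cfg)
  expect_within_binom_ci99(sum(attr(co$phenotypes, "true_case")), 4000,
                           0.5)
  cfg2 <- sim_config(n_individuals = 500,
                     genes = list(gene_spec("g", maf = 0.2)),
                     intercept = -40, interaction_effects = NULL,
                     covariate_effects = numeric(0), seed = 8)
  co2 <- simulate_cohort(cfg2)
  expect_true(all(attr(co2$phenotypes, "true_case") == 0))
  expect_true(all(co2$phenotypes$age < 85))
})

test_that("trait model errors on unknown SNPs and covariates", {
  cfg <- small_config(n = 100, seed = 1)
  gm <- simulate_genotypes(cfg)
  cv <- simulate_covariates(cfg)
  bad <- cfg
  bad$interaction_effects <- data.frame(snp1 = "geneA_snp01",
                                        snp2 = "nope_snp99", beta = 0.5)
  expect_error(simulate_trait(gm, cv, bad), "nope_snp99")
  bad2 <- cfg
  bad2$covariate_effects <- c(bmi = 0.1)
  expect_error(simulate_trait(gm, cv, bad2), "bmi")
})

test_that("exclusion fraction plants ages below the control window", {
  cfg <- small_config(n = 2000, seed = 4)
  cfg$exclude_fraction <- 0.1
  co <- simulate_cohort(cfg)
  n_young <- sum(co$phenotypes$age < 75)
  expect_within_binom_ci99(n_young, 2000, 0.1)
})

test_that("case prevalence calibrates to the configured fraction", {
  cfg <- small_config(n = 6142, seed = 13, b12 = 0.6)
  co <- simulate_cohort(cfg)
  expect_within_binom_ci99(sum(attr(co$phenotypes, "true_case")), 6142,
                           2564 / 6142)
})
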