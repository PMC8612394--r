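# shared fixture builders and oracles

# 99% binomial CI bounds for an observed count at n draws, probability p
binom_ci99 <- function(n, p) {
  stats::qbinom(c(0.005, 0.995), n, p)
}

expect_within_binom_ci99 <- function(count, n, p) {
  ci <- binom_ci99(n, p)
  expect_gte(count, ci[1])
  expect_lte(count, ci[2])
}

# small two-gene config for fast scans: 6 + 2 SNPs, planted interaction
small_config <- function(n = 600, seed = 1, b12 = 0, missing_rate = 0,
                         r2 = 0.8) {
  genes <- list(
    gene_spec("geneA", maf = rep(c(0.2, 0.3), each = 3),
              blocks = c(3, 3), r2 = r2, chrom = 15L),
    gene_spec("geneB", maf = rep(0.25, 2), blocks = 2, r2 = r2,
              chrom = 12L, pos_start = 5e6))
  ie <- if (b12 != 0) {
    data.frame(snp1 = "geneA_snp01", snp2 = "geneB_snp01", beta = b12)
  } else NULL
  sim_config(n_individuals = n, genes = genes, interaction_effects = ie,
             missing_rate = missing_rate, seed = seed)
}

# a labelled cohort from a config, returning the pieces scans need
small_cohort <- function(cfg) {
  co <- simulate_cohort(cfg)
  coh <- build_cohort(co$phenotypes, covariates = co$covariates)
  list(geno = co$genotypes, covars = co$covariates, labels = coh$labels,
       cohort = coh, sim = co)
}

# brute-force HWE exact oracle: direct factorial ratio over all
# heterozygote counts compatible with the allele totals (valid for
# 2n <= 170 where factorial() stays finite)
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  hs <- seq.int(nA %% 2, min(nA, na), by = 2)
  pr <- vapply(hs, function(h) {
    factorial(n) / (factorial((nA - h) / 2) * factorial(h) *
                      factorial((na - h) / 2)) * 2^h *
      factorial(nA) * factorial(na) / factorial(2 * n)
  }, 0)
  pr <- pr / sum(pr)
  p_obs <- pr[hs == n_Aa]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# reference logistic fit through stats::glm at tight convergence
glm_oracle <- function(x, y) {
  df <- as.data.frame(x[, -1, drop = FALSE])
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial(),
                    control = list(epsilon = 1e-14, maxit = 200))
  list(coef = unname(stats::coef(fit)),
       se = unname(summary(fit)$coefficients[, 2]),
       loglik = as.numeric(stats::logLik(fit)))
}
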