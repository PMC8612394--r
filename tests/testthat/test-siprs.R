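make_scan_cohort <- function(n = 800, seed = 30, b12 = 0) {
  genes <- list(
    gene_spec("fix", maf = 0.25, chrom = 1L),
    gene_spec("part", maf = rep(0.25, 12), blocks = rep(1, 12),
              chrom = 2L, pos_start = 5e6))
  ie <- if (b12 != 0) {
    data.frame(snp1 = "fix_snp01",
               snp2 = paste0("part_snp", sprintf("%02d", 1:4)),
               beta = b12)
  } else NULL
  cfg <- sim_config(n_individuals = n, genes = genes,
                    interaction_effects = ie, seed = seed)
  co <- small_cohort(cfg)
  scan <- fixed_snp_scan(co$geno, "fix_snp01", co$covars, co$labels)
  c(co, list(scan = scan))
}

test_that("index construction: inclusion, ordering, weighting", {
  co <- make_scan_cohort(b12 = 0.7)
  scan <- co$scan
  idx <- build_index(scan, co$geno, threshold = 0.5)
  expect_true(all(idx$pairs$p12 <= 0.5))
  expect_false(is.unsorted(idx$pairs$p12))
  expect_equal(idx$n_pairs, nrow(idx$pairs))
  # standardisation
  expect_equal(mean(idx$scores), 0, tolerance = 1e-9)
  expect_equal(sd(idx$scores), 1, tolerance = 1e-9)
  # single-pair index is a rescaling of b12 * g_fixed * g_partner
  one <- build_index(scan, co$geno,
                     threshold = min(scan$p12, na.rm = TRUE) * 1.0001)
  expect_equal(one$n_pairs, 1)
  raw <- one$pairs$b12[1] * co$geno$genotypes[, "fix_snp01"] *
    co$geno$genotypes[, one$pairs$partner[1]]
  expect_equal(cor(one$raw_scores, raw), 1, ignore_attr = TRUE)
  # count weighting counts carried interactions
  cnt <- build_index(scan, co$geno, threshold = 0.5,
                     weighting = "count")
  gm <- co$geno$genotypes
  manual <- rowSums(gm[, "fix_snp01"] * gm[, cnt$pairs$partner] > 0)
  expect_equal(unname(cnt$raw_scores), unname(manual))
})

test_that("empty index errors with the minimal passing threshold", {
  co <- make_scan_cohort(seed = 31)
  pmin_ <- min(co$scan$p12, na.rm = TRUE)
  err <- tryCatch(build_index(co$scan, co$geno, threshold = pmin_ / 10),
                  error = identity)
  expect_match(conditionMessage(err), "no pair passes")
  expect_match(conditionMessage(err), "smallest interaction P-value")
  expect_match(conditionMessage(err), sprintf("%.3g", pmin_),
               fixed = TRUE)
})

test_that("pair sets are nested across thresholds; n_pairs monotone", {
  co <- make_scan_cohort(seed = 32, b12 = 0.5)
  t1 <- build_index(co$scan, co$geno, 0.05)
  t2 <- build_index(co$scan, co$geno, 0.3)
  expect_true(all(t1$pairs$partner %in% t2$pairs$partner))
  sweep <- threshold_sweep(co$scan, co$geno, co$labels, co$covars,
                           grid = c(0.01, 0.05, 0.2, 0.5))
  expect_false(is.unsorted(sweep$n_pairs))
})

test_that("evaluation metrics behave at the extremes", {
  co <- make_scan_cohort(seed = 33, b12 = 0.8)
  idx <- build_index(co$scan, co$geno, 0.3)
  # score equal to the label separates perfectly
  fake <- idx
  fake$scores <- stats::setNames(as.numeric(co$labels),
                                 names(co$labels))
  ev <- suppressWarnings(
    evaluate_index(fake, co$labels, co$covars,
                   cfg = scan_config(covariates = character(0))))
  expect_equal(ev$auc, 1)
  # constant score refused
  fake$scores[] <- 0
  expect_error(evaluate_index(fake, co$labels, co$covars), "constant")
})

test_that("real planted interactions produce a predictive index", {
  co <- make_scan_cohort(n = 2000, seed = 34, b12 = 0.8)
  idx <- build_index(co$scan, co$geno, 0.05)
  ev <- evaluate_index(idx, co$labels, co$covars)
  expect_lt(ev$p_assoc, 1e-4)
  expect_gt(ev$auc, 0.55)
  expect_true(ev$auc_lo <= ev$auc & ev$auc <= ev$auc_hi)
  expect_gt(ev$r2, 0)
})

test_that("sweep records empty grid points and continues", {
  co <- make_scan_cohort(seed = 35)
  pmin_ <- min(co$scan$p12, na.rm = TRUE)
  sweep <- threshold_sweep(co$scan, co$geno, co$labels, co$covars,
                           grid = c(pmin_ / 100, 0.5))
  expect_equal(nrow(sweep), 2)
  expect_equal(sweep$n_pairs[1], 0L)
  expect_true(is.na(sweep$p_assoc[1]))
  expect_false(is.na(sweep$p_assoc[2]))
})

test_that("split-sample analysis scans and evaluates disjoint halves", {
  co <- make_scan_cohort(n = 600, seed = 36)
  an <- siprs_analysis(co$geno, "fix_snp01", co$labels, co$covars,
                       grid = c(0.2, 0.5), split_sample = TRUE,
                       seed = 9)
  expect_length(intersect(an$scan_ids, an$eval_ids), 0)
  expect_setequal(c(an$scan_ids, an$eval_ids), names(co$labels))
  expect_equal(unique(an$scan$n_used), length(an$scan_ids))
  # deterministic split
  an2 <- siprs_analysis(co$geno, "fix_snp01", co$labels, co$covars,
                        grid = c(0.2, 0.5), split_sample = TRUE,
                        seed = 9)
  expect_identical(an$eval_ids, an2$eval_ids)
  expect_equal(an$sweep$p_assoc, an2$sweep$p_assoc)
})
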