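#' Default P-value threshold grid for SIPRS sweeps
#'
#' Nine log-spaced thresholds: 5e-5, 1e-4, 5e-4, 1e-3, 5e-3, 0.01, 0.02,
#' 0.03, 0.05.
#' @return numeric vector of length nine.
#' @export
siprs_grid <- function() {
  c(5e-5, 1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 2e-2, 3e-2, 5e-2)
}

#' Build a SNP-specific interaction polygenic risk score index
#'
#' Aggregates the interacting pairs of a fixed-SNP scan whose interaction
#' P-value does not exceed a threshold into a per-individual score. With
#' `weighting = "beta"` (default) the score is the signed weighted sum
#' `sum_k b12_k * g_fixed * g_k`, honouring both positive and negative
#' associations; with `weighting = "count"` it is the number of included
#' pairs for which the individual carries minor alleles at both loci
#' (a genetic-dose-style count). Missing genotypes contribute 0. The score
#' is standardised to zero mean and unit variance over the cohort before
#' evaluation.
#'
#' @param scan a fixed-SNP `interaction_scan` (or any data frame with
#'   `rsid1`, `rsid2`, `b12`, `p12`, `testable`, `converged`).
#' @param geno `genotype_matrix` holding the fixed SNP and partners for
#'   the individuals to be scored.
#' @param threshold P-value cutoff in (0, 1\].
#' @param weighting `"beta"` or `"count"`.
#' @param fixed_snp rsid of the fixed SNP; defaults to the scan's
#'   `fixed_snp` attribute.
#' @param individuals optional character ids restricting the scored set.
#' @return object of class `siprs_index`: list with `fixed_snp`,
#'   `threshold`, `weighting`, `pairs` (data frame sorted by p12),
#'   `n_pairs`, `scores` (named, standardised), `raw_scores`.
#' @export
build_index <- function(scan, geno, threshold, weighting = c("beta",
                                                             "count"),
                        fixed_snp = attr(scan, "fixed_snp"),
                        individuals = NULL) {
  weighting <- match.arg(weighting)
  if (is.null(fixed_snp)) stop("fixed_snp must be supplied")
  stopifnot(threshold > 0, threshold <= 1)
  ok <- scan$testable & scan$converged & !is.na(scan$p12)
  res <- scan[ok, , drop = FALSE]
  partner <- ifelse(res$rsid1 == fixed_snp, res$rsid2, res$rsid1)
  inc <- res$p12 <= threshold
  if (!any(inc)) {
    stop(sprintf(paste0("no pair passes threshold %.3g; the smallest ",
                        "interaction P-value is %.3g"),
                 threshold, min(res$p12)))
  }
  pairs <- data.frame(partner = partner[inc], b12 = res$b12[inc],
                      p12 = res$p12[inc], stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$p12, pairs$partner), , drop = FALSE]
  rownames(pairs) <- NULL
  if (is.null(individuals)) individuals <- geno$individual_ids
  g <- geno$genotypes[individuals, , drop = FALSE]
  gf <- as.numeric(g[, fixed_snp])
  gf[is.na(gf)] <- 0
  gp <- g[, pairs$partner, drop = FALSE]
  gp[is.na(gp)] <- 0L
  prod_mat <- gf * gp
  raw <- if (weighting == "beta") {
    drop(prod_mat %*% pairs$b12)
  } else {
    rowSums(prod_mat > 0)
  }
  s <- stats::sd(raw)
  scores <- if (s > 0) (raw - mean(raw)) / s else raw - mean(raw)
  names(scores) <- individuals
  names(raw) <- individuals
  structure(list(fixed_snp = fixed_snp, threshold = threshold,
                 weighting = weighting, pairs = pairs,
                 n_pairs = nrow(pairs), scores = scores,
                 raw_scores = raw),
            class = "siprs_index")
}

#' @export
print.siprs_index <- function(x, ...) {
  cat(sprintf("SIPRS index for %s: threshold %.3g, %d pair(s), %s weights\n",
              x$fixed_snp, x$threshold, x$n_pairs, x$weighting))
  invisible(x)
}

#' Evaluate a SIPRS index against the survival trait
#'
#' Fits `logit P(case) = a + b * score + gamma' x` and reports the 1-df
#' likelihood-ratio P-value for the score term, the Nagelkerke pseudo-R2
#' increment of the score over the covariate-only model (both computed
#' against the intercept-only null; McFadden optional), and the ROC AUC of
#' the score-bearing model's fitted probabilities with a DeLong 95%
#' confidence interval.
#'
#' @param index a `siprs_index`.
#' @param labels named 0/1 vector of case labels.
#' @param covariates covariate data frame with `individual_id`.
#' @param cfg a [scan_config()] naming the adjustment covariates.
#' @param r2_method `"nagelkerke"` (default) or `"mcfadden"`.
#' @return one-row data frame of class `siprs_eval`: `fixed_snp`,
#'   `threshold`, `n_pairs`, `p_assoc`, `r2`, `auc`, `auc_lo`, `auc_hi`,
#'   `n_used`.
#' @export
evaluate_index <- function(index, labels, covariates,
                           cfg = scan_config(),
                           r2_method = c("nagelkerke", "mcfadden")) {
  r2_method <- match.arg(r2_method)
  ids <- intersect(names(index$scores), names(labels))
  score <- index$scores[ids]
  if (stats::sd(score) == 0) stop("constant SIPRS score; cannot evaluate")
  y <- unname(labels[ids])
  cv <- .covar_matrix(covariates[match(ids, covariates$individual_id), ,
                                 drop = FALSE], cfg)
  cc <- stats::complete.cases(cv) & !is.na(y)
  score <- score[cc]; y <- y[cc]; cv <- cv[cc, , drop = FALSE]
  x_full <- cbind(`(Intercept)` = 1, score = as.numeric(score), cv)
  x_cov <- cbind(`(Intercept)` = 1, cv)
  x_null <- cbind(`(Intercept)` = rep(1, length(y)))
  full <- fit_logistic(x_full, y)
  covfit <- fit_logistic(x_cov, y)
  nullfit <- fit_logistic(x_null, y)
  p_assoc <- lrt_logistic(full, covfit, df = 1)$p_value
  r2fun <- if (r2_method == "nagelkerke") nagelkerke_r2 else mcfadden_r2
  r2 <- r2fun(full, nullfit) - r2fun(covfit, nullfit)
  roc <- pROC::roc(response = y, predictor = full$fitted,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))
  out <- data.frame(fixed_snp = index$fixed_snp,
                    threshold = index$threshold,
                    n_pairs = index$n_pairs, p_assoc = p_assoc,
                    r2 = max(0, r2), auc = ci[2], auc_lo = ci[1],
                    auc_hi = ci[3], n_used = length(y),
                    stringsAsFactors = FALSE)
  class(out) <- c("siprs_eval", "data.frame")
  out
}

#' Threshold sweep of SIPRS indices
#'
#' Builds and evaluates one SIPRS index per grid threshold. Grid points at
#' which no pair passes are recorded as empty rows (NA metrics) and the
#' sweep continues.
#'
#' @inheritParams build_index
#' @param labels named 0/1 vector.
#' @param covariates covariate data frame.
#' @param grid numeric vector of thresholds (default [siprs_grid()]).
#' @param cfg a [scan_config()].
#' @param r2_method passed to [evaluate_index()].
#' @return data frame of class `siprs_sweep`, one row per threshold.
#' @export
threshold_sweep <- function(scan, geno, labels, covariates,
                            grid = siprs_grid(),
                            weighting = c("beta", "count"),
                            fixed_snp = attr(scan, "fixed_snp"),
                            cfg = scan_config(),
                            r2_method = c("nagelkerke", "mcfadden")) {
  weighting <- match.arg(weighting)
  if (!length(grid)) stop("threshold grid must be non-empty")
  if (is.null(fixed_snp)) stop("fixed_snp must be supplied")
  rows <- lapply(sort(grid), function(t) {
    idx <- tryCatch(build_index(scan, geno, t, weighting, fixed_snp),
                    error = function(e) NULL)
    if (is.null(idx)) {
      return(data.frame(fixed_snp = fixed_snp, threshold = t,
                        n_pairs = 0L, p_assoc = NA_real_, r2 = NA_real_,
                        auc = NA_real_, auc_lo = NA_real_,
                        auc_hi = NA_real_, n_used = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    evaluate_index(idx, labels, covariates, cfg, r2_method)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("siprs_sweep", "data.frame"),
            weighting = weighting)
}

#' @export
print.siprs_sweep <- function(x, ...) {
  cat("SIPRS threshold sweep for", x$fixed_snp[1],
      sprintf("(%s weights)\n", attr(x, "weighting")))
  print.data.frame(x[, c("threshold", "n_pairs", "r2", "p_assoc", "auc",
                         "auc_lo", "auc_hi")],
                   row.names = FALSE, digits = 3)
  invisible(x)
}

#' Bar plot of a SIPRS threshold sweep
#'
#' One bar per threshold; bar height is the pseudo-R2 increment, annotated
#' with the number of included pairs and the association P-value.
#'
#' @param x a `siprs_sweep`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.siprs_sweep <- function(x, ...) {
  h <- ifelse(is.na(x$r2), 0, x$r2)
  bp <- graphics::barplot(h, names.arg = format(x$threshold),
                          xlab = "P-value threshold",
                          ylab = "pseudo-R2 (increment over covariates)",
                          main = paste("SIPRS sweep:", x$fixed_snp[1]),
                          ylim = c(0, max(h) * 1.35 + 1e-3), ...)
  lab <- sprintf("%d\n%.3f\n%.1e", x$n_pairs, x$r2, x$p_assoc)
  lab[is.na(x$r2)] <- "0"
  graphics::text(bp, h, lab, pos = 3, cex = 0.6)
  invisible(x)
}

#' Full SIPRS analysis for one fixed SNP
#'
#' Runs the fixed-SNP interaction scan and the threshold sweep. In
#' split-sample mode the cohort is randomly halved: the scan (and hence
#' pair selection and weights) uses one half and the indices are scored
#' and evaluated on the held-out half, which restores the calibration of
#' the association P-values; in-sample evaluation (the default) reuses the
#' scan sample and is known to be anti-conservative under the null because
#' the same data select the pairs and test the score.
#'
#' @param geno `genotype_matrix`.
#' @param fixed_snp rsid.
#' @param labels named 0/1 vector.
#' @param covariates covariate data frame.
#' @param grid threshold grid.
#' @param weighting `"beta"` or `"count"`.
#' @param split_sample logical; evaluate on a held-out half.
#' @param seed RNG seed for the split.
#' @param cfg a [scan_config()].
#' @param partners optional partner restriction for the scan.
#' @return list of class `siprs_analysis` with `scan`, `sweep`,
#'   `split_sample`, and (when splitting) `scan_ids`, `eval_ids`.
#' @export
siprs_analysis <- function(geno, fixed_snp, labels, covariates,
                           grid = siprs_grid(),
                           weighting = c("beta", "count"),
                           split_sample = FALSE, seed = 1L,
                           cfg = scan_config(), partners = NULL) {
  weighting <- match.arg(weighting)
  ids <- intersect(geno$individual_ids, names(labels))
  scan_ids <- eval_ids <- ids
  if (split_sample) {
    set.seed(.stage_seed(seed, "split"))
    half <- sample(ids, floor(length(ids) / 2))
    scan_ids <- sort(half)
    eval_ids <- sort(setdiff(ids, half))
  }
  scan <- fixed_snp_scan(geno, fixed_snp, covariates,
                         labels[scan_ids], cfg, partners = partners)
  sweep <- threshold_sweep(
    scan,
    genotype_matrix(geno$genotypes[eval_ids, , drop = FALSE],
                    geno$snp_meta, eval_ids),
    labels[eval_ids], covariates, grid, weighting, fixed_snp, cfg)
  structure(list(scan = scan, sweep = sweep, split_sample = split_sample,
                 scan_ids = if (split_sample) scan_ids,
                 eval_ids = if (split_sample) eval_ids),
            class = "siprs_analysis")
}

#' @export
print.siprs_analysis <- function(x, ...) {
  cat("SIPRS analysis",
      if (x$split_sample) "(split-sample)" else "(in-sample)", "\n")
  print(x$sweep)
  invisible(x)
}
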