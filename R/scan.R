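#' Scan configuration
#'
#' @param covariates character vector of covariate column names adjusted
#'   for in every model.
#' @param test `"lrt"` (default) for likelihood-ratio P-values or
#'   `"wald"`.
#' @param min_cell minimum number of complete-case individuals carrying
#'   minor alleles at both loci (`g1 > 0 & g2 > 0`) for a pair to be
#'   testable.
#' @param fixed_snp optional rsid for fixed-SNP scans.
#' @return a `scan_config` list.
#' @export
scan_config <- function(covariates = c("education", "smoking", "sex",
                                       paste0("PC", 1:5)),
                        test = c("lrt", "wald"), min_cell = 5,
                        fixed_snp = NULL) {
  structure(list(covariates = covariates, test = match.arg(test),
                 min_cell = min_cell, fixed_snp = fixed_snp),
            class = "scan_config")
}

.covar_matrix <- function(covariates, cfg) {
  if (!length(cfg$covariates)) {
    return(matrix(numeric(0), nrow(covariates), 0))
  }
  missing_cov <- setdiff(cfg$covariates, names(covariates))
  if (length(missing_cov)) {
    stop("covariate(s) not found: ", paste(missing_cov, collapse = ", "))
  }
  as.matrix(covariates[, cfg$covariates, drop = FALSE])
}

#' Single-SNP (marginal) association test
#'
#' Logistic model with the SNP's additive main effect plus covariates;
#' the P-value is a 1-df likelihood-ratio test of the SNP term (Wald
#' optional via `cfg$test`).
#'
#' @param g additive genotype vector (0/1/2, NA for missing).
#' @param covariates covariate data frame aligned to `g`.
#' @param labels 0/1 case labels aligned to `g`.
#' @param cfg a [scan_config()].
#' @return list with `p`, `beta`, `se`, `n_used`, `testable`, `converged`.
#' @export
test_single <- function(g, covariates, labels, cfg = scan_config()) {
  cv <- .covar_matrix(covariates, cfg)
  cc <- !is.na(g) & !is.na(labels) & stats::complete.cases(cv)
  g <- as.numeric(g[cc])
  y <- labels[cc]
  cv <- cv[cc, , drop = FALSE]
  if (length(unique(g)) < 2) {
    return(list(p = NA_real_, beta = NA_real_, se = NA_real_,
                n_used = sum(cc), testable = FALSE, converged = FALSE))
  }
  x_full <- cbind(`(Intercept)` = 1, g = g, cv)
  x_red <- cbind(`(Intercept)` = 1, cv)
  full <- fit_logistic(x_full, y)
  if (!full$converged) {
    return(list(p = NA_real_, beta = unname(coef(full)["g"]),
                se = NA_real_, n_used = sum(cc), testable = TRUE,
                converged = FALSE))
  }
  se <- sqrt(diag(full$vcov))["g"]
  p <- if (cfg$test == "wald") {
    2 * stats::pnorm(-abs(coef(full)["g"] / se))
  } else {
    lrt_logistic(full, fit_logistic(x_red, y), df = 1)$p_value
  }
  list(p = unname(p), beta = unname(coef(full)["g"]), se = unname(se),
       n_used = sum(cc), testable = TRUE, converged = TRUE)
}

#' Test one SNP pair for interaction with a survival trait
#'
#' Fits `logit P(case) = b0 + b1 g1 + b2 g2 + b12 (g1 * g2) + gamma' x`
#' on complete cases and tests `b12 = 0` with a 1-df likelihood-ratio test
#' (default) or Wald test. Marginal P-values for the two SNPs come from
#' separate single-SNP models ([test_single()]).
#'
#' @param g1,g2 additive genotype vectors.
#' @param covariates covariate data frame.
#' @param labels 0/1 case labels.
#' @param cfg a [scan_config()].
#' @param meta1,meta2 optional one-row data frames of SNP metadata
#'   (`rsid`, `ea`, `nea`, `minor_allele`).
#' @param marginals compute `p1`/`p2` via [test_single()] (skippable for
#'   speed in simulation studies); precomputed values can be supplied via
#'   `p1`, `p2`.
#' @param p1,p2 optional precomputed marginal P-values.
#' @return one-row data frame (an `InteractionResult`): rsid1, ea_nea1,
#'   minor_allele1, p1, maf1, rsid2, ea_nea2, minor_allele2, p2, maf2,
#'   b12, se12, p12, n_used, converged, testable.
#' @export
test_pair <- function(g1, g2, covariates, labels, cfg = scan_config(),
                      meta1 = NULL, meta2 = NULL, marginals = TRUE,
                      p1 = NA_real_, p2 = NA_real_) {
  cv <- .covar_matrix(covariates, cfg)
  cc <- !is.na(g1) & !is.na(g2) & !is.na(labels) & stats::complete.cases(cv)
  g1c <- as.numeric(g1[cc]); g2c <- as.numeric(g2[cc])
  y <- labels[cc]
  cvc <- cv[cc, , drop = FALSE]
  n_used <- sum(cc)
  maf1 <- if (n_used) min(mean(g1c) / 2, 1 - mean(g1c) / 2) else NA_real_
  maf2 <- if (n_used) min(mean(g2c) / 2, 1 - mean(g2c) / 2) else NA_real_
  if (marginals && is.na(p1)) {
    p1 <- test_single(g1, covariates, labels, cfg)$p
  }
  if (marginals && is.na(p2)) {
    p2 <- test_single(g2, covariates, labels, cfg)$p
  }
  res <- data.frame(
    rsid1 = .meta_or(meta1, "rsid", "snp1"),
    ea_nea1 = paste0(.meta_or(meta1, "ea", "?"), "/",
                     .meta_or(meta1, "nea", "?")),
    minor_allele1 = .meta_or(meta1, "minor_allele", "?"),
    p1 = p1, maf1 = maf1,
    rsid2 = .meta_or(meta2, "rsid", "snp2"),
    ea_nea2 = paste0(.meta_or(meta2, "ea", "?"), "/",
                     .meta_or(meta2, "nea", "?")),
    minor_allele2 = .meta_or(meta2, "minor_allele", "?"),
    p2 = p2, maf2 = maf2,
    b12 = NA_real_, se12 = NA_real_, p12 = NA_real_,
    n_used = n_used, converged = FALSE, testable = FALSE,
    stringsAsFactors = FALSE)
  prod12 <- g1c * g2c
  if (length(unique(g1c)) < 2 || length(unique(g2c)) < 2 ||
      length(unique(prod12)) < 2 || sum(prod12 > 0) < cfg$min_cell) {
    return(res)
  }
  x_full <- cbind(`(Intercept)` = 1, g1 = g1c, g2 = g2c, g12 = prod12, cvc)
  x_red <- cbind(`(Intercept)` = 1, g1 = g1c, g2 = g2c, cvc)
  full <- tryCatch(fit_logistic(x_full, y), error = function(e) NULL)
  if (is.null(full)) return(res)
  res$testable <- TRUE
  res$b12 <- unname(coef(full)["g12"])
  if (!full$converged) return(res)
  res$converged <- TRUE
  res$se12 <- unname(sqrt(diag(full$vcov))["g12"])
  res$p12 <- if (cfg$test == "wald") {
    2 * stats::pnorm(-abs(res$b12 / res$se12))
  } else {
    lrt_logistic(full, fit_logistic(x_red, y), df = 1)$p_value
  }
  res
}

.empty_scan <- function() {
  data.frame(rsid1 = character(0), ea_nea1 = character(0),
             minor_allele1 = character(0), p1 = numeric(0),
             maf1 = numeric(0), rsid2 = character(0),
             ea_nea2 = character(0), minor_allele2 = character(0),
             p2 = numeric(0), maf2 = numeric(0), b12 = numeric(0),
             se12 = numeric(0), p12 = numeric(0), n_used = integer(0),
             converged = logical(0), testable = logical(0),
             stringsAsFactors = FALSE)
}

.meta_or <- function(meta, field, default) {
  if (is.null(meta) || is.null(meta[[field]])) default else meta[[field]]
}

.snp_meta_row <- function(geno, rsid) {
  geno$snp_meta[match(rsid, geno$snp_meta$rsid), , drop = FALSE]
}

#' Cross-gene candidate interaction scan
#'
#' Tests every pair (a, b) with a from one gene and b from the other,
#' producing |A| x |B| interaction results ordered by (rsid1, rsid2).
#' Marginal single-SNP P-values are computed once per SNP and reused.
#'
#' @param geno a `genotype_matrix`.
#' @param geneA,geneB gene labels (matched against `snp_meta$gene`) or
#'   character vectors of rsids. The two sets must be disjoint.
#' @param covariates covariate data frame with `individual_id`.
#' @param labels named 0/1 vector (e.g. from [build_cohort()]); only
#'   labelled individuals enter the models.
#' @param cfg a [scan_config()].
#' @param marginals compute per-SNP marginal P-values (once per SNP);
#'   set FALSE to skip them in simulation studies.
#' @return data frame of class `interaction_scan`, one row per pair.
#' @export
cross_gene_scan <- function(geno, geneA, geneB, covariates, labels,
                            cfg = scan_config(), marginals = TRUE) {
  snpsA <- .resolve_snps(geno, geneA)
  snpsB <- .resolve_snps(geno, geneB)
  if (length(intersect(snpsA, snpsB))) {
    stop("gene SNP sets overlap: ",
         paste(intersect(snpsA, snpsB), collapse = ", "))
  }
  al <- .align_inputs(geno, covariates, labels)
  marg <- .marginal_cache(al, c(snpsA, snpsB), cfg, marginals)
  snpsA <- sort(snpsA); snpsB <- sort(snpsB)
  rows <- vector("list", length(snpsA) * length(snpsB))
  k <- 0L
  for (a in snpsA) {
    for (b in snpsB) {
      k <- k + 1L
      rows[[k]] <- test_pair(al$g[, a], al$g[, b], al$covars, al$labels,
                             cfg, .snp_meta_row(geno, a),
                             .snp_meta_row(geno, b), marginals = FALSE,
                             p1 = marg[[a]], p2 = marg[[b]])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_scan()
  structure(out, class = c("interaction_scan", "data.frame"),
            scan_type = "cross_gene", fixed_snp = NULL,
            genes = c(geneA = if (is.character(geneA) &&
                                  length(geneA) == 1) geneA else NA,
                      geneB = if (is.character(geneB) &&
                                  length(geneB) == 1) geneB else NA))
}

#' Genome-wide fixed-SNP interaction scan
#'
#' For a fixed SNP, tests its interaction with every other SNP in the
#' matrix. Each model carries main effects for the fixed SNP and the
#' partner, their product term, and the covariates, so the fixed SNP is
#' always adjusted for; the fixed SNP is excluded from its own scan. The
#' scan is pairwise-identical to calling [test_pair()] per partner.
#'
#' @param geno a `genotype_matrix`.
#' @param fixed_snp rsid of the fixed SNP (must be present).
#' @param covariates covariate data frame with `individual_id`.
#' @param labels named 0/1 vector.
#' @param cfg a [scan_config()].
#' @param partners optional character vector restricting the partner SNPs.
#' @param marginals compute per-SNP marginal P-values; FALSE to skip.
#' @return data frame of class `interaction_scan`, one row per partner,
#'   with the fixed SNP as rsid1.
#' @export
fixed_snp_scan <- function(geno, fixed_snp, covariates, labels,
                           cfg = scan_config(), partners = NULL,
                           marginals = TRUE) {
  if (!fixed_snp %in% geno$snp_meta$rsid) {
    stop("fixed SNP not present in genotypes: ", fixed_snp)
  }
  if (is.null(partners)) partners <- geno$snp_meta$rsid
  partners <- sort(setdiff(partners, fixed_snp))
  al <- .align_inputs(geno, covariates, labels)
  marg <- .marginal_cache(al, c(fixed_snp, partners), cfg, marginals)
  meta_f <- .snp_meta_row(geno, fixed_snp)
  rows <- lapply(partners, function(b) {
    test_pair(al$g[, fixed_snp], al$g[, b], al$covars, al$labels, cfg,
              meta_f, .snp_meta_row(geno, b), marginals = FALSE,
              p1 = marg[[fixed_snp]], p2 = marg[[b]])
  })
  out <- if (length(rows)) do.call(rbind, rows) else .empty_scan()
  structure(out, class = c("interaction_scan", "data.frame"),
            scan_type = "fixed_snp", fixed_snp = fixed_snp)
}

.resolve_snps <- function(geno, gene) {
  if (length(gene) == 1 && gene %in% geno$snp_meta$gene) {
    geno$snp_meta$rsid[geno$snp_meta$gene == gene]
  } else {
    missing_snps <- setdiff(gene, geno$snp_meta$rsid)
    if (length(missing_snps)) {
      stop("SNP(s) not present in genotypes: ",
           paste(missing_snps, collapse = ", "))
    }
    gene
  }
}

.align_inputs <- function(geno, covariates, labels) {
  ids <- names(labels)
  if (is.null(ids)) stop("labels must be a named vector of 0/1")
  ids <- intersect(geno$individual_ids, ids)
  list(g = geno$genotypes[ids, , drop = FALSE],
       covars = covariates[match(ids, covariates$individual_id), ,
                           drop = FALSE],
       labels = unname(labels[ids]))
}

.marginal_cache <- function(al, snps, cfg, marginals = TRUE) {
  out <- lapply(unique(snps), function(s) {
    if (!marginals) return(NA_real_)
    test_single(al$g[, s], al$covars, al$labels, cfg)$p
  })
  names(out) <- unique(snps)
  out
}

#' Sex-stratified scan
#'
#' Restricts the cohort to one sex and removes `sex` from the covariate
#' list, then runs [cross_gene_scan()].
#'
#' @inheritParams cross_gene_scan
#' @param sex 0 (male) or 1 (female), matched against the `sex` covariate.
#' @export
sex_stratified_scan <- function(geno, geneA, geneB, covariates, labels,
                                sex, cfg = scan_config()) {
  keep_ids <- covariates$individual_id[covariates$sex == sex]
  labels <- labels[names(labels) %in% keep_ids]
  cfg$covariates <- setdiff(cfg$covariates, "sex")
  cross_gene_scan(geno, geneA, geneB, covariates, labels, cfg)
}

#' @export
print.interaction_scan <- function(x, ...) {
  cat("Interaction scan (", attr(x, "scan_type"), "), ",
      nrow(x), " pairs\n", sep = "")
  if (!is.null(attr(x, "fixed_snp"))) {
    cat("fixed SNP:", attr(x, "fixed_snp"), "\n")
  }
  ord <- order(x$p12)
  print.data.frame(utils::head(x[ord, c("rsid1", "rsid2", "b12", "se12",
                                        "p12", "n_used")], 8),
                   row.names = FALSE, digits = 4)
  if (nrow(x) > 8) cat("...", nrow(x) - 8, "more pairs\n")
  invisible(x)
}

#' @export
summary.interaction_scan <- function(object, alpha = 0.05, ...) {
  n_test <- sum(object$testable & object$converged)
  thr <- if (n_test) alpha / n_test else NA
  cat("Pairs:", nrow(object), " testable+converged:", n_test, "\n")
  cat(sprintf("Bonferroni threshold (alpha = %.3g): %.3g\n", alpha, thr))
  cat("smallest p12:", format(min(object$p12, na.rm = TRUE), digits = 4),
      "\n")
  invisible(object)
}
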