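#' Squared genotype correlation (LD R-squared)
#'
#' Squared Pearson correlation of additive genotype codes over
#' pairwise-complete individuals — the LD measure used for clumping.
#'
#' @param g1,g2 additive genotype vectors.
#' @return R-squared in \[0, 1\]; NA (with a warning) if either vector is
#'   constant over the pairwise-complete individuals.
#' @export
genotype_r2 <- function(g1, g2) {
  cc <- !is.na(g1) & !is.na(g2)
  if (length(unique(g1[cc])) < 2 || length(unique(g2[cc])) < 2) {
    warning("constant genotype vector; R^2 undefined")
    return(NA_real_)
  }
  stats::cor(g1[cc], g2[cc])^2
}

# pairwise R^2 matrix over a set of SNPs (complete-case pairwise)
.r2_matrix <- function(g) {
  r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  r^2
}

#' Cluster one gene's SNPs into LD regions
#'
#' Greedy significance-seeded clustering (PLINK-clump style): pairs are
#' ranked by interaction P-value (`p12`, ascending; ties broken by rsid
#' order); the seed of each new cluster is the not-yet-assigned SNP of this
#' gene appearing in the best unconsumed pair, and the cluster absorbs
#' every unassigned SNP whose R-squared with the seed is at least the
#' threshold. SNPs of the gene that appear in no testable pair are seeded
#' last, in rsid order. The result is a partition of the gene's SNPs.
#'
#' @param geno a `genotype_matrix` (LD is measured on the analysis
#'   cohort's genotypes, cases and controls combined).
#' @param gene gene label or character vector of rsids.
#' @param results an `interaction_scan` data frame supplying `p12` per
#'   pair.
#' @param r2_threshold LD threshold (default 0.1).
#' @return list of clusters, each a list with `seed` and `members`
#'   (character rsids); class `ld_clusters`.
#' @export
cluster_gene <- function(geno, gene, results, r2_threshold = 0.1) {
  snps <- .resolve_snps(geno, gene)
  if (!length(snps)) return(structure(list(), class = "ld_clusters"))
  r2 <- .r2_matrix(geno$genotypes[, snps, drop = FALSE])
  ok <- results$testable & results$converged & !is.na(results$p12)
  res <- results[ok, , drop = FALSE]
  res <- res[order(res$p12, res$rsid1, res$rsid2), , drop = FALSE]
  # per pair, the SNP belonging to this gene (cross-gene pairs carry one)
  seed_queue <- character(0)
  for (k in seq_len(nrow(res))) {
    for (s in c(res$rsid1[k], res$rsid2[k])) {
      if (s %in% snps) seed_queue <- c(seed_queue, s)
    }
  }
  seed_queue <- c(seed_queue, sort(snps))
  assigned <- character(0)
  clusters <- list()
  for (s in seed_queue) {
    if (s %in% assigned) next
    free <- setdiff(snps, assigned)
    members <- free[!is.na(r2[s, free]) & r2[s, free] >= r2_threshold]
    members <- union(s, members)
    clusters[[length(clusters) + 1L]] <- list(seed = s,
                                              members = sort(members))
    assigned <- c(assigned, members)
  }
  structure(clusters, class = "ld_clusters", gene = gene,
            r2_threshold = r2_threshold)
}

#' @export
print.ld_clusters <- function(x, ...) {
  cat("LD clusters (R^2 >= ", attr(x, "r2_threshold"), "), gene ",
      attr(x, "gene"), ": ", length(x), " cluster(s)\n", sep = "")
  for (i in seq_along(x)) {
    cat(sprintf("  [%d] seed %s: %d SNP(s)\n", i, x[[i]]$seed,
                length(x[[i]]$members)))
  }
  invisible(x)
}

#' Select independent representative pairs
#'
#' For every (cluster-of-gene-A, cluster-of-gene-B) cell, the
#' representative is the member pair with the smallest interaction
#' P-value (ties broken by rsid order); cells with no testable pair are
#' dropped and recorded. The number of independent tests is the number of
#' cells, and the Bonferroni-corrected threshold is `alpha` divided by it.
#'
#' @param clustersA,clustersB `ld_clusters` from [cluster_gene()].
#' @param results an `interaction_scan` covering the cross-cluster pairs.
#' @param alpha family-wise significance level (default 0.05).
#' @return object of class `independent_pairs`: the representative rows
#'   (sorted by p12 ascending) with attributes `n_independent_tests`,
#'   `bonferroni_alpha`, `dropped_cells`, `significant` (logical vector).
#' @export
select_representatives <- function(clustersA, clustersB, results,
                                   alpha = 0.05) {
  ok <- results$testable & results$converged & !is.na(results$p12)
  res <- results[ok, , drop = FALSE]
  key <- paste(res$rsid1, res$rsid2, sep = "\r")
  reps <- list()
  dropped <- character(0)
  for (i in seq_along(clustersA)) {
    for (j in seq_along(clustersB)) {
      ma <- clustersA[[i]]$members
      mb <- clustersB[[j]]$members
      sel <- which((res$rsid1 %in% ma & res$rsid2 %in% mb) |
                     (res$rsid1 %in% mb & res$rsid2 %in% ma))
      if (!length(sel)) {
        dropped <- c(dropped, sprintf("A%d x B%d", i, j))
        next
      }
      cell <- res[sel, , drop = FALSE]
      best <- cell[order(cell$p12, cell$rsid1, cell$rsid2)[1], ,
                   drop = FALSE]
      reps[[length(reps) + 1L]] <- best
    }
  }
  n_tests <- length(clustersA) * length(clustersB)
  out <- do.call(rbind, reps)
  out <- out[order(out$p12, out$rsid1, out$rsid2), , drop = FALSE]
  rownames(out) <- NULL
  thr <- bonferroni_threshold(n_tests, alpha)
  structure(out, class = c("independent_pairs", "data.frame"),
            n_independent_tests = n_tests, alpha = alpha,
            bonferroni_alpha = thr, dropped_cells = dropped,
            significant = out$p12 <= thr)
}

#' Bonferroni-corrected P-value threshold
#'
#' @param n_tests number of independent tests (>= 1).
#' @param alpha family-wise significance level.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(8)    # 0.00625
#' bonferroni_threshold(504)  # 9.92e-05
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Clump a cross-gene scan to independent representative pairs
#'
#' Clusters each gene's SNPs into LD regions at the given R-squared
#' threshold, then selects the most significant member pair per
#' cross-cluster cell and applies the Bonferroni correction over the
#' number of cells.
#'
#' @param scan a cross-gene `interaction_scan`.
#' @param geno the `genotype_matrix` the scan was run on.
#' @param geneA,geneB gene labels or rsid vectors (defaulting to the
#'   distinct rsid1/rsid2 sets of the scan).
#' @param r2 LD threshold (default 0.1).
#' @param alpha family-wise level (default 0.05).
#' @return an `independent_pairs` object (see
#'   [select_representatives()]) with the per-gene `ld_clusters` attached
#'   as attributes `clustersA`, `clustersB`.
#' @export
clump_pairs <- function(scan, geno, geneA = unique(scan$rsid1),
                        geneB = unique(scan$rsid2), r2 = 0.1,
                        alpha = 0.05) {
  ca <- cluster_gene(geno, geneA, scan, r2_threshold = r2)
  cb <- cluster_gene(geno, geneB, scan, r2_threshold = r2)
  out <- select_representatives(ca, cb, scan, alpha = alpha)
  attr(out, "clustersA") <- ca
  attr(out, "clustersB") <- cb
  out
}

#' @export
print.independent_pairs <- function(x, ...) {
  cat("Independent SNP pairs after LD clumping:", nrow(x), "pairs\n")
  cat(sprintf("independent tests: %d; Bonferroni threshold: %.3g\n",
              attr(x, "n_independent_tests"), attr(x, "bonferroni_alpha")))
  cols <- c("rsid1", "ea_nea1", "minor_allele1", "p1", "maf1",
            "rsid2", "ea_nea2", "minor_allele2", "p2", "maf2",
            "b12", "p12")
  print.data.frame(x[, cols], row.names = FALSE, digits = 3)
  sig <- attr(x, "significant")
  if (any(sig)) {
    cat("significant under Bonferroni:",
        paste(x$rsid1[sig], x$rsid2[sig], sep = " x ", collapse = "; "),
        "\n")
  } else cat("no pair significant under Bonferroni\n")
  invisible(x)
}
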