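#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of Hardy-Weinberg genotype proportions. Given the
#' observed allele counts, the heterozygote count under the null follows the
#' conditional (hypergeometric-type) distribution
#' `P(h) prop.to 2^h / (nAA! h! naa!)`; the P-value is the sum of the
#' probabilities of all heterozygote configurations no more probable than
#' the observed one. The exact test is used rather than the chi-square
#' approximation because the QC threshold sits in the extreme tail
#' (P < 1e-7) where the approximation misbehaves for rare alleles.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major homozygote, heterozygote,
#'   minor homozygote; the test is symmetric in the homozygote labels).
#' @return the exact P-value; 1 for a monomorphic marker by convention.
#' @examples
#' hwe_exact_test(5, 10, 5)
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype call is required")
  rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (rare == 0) return(1)
  hs <- seq.int(rare %% 2, min(rare, 2 * n - rare), by = 2)
  # unnormalised log conditional probabilities of each heterozygote count
  lp <- hs * log(2) - lfactorial((rare - hs) / 2) - lfactorial(hs) -
    lfactorial((2 * n - rare - hs) / 2)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  p_obs <- pr[hs == n_Aa]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Per-SNP quality-control statistics
#'
#' @param geno a `genotype_matrix`.
#' @return data frame with one row per SNP: `rsid`, `gene`, `maf`
#'   (minor allele frequency over non-missing calls), `call_rate`, `hwe_p`
#'   (exact test), `n_called`. SNPs with zero non-missing calls get NA MAF
#'   and HWE and are flagged in `defined`.
#' @export
snp_stats <- function(geno) {
  g <- geno$genotypes
  if (ncol(g) == 0 || nrow(g) == 0) stop("empty genotype matrix")
  n0 <- colSums(g == 0, na.rm = TRUE)
  n1 <- colSums(g == 1, na.rm = TRUE)
  n2 <- colSums(g == 2, na.rm = TRUE)
  n_called <- n0 + n1 + n2
  p <- ifelse(n_called > 0, (n1 + 2 * n2) / (2 * n_called), NA_real_)
  maf <- pmin(p, 1 - p)
  hwe <- rep(NA_real_, ncol(g))
  for (j in seq_len(ncol(g))) {
    if (n_called[j] > 0) hwe[j] <- hwe_exact_test(n0[j], n1[j], n2[j])
  }
  data.frame(rsid = geno$snp_meta$rsid, gene = geno$snp_meta$gene,
             maf = unname(maf), call_rate = unname(n_called / nrow(g)),
             hwe_p = hwe, n_called = unname(n_called),
             defined = unname(n_called > 0),
             stringsAsFactors = FALSE)
}

#' QC threshold set (one protocol)
#'
#' Defaults follow a standard GWAS QC protocol: per-individual missingness
#' 5%, heterozygosity outliers beyond 3 SD, ancestry (PC) outliers beyond
#' 8 SD, MAF below 1%, per-SNP missingness 5%, exact HWE P below 1e-7.
#'
#' @param ind_missing_max maximum per-individual missing-call fraction.
#' @param het_outlier_sd heterozygosity outlier cut in SD units.
#' @param ancestry_outlier_sd PC outlier cut in SD units.
#' @param maf_min minimum minor allele frequency.
#' @param snp_missing_max maximum per-SNP missing-call fraction.
#' @param hwe_p_min minimum exact HWE P-value.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(ind_missing_max = 0.05, het_outlier_sd = 3,
                          ancestry_outlier_sd = 8, maf_min = 0.01,
                          snp_missing_max = 0.05, hwe_p_min = 1e-7) {
  stopifnot(ind_missing_max >= 0, ind_missing_max <= 1,
            snp_missing_max >= 0, snp_missing_max <= 1,
            maf_min >= 0, maf_min <= 1,
            het_outlier_sd > 0, ancestry_outlier_sd > 0,
            hwe_p_min > 0, hwe_p_min < 1)
  structure(list(ind_missing_max = ind_missing_max,
                 het_outlier_sd = het_outlier_sd,
                 ancestry_outlier_sd = ancestry_outlier_sd,
                 maf_min = maf_min, snp_missing_max = snp_missing_max,
                 hwe_p_min = hwe_p_min),
            class = "qc_thresholds")
}

#' Individual-level QC filters
#'
#' Drops individuals with a per-individual missing-call fraction above the
#' threshold, an observed heterozygous-call fraction outside mean +/- k SD,
#' any of PC1-PC5 outside mean +/- k SD, and duplicate genotype vectors
#' (the first occurrence is kept). All statistics are computed on the input
#' snapshot; filters are applied jointly, not sequentially. A sex-mismatch
#' check against reported sex is accepted for interface compatibility but
#' skipped with a warning: it requires sex-chromosome data, which the
#' autosomal generator does not model.
#'
#' @param geno a `genotype_matrix`.
#' @param pcs data frame or matrix of principal components aligned to the
#'   individuals (columns PC1..PC5 used if named; otherwise the first five
#'   columns).
#' @param thresholds a [qc_thresholds()].
#' @param reported_sex optional reported-sex vector; triggers the stub
#'   warning if supplied.
#' @return list with `kept` (character ids), and per-filter dropped id
#'   lists `dropped_missing`, `dropped_het`, `dropped_ancestry`,
#'   `dropped_duplicate`.
#' @export
individual_filters <- function(geno, pcs, thresholds = qc_thresholds(),
                               reported_sex = NULL) {
  g <- geno$genotypes
  ids <- geno$individual_ids
  if (!is.null(reported_sex)) {
    warning("sex-mismatch check skipped: requires sex-chromosome data")
  }
  miss <- rowMeans(is.na(g))
  het <- rowMeans(g == 1, na.rm = TRUE)
  het[is.nan(het)] <- NA
  het_mu <- mean(het, na.rm = TRUE)
  het_sd <- stats::sd(het, na.rm = TRUE)
  drop_miss <- miss > thresholds$ind_missing_max
  drop_het <- if (is.na(het_sd) || het_sd == 0) rep(FALSE, length(ids)) else
    !is.na(het) & abs(het - het_mu) > thresholds$het_outlier_sd * het_sd
  pcs <- as.data.frame(pcs)
  pc_cols <- grep("^PC[0-9]+$", names(pcs), value = TRUE)
  if (!length(pc_cols)) pc_cols <- names(pcs)[seq_len(min(5, ncol(pcs)))]
  drop_anc <- rep(FALSE, length(ids))
  for (cn in pc_cols) {
    v <- pcs[[cn]]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) next
    drop_anc <- drop_anc | abs(v - mean(v)) > thresholds$ancestry_outlier_sd * s
  }
  key <- apply(g, 1, paste, collapse = ",")
  drop_dup <- duplicated(key)
  keep <- !(drop_miss | drop_het | drop_anc | drop_dup)
  list(kept = ids[keep],
       dropped_missing = ids[drop_miss],
       dropped_het = ids[drop_het],
       dropped_ancestry = ids[drop_anc],
       dropped_duplicate = ids[drop_dup])
}

.snp_pass <- function(stats, thresholds) {
  with(stats, defined &
         !is.na(maf) & maf >= thresholds$maf_min &
         call_rate >= 1 - thresholds$snp_missing_max &
         !is.na(hwe_p) & hwe_p >= thresholds$hwe_p_min)
}

#' Two-protocol union quality control
#'
#' Runs two QC protocols (each a full threshold set) on the same input
#' snapshot and retains the union of survivors, separately for individuals
#' and for SNPs: an individual or SNP that passes either protocol remains
#' in the final data set. Running both protocols with identical thresholds
#' reduces to single-protocol QC.
#'
#' @param geno a `genotype_matrix`.
#' @param pcs principal components aligned to individuals (see
#'   [individual_filters()]).
#' @param protoA,protoB [qc_thresholds()] objects for the two protocols.
#' @return list with `genotypes` (filtered `genotype_matrix`) and `report`
#'   (a `qc_report`: per-protocol pass sets, per-filter removal counts,
#'   per-SNP statistics).
#' @export
union_qc <- function(geno, pcs, protoA = qc_thresholds(),
                     protoB = protoA) {
  st <- snp_stats(geno)
  indA <- individual_filters(geno, pcs, protoA)
  indB <- individual_filters(geno, pcs, protoB)
  snpA <- st$rsid[.snp_pass(st, protoA)]
  snpB <- st$rsid[.snp_pass(st, protoB)]
  keep_ind <- geno$individual_ids[geno$individual_ids %in%
                                    union(indA$kept, indB$kept)]
  keep_snp <- st$rsid[st$rsid %in% union(snpA, snpB)]
  out <- genotype_matrix(
    geno$genotypes[keep_ind, keep_snp, drop = FALSE],
    geno$snp_meta[match(keep_snp, geno$snp_meta$rsid), , drop = FALSE],
    keep_ind)
  report <- structure(list(
    n_individuals_in = length(geno$individual_ids),
    n_snps_in = nrow(st),
    kept_individuals = keep_ind,
    kept_snps = keep_snp,
    protocolA = list(individuals = indA, snps = snpA),
    protocolB = list(individuals = indB, snps = snpB),
    removal_counts = c(
      individuals_removed = length(geno$individual_ids) - length(keep_ind),
      snps_removed = nrow(st) - length(keep_snp),
      A_ind_missing = length(indA$dropped_missing),
      A_ind_het = length(indA$dropped_het),
      A_ind_ancestry = length(indA$dropped_ancestry),
      A_ind_duplicate = length(indA$dropped_duplicate),
      A_snp_failed = nrow(st) - length(snpA),
      B_snp_failed = nrow(st) - length(snpB)),
    snp_stats = st), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (two-protocol union retention)\n")
  cat(sprintf("individuals: %d in, %d kept (%d removed)\n",
              x$n_individuals_in, length(x$kept_individuals),
              x$n_individuals_in - length(x$kept_individuals)))
  cat(sprintf("SNPs: %d in, %d kept (%d removed)\n", x$n_snps_in,
              length(x$kept_snps), x$n_snps_in - length(x$kept_snps)))
  cat("per-filter removals:\n")
  print(x$removal_counts)
  invisible(x)
}
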