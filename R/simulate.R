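#' Describe one gene for the genotype simulator
#'
#' A gene is a set of SNPs with target minor allele frequencies, partitioned
#' into LD blocks. Genotypes within a block are generated with a common
#' target pairwise genotype R-squared; genotypes in different blocks (and in
#' different genes) are independent.
#'
#' @param label gene label attached to every SNP (used by the clumping
#'   stage, which clusters SNPs per gene).
#' @param maf numeric vector of target minor allele frequencies, one per
#'   SNP, each in (0, 0.5].
#' @param blocks either an integer vector of block sizes summing to
#'   `length(maf)`, or a list of integer index vectors partitioning
#'   `seq_along(maf)`.
#' @param r2 target within-block pairwise genotype R-squared in \[0, 1\].
#'   A single value, recycled per block.
#' @param chrom chromosome code written to SNP metadata.
#' @param pos_start base-pair position of the first SNP; SNPs are laid out
#'   every 500 bp.
#' @return a `gene_spec` list.
#' @export
gene_spec <- function(label, maf, blocks = length(maf), r2 = 0.8,
                      chrom = 1L, pos_start = 1e6) {
  maf <- as.numeric(maf)
  if (any(maf <= 0) || any(maf > 0.5)) {
    stop("every target MAF must be in (0, 0.5]; got ",
         paste(maf[maf <= 0 | maf > 0.5], collapse = ", "))
  }
  if (!is.list(blocks)) {
    sizes <- as.integer(blocks)
    if (sum(sizes) != length(maf)) {
      stop("block sizes must sum to the number of SNPs")
    }
    blocks <- split(seq_along(maf), rep(seq_along(sizes), sizes))
  }
  idx <- sort(unname(unlist(blocks)))
  if (!identical(idx, seq_along(maf))) {
    stop("block partition must cover each SNP of the gene exactly once")
  }
  r2 <- rep_len(as.numeric(r2), length(blocks))
  if (any(r2 < 0) || any(r2 > 1)) stop("target R^2 must be in [0, 1]")
  structure(list(label = label, maf = maf, blocks = blocks, r2 = r2,
                 chrom = chrom, pos_start = pos_start),
            class = "gene_spec")
}

#' Simulation configuration
#'
#' Collects everything the synthetic cohort generator needs: sample size,
#' gene/LD structure, covariate prevalences, and the logistic trait model.
#' Defaults emulate a two-gene candidate study at the scale of a large
#' ageing cohort: 63 SNPs in eight LD blocks (geneA, a stress-sensor gene
#' proxy) and 8 SNPs in one block (geneB, a cell-fate regulator proxy),
#' n = 6142 individuals with an expected 2564 cases and 3578 controls, one
#' cross-gene interaction of log-odds 0.60 on the first SNP of each gene,
#' and no main effects.
#'
#' @param n_individuals number of individuals.
#' @param genes list of [gene_spec()] objects.
#' @param covariates named list of Bernoulli prevalences for `education`,
#'   `smoking` and `sex` (proportion female); PC1-PC5 are always standard
#'   normal.
#' @param intercept trait-model intercept on the log-odds scale, or `NULL`
#'   to calibrate it so the expected case fraction equals `case_fraction`.
#' @param main_effects named numeric vector of per-SNP log-odds main
#'   effects (additive coding); names are rsids.
#' @param interaction_effects data frame with columns `snp1`, `snp2`,
#'   `beta`: log-odds coefficients on the genotype product.
#' @param covariate_effects named numeric vector of covariate log-odds.
#' @param case_fraction target expected case fraction used when
#'   `intercept = NULL`.
#' @param missing_rate genotype missingness rate (missing completely at
#'   random), in \[0, 1).
#' @param exclude_fraction fraction of individuals assigned an age below
#'   the control window (to exercise trait exclusion logic).
#' @param seed master seed; expanded into independent per-stage substreams.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals = 6142,
                       genes = default_genes(),
                       covariates = list(education = 0.94, smoking = 0.57,
                                         sex = 0.569),
                       intercept = NULL,
                       main_effects = numeric(0),
                       interaction_effects = default_interactions(genes),
                       covariate_effects = c(education = 0.25,
                                             smoking = -0.25, sex = 0.1),
                       case_fraction = 2564 / 6142,
                       missing_rate = 0,
                       exclude_fraction = 0,
                       seed = 1L) {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (exclude_fraction < 0 || exclude_fraction >= 1) {
    stop("exclude_fraction must be in [0, 1)")
  }
  stopifnot(all(vapply(genes, inherits, TRUE, "gene_spec")))
  labs <- vapply(genes, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("gene labels must be unique")
  structure(list(n_individuals = as.integer(n_individuals), genes = genes,
                 covariates = covariates, intercept = intercept,
                 main_effects = main_effects,
                 interaction_effects = interaction_effects,
                 covariate_effects = covariate_effects,
                 case_fraction = case_fraction,
                 missing_rate = missing_rate,
                 exclude_fraction = exclude_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default two-gene LD structure
#'
#' geneA: 63 SNPs in eight blocks (sizes 8,8,8,8,8,8,8,7) whose block MAFs
#' are 0.06, 0.03, 0.47, 0.03, 0.05, 0.44, 0.02, 0.13 (spanning 0.02-0.47);
#' geneB: 8 SNPs in one block at MAF 0.14. Within-block target R2 = 0.8.
#'
#' @return list of two [gene_spec()] objects.
#' @export
default_genes <- function() {
  maf_a <- c(0.06, 0.03, 0.47, 0.03, 0.05, 0.44, 0.02, 0.13)
  sizes <- c(8, 8, 8, 8, 8, 8, 8, 7)
  list(
    gene_spec("geneA", maf = rep(maf_a, sizes), blocks = sizes, r2 = 0.8,
              chrom = 15L, pos_start = 39e6),
    gene_spec("geneB", maf = rep(0.14, 8), blocks = 8, r2 = 0.8,
              chrom = 12L, pos_start = 57e6)
  )
}

#' Default planted interaction: first SNP of gene 1 x first SNP of gene 2,
#' log-odds 0.60.
#' @param genes list of [gene_spec()] objects (at least two).
#' @return data frame with columns snp1, snp2, beta.
#' @export
default_interactions <- function(genes) {
  if (length(genes) < 2) return(data.frame(snp1 = character(0),
                                           snp2 = character(0),
                                           beta = numeric(0)))
  data.frame(snp1 = .snp_ids(genes[[1]])[1],
             snp2 = .snp_ids(genes[[2]])[1],
             beta = 0.60, stringsAsFactors = FALSE)
}

.snp_ids <- function(gene) {
  sprintf("%s_snp%02d", gene$label, seq_along(gene$maf))
}

# Independent per-stage seeds derived from the master seed, so that e.g.
# regenerating covariates does not shift the genotype stream.
.stage_seed <- function(seed, stage) {
  offs <- c(genotypes = 11L, covariates = 29L, trait = 47L, missing = 83L,
            split = 101L)
  (as.integer(seed) * 1009L + offs[[stage]]) %% .Machine$integer.max
}

# ---- latent-Gaussian LD calibration -------------------------------------

# upper-orthant probability P(Z1 > t1, Z2 > t2) for standard bivariate
# normal with correlation rho, by one-dimensional quadrature
.bvn_upper <- function(t1, t2, rho) {
  rho <- max(min(rho, 0.9999999), -0.9999999)
  s <- sqrt(1 - rho^2)
  f <- function(z) {
    stats::dnorm(z) * stats::pnorm((t2 - rho * z) / s, lower.tail = FALSE)
  }
  stats::integrate(f, lower = t1, upper = Inf, rel.tol = 1e-11,
                   abs.tol = 1e-13)$value
}

# correlation between threshold indicators 1(Z1 > t1), 1(Z2 > t2)
.allele_corr <- function(maf1, maf2, rho) {
  t1 <- stats::qnorm(1 - maf1)
  t2 <- stats::qnorm(1 - maf2)
  p11 <- .bvn_upper(t1, t2, rho)
  (p11 - maf1 * maf2) / sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

#' Maximum attainable genotype R-squared between two loci
#'
#' With unequal allele frequencies two loci cannot be perfectly correlated:
#' the allele-indicator correlation is bounded by the comonotone coupling.
#'
#' @param maf1,maf2 minor allele frequencies in (0, 0.5].
#' @return the maximum attainable genotype R-squared.
#' @export
max_attainable_r2 <- function(maf1, maf2) {
  r <- (min(maf1, maf2) - maf1 * maf2) /
    sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
  r^2
}

# monotone search for the latent correlation that realises a target
# genotype R^2 between two thresholded loci
.calibrate_rho <- function(maf1, maf2, r2_target) {
  if (r2_target == 0) return(0)
  r_target <- sqrt(r2_target)
  r_max <- sqrt(max_attainable_r2(maf1, maf2))
  if (r_target > r_max + 1e-8) {
    stop(sprintf(paste0("target R^2 = %.4g is unattainable for MAFs ",
                        "%.4g and %.4g; the maximum attainable R^2 is ",
                        "%.4g"),
                 r2_target, maf1, maf2, r_max^2))
  }
  if (r_target >= r_max - 1e-10) return(1)
  stats::uniroot(function(rho) .allele_corr(maf1, maf2, rho) - r_target,
                 lower = 0, upper = 0.9999999, tol = 1e-9)$root
}

# latent correlation matrix for one block; exact-LD blocks (rho == 1) are
# handled upstream by sharing a single latent column
.block_sigma <- function(maf, r2_target) {
  m <- length(maf)
  sig <- diag(m)
  if (m == 1 || r2_target == 0) return(sig)
  for (i in seq_len(m - 1)) {
    for (j in seq.int(i + 1, m)) {
      sig[i, j] <- sig[j, i] <- .calibrate_rho(maf[i], maf[j], r2_target)
    }
  }
  sig
}

.chol_psd <- function(sigma) {
  tryCatch(chol(sigma), error = function(e) {
    eg <- eigen(sigma, symmetric = TRUE)
    vals <- pmax(eg$values, 1e-8)
    s <- eg$vectors %*% (vals * t(eg$vectors))
    d <- sqrt(diag(s))
    chol(s / tcrossprod(d))
  })
}

#' Simulate genotypes
#'
#' Generates additive-coded genotypes (counts of the minor allele, 0/1/2)
#' under a latent-Gaussian threshold model applied per haplotype: each
#' haplotype's alleles are indicators of correlated standard normals
#' exceeding the per-SNP threshold `qnorm(1 - MAF)`, and an individual's
#' genotype is the sum of two independent haplotypes. The latent
#' correlation within each LD block is calibrated by monotone root search
#' so that the realised genotype R-squared matches the block's target; the
#' genotype correlation equals the haplotype allele correlation because the
#' two haplotypes are independent and identically distributed. A target
#' R-squared of 1 (attainable only at equal MAFs) shares a single latent
#' variable, producing identical genotype columns.
#'
#' @param config a [sim_config()].
#' @return a `genotype_matrix`: list with `genotypes` (n x m integer matrix
#'   with NA for missing), `snp_meta` (data frame: rsid, gene, chrom, pos,
#'   ea, nea, minor_allele), `individual_ids`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config$seed, "genotypes"))
  n <- config$n_individuals
  geno_cols <- list()
  meta <- list()
  for (gene in config$genes) {
    ids <- .snp_ids(gene)
    m <- length(gene$maf)
    g_gene <- matrix(0L, n, m)
    for (b in seq_along(gene$blocks)) {
      idx <- gene$blocks[[b]]
      maf_b <- gene$maf[idx]
      r2_b <- gene$r2[b]
      if (r2_b == 1 && length(idx) > 1) {
        if (length(unique(maf_b)) > 1) {
          .calibrate_rho(min(maf_b), max(maf_b), 1) # raises with the bound
        }
        z <- matrix(stats::rnorm(2 * n), 2 * n, 1)
        z <- z[, rep(1, length(idx)), drop = FALSE]
      } else {
        sig <- .block_sigma(maf_b, r2_b)
        z <- matrix(stats::rnorm(2 * n * length(idx)), 2 * n) %*%
          .chol_psd(sig)
      }
      thr <- stats::qnorm(1 - maf_b)
      x <- sweep(z, 2, thr, ">")
      g_gene[, idx] <- x[seq_len(n), , drop = FALSE] +
        x[seq.int(n + 1, 2 * n), , drop = FALSE]
    }
    alle <- replicate(m, sample(c("A", "C", "G", "T"), 2))
    minor_is_ea <- sample(c(TRUE, FALSE), m, replace = TRUE)
    meta[[gene$label]] <- data.frame(
      rsid = ids, gene = gene$label, chrom = gene$chrom,
      pos = gene$pos_start + 500L * seq_len(m),
      ea = alle[1, ], nea = alle[2, ],
      minor_allele = ifelse(minor_is_ea, alle[1, ], alle[2, ]),
      stringsAsFactors = FALSE)
    geno_cols[[gene$label]] <- g_gene
  }
  g <- do.call(cbind, geno_cols)
  snp_meta <- do.call(rbind, meta)
  rownames(snp_meta) <- NULL
  ind_ids <- sprintf("ind%06d", seq_len(n))
  dimnames(g) <- list(ind_ids, snp_meta$rsid)
  if (config$missing_rate > 0) {
    set.seed(.stage_seed(config$seed, "missing"))
    g[stats::runif(length(g)) < config$missing_rate] <- NA_integer_
  }
  genotype_matrix(g, snp_meta)
}

#' Construct a genotype matrix container
#'
#' @param genotypes integer matrix of minor-allele counts (0/1/2, NA for
#'   missing), individuals in rows, SNPs in columns.
#' @param snp_meta data frame with at least columns `rsid`, `gene`,
#'   `chrom`, `pos`, `ea`, `nea`, `minor_allele`, one row per column of
#'   `genotypes`.
#' @param individual_ids optional character vector; defaults to rownames.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, snp_meta, individual_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("non-missing genotypes must be 0, 1 or 2")
  }
  if (is.null(individual_ids)) individual_ids <- rownames(genotypes)
  if (is.null(individual_ids)) {
    individual_ids <- sprintf("ind%06d", seq_len(nrow(genotypes)))
  }
  if (anyDuplicated(individual_ids)) stop("individual ids must be unique")
  if (anyDuplicated(snp_meta$rsid)) stop("SNP ids must be unique")
  if (nrow(snp_meta) != ncol(genotypes)) {
    stop("snp_meta must have one row per genotype column")
  }
  dimnames(genotypes) <- list(individual_ids, snp_meta$rsid)
  rownames(snp_meta) <- NULL
  structure(list(genotypes = genotypes, snp_meta = snp_meta,
                 individual_ids = individual_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "SNPs\n")
  tab <- table(x$snp_meta$gene)
  cat("genes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("missingness: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Simulate covariates
#'
#' Education, smoking and sex are Bernoulli at the configured prevalences
#' (sex = 1 codes female); PC1-PC5 are i.i.d. standard normal stand-ins for
#' genetic principal components.
#'
#' @param config a [sim_config()].
#' @return data frame with `individual_id`, `education`, `smoking`, `sex`,
#'   `PC1`..`PC5`.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config$seed, "covariates"))
  n <- config$n_individuals
  cv <- config$covariates
  out <- data.frame(
    individual_id = sprintf("ind%06d", seq_len(n)),
    education = stats::rbinom(n, 1, cv$education),
    smoking = stats::rbinom(n, 1, cv$smoking),
    sex = stats::rbinom(n, 1, cv$sex),
    stringsAsFactors = FALSE)
  for (k in 1:5) out[[paste0("PC", k)]] <- stats::rnorm(n)
  out
}

#' Simulate the survival trait
#'
#' Draws the case indicator from the logistic model
#' `logit P(case) = b0 + sum(main * g) + sum(b12 * g_a * g_b) +
#' sum(gamma * x)`, then assigns ages: cases get a lifespan of 85 plus an
#' exponential excess (mean 4 years); controls get an age (death or last
#' follow-up) uniform on \[75, 85). A configured fraction of individuals is
#' instead given an age uniform on \[60, 75) to exercise exclusion logic.
#' Missing genotypes contribute their expected value (2 x MAF target) to
#' the linear predictor.
#'
#' @param geno a `genotype_matrix` from [simulate_genotypes()].
#' @param covariates data frame from [simulate_covariates()].
#' @param config the [sim_config()] used to generate both.
#' @return data frame with `individual_id`, `age`, `died` (logical; TRUE =
#'   lifespan observed). The latent case indicator is attached as attribute
#'   `"true_case"` for parameter-recovery tests.
#' @export
simulate_trait <- function(geno, covariates, config) {
  stopifnot(inherits(config, "sim_config"))
  g <- geno$genotypes
  if (!identical(rownames(g), covariates$individual_id)) {
    stop("genotype and covariate tables must be aligned on individuals")
  }
  set.seed(.stage_seed(config$seed, "trait"))
  n <- nrow(g)
  eta <- numeric(n)
  maf_target <- unlist(lapply(config$genes, `[[`, "maf"))
  names(maf_target) <- unlist(lapply(config$genes, .snp_ids))
  gcol <- function(id) {
    if (!id %in% colnames(g)) {
      stop("trait model references unknown SNP: ", id)
    }
    v <- as.numeric(g[, id])
    if (anyNA(v)) {
      v[is.na(v)] <- 2 * maf_target[[id]]
    }
    v
  }
  if (length(config$main_effects)) {
    for (id in names(config$main_effects)) {
      eta <- eta + config$main_effects[[id]] * gcol(id)
    }
  }
  ie <- config$interaction_effects
  if (!is.null(ie) && nrow(ie)) {
    for (k in seq_len(nrow(ie))) {
      eta <- eta + ie$beta[k] * gcol(ie$snp1[k]) * gcol(ie$snp2[k])
    }
  }
  if (length(config$covariate_effects)) {
    for (nm in names(config$covariate_effects)) {
      if (!nm %in% names(covariates)) {
        stop("trait model references unknown covariate: ", nm)
      }
      eta <- eta + config$covariate_effects[[nm]] * covariates[[nm]]
    }
  }
  b0 <- config$intercept
  if (is.null(b0)) {
    b0 <- stats::uniroot(
      function(b) mean(stats::plogis(b + eta)) - config$case_fraction,
      lower = -30, upper = 30, tol = 1e-10)$root
  }
  case <- stats::rbinom(n, 1, stats::plogis(b0 + eta))
  age <- ifelse(case == 1, 85 + stats::rexp(n, rate = 1 / 4),
                stats::runif(n, 75, 85))
  died <- stats::runif(n) < ifelse(case == 1, 0.6, 0.7)
  if (config$exclude_fraction > 0) {
    drop_idx <- stats::runif(n) < config$exclude_fraction
    age[drop_idx] <- stats::runif(sum(drop_idx), 60, 75)
  }
  out <- data.frame(individual_id = rownames(g), age = age, died = died,
                    stringsAsFactors = FALSE)
  attr(out, "true_case") <- case
  attr(out, "intercept") <- b0
  out
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_covariates()] and [simulate_trait()] under one configuration.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort` with `genotypes`, `covariates`,
#'   `phenotypes`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  geno <- simulate_genotypes(config)
  covars <- simulate_covariates(config)
  pheno <- simulate_trait(geno, covars, config)
  structure(list(genotypes = geno, covariates = covars,
                 phenotypes = pheno, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic cohort: n =", x$config$n_individuals, "\n")
  print(x$genotypes)
  cat("expected case fraction:", format(x$config$case_fraction), "\n")
  invisible(x)
}
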