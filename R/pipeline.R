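#' Pipeline configuration
#'
#' Bundles every stage's configuration with a master seed. Stages:
#' simulate (optional; skipped when `geno_prefix` points at existing
#' PLINK data), qc, trait, cross-gene scan, clump, SIPRS.
#'
#' @param sim a [sim_config()] or NULL to read genotypes from
#'   `geno_prefix`.
#' @param geno_prefix PLINK prefix to read when `sim` is NULL; also used
#'   as the simulated-output prefix name.
#' @param qc_a,qc_b [qc_thresholds()] for the two union-QC protocols.
#' @param trait a [trait_config()].
#' @param scan a [scan_config()].
#' @param genes character vector of the two gene labels scanned against
#'   each other (defaults to the first two labels in the data).
#' @param clump_r2 LD threshold for clumping.
#' @param alpha family-wise level for the Bonferroni correction.
#' @param siprs_grid threshold grid for the SIPRS sweep.
#' @param siprs_weighting `"beta"` or `"count"`.
#' @param siprs_fixed fixed SNP for the SIPRS stage; default: rsid1 of the
#'   most significant independent pair.
#' @param split_sample evaluate SIPRS on a held-out half.
#' @param seed master seed recorded in every stage's metadata.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), geno_prefix = "genotypes",
                            qc_a = qc_thresholds(), qc_b = qc_a,
                            trait = trait_config(), scan = scan_config(),
                            genes = NULL, clump_r2 = 0.1, alpha = 0.05,
                            siprs_grid = episurv::siprs_grid(),
                            siprs_weighting = "beta", siprs_fixed = NULL,
                            split_sample = FALSE, seed = 1L) {
  structure(list(sim = sim, geno_prefix = geno_prefix, qc_a = qc_a,
                 qc_b = qc_b, trait = trait, scan = scan, genes = genes,
                 clump_r2 = clump_r2, alpha = alpha,
                 siprs_grid = siprs_grid,
                 siprs_weighting = siprs_weighting,
                 siprs_fixed = siprs_fixed, split_sample = split_sample,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage_metadata <- function(out_dir, stage, seed, files) {
  files <- files[file.exists(files)]
  md <- list(stage = stage, seed = seed,
             package_version = as.character(utils::packageVersion("episurv")),
             outputs = as.list(stats::setNames(
               unname(tools::md5sum(files)), basename(files))))
  jsonlite::write_json(md, file.path(out_dir,
                                     paste0(stage, ".meta.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> QC -> trait -> cross-gene interaction
#' scan -> LD clumping -> SIPRS sweep, writing each stage's outputs and a
#' JSON metadata sidecar (seed, package version, output checksums) into
#' `out_dir`. Re-running with an identical configuration and seed
#' reproduces byte-identical result files. A stage failure halts the run,
#' names the failing stage, and leaves a `FAILED` marker next to the
#' partial outputs.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return list of class `episurv_pipeline` with the in-memory stage
#'   results (`cohort`, `qc`, `trait_cohort`, `scan`, `independent_pairs`,
#'   `siprs`), invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out_dir, "FAILED"))
  stage <- "setup"
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      writeLines(paste("failed at stage:", name, "-",
                       conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  prefix <- file.path(out_dir, basename(cfg$geno_prefix))

  sim_out <- run_stage("simulate", {
    if (!is.null(cfg$sim)) {
      cohort <- simulate_cohort(cfg$sim)
      write_plink(cohort$genotypes, prefix)
      write_phenotypes(cohort$phenotypes,
                       file.path(out_dir, "phenotypes.tsv"))
      write_covariates(cohort$covariates,
                       file.path(out_dir, "covariates.tsv"))
      jsonlite::write_json(
        list(seed = cfg$sim$seed,
             n_individuals = cfg$sim$n_individuals,
             case_fraction = cfg$sim$case_fraction,
             intercept = attr(cohort$phenotypes, "intercept"),
             main_effects = as.list(cfg$sim$main_effects),
             interaction_effects = cfg$sim$interaction_effects,
             covariate_effects = as.list(cfg$sim$covariate_effects)),
        file.path(out_dir, "true_parameters.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
      .stage_metadata(out_dir, "simulate", cfg$seed,
                      c(paste0(prefix, c(".bed", ".bim", ".fam")),
                        file.path(out_dir, c("phenotypes.tsv",
                                             "covariates.tsv",
                                             "true_parameters.json"))))
      cohort
    } else {
      geno <- read_plink(cfg$geno_prefix)
      list(genotypes = geno,
           covariates = read_covariates(file.path(out_dir,
                                                  "covariates.tsv")),
           phenotypes = read_phenotypes(file.path(out_dir,
                                                  "phenotypes.tsv")))
    }
  })

  qc_out <- run_stage("qc", {
    pcs <- sim_out$covariates[, paste0("PC", 1:5)]
    res <- union_qc(sim_out$genotypes, pcs, cfg$qc_a, cfg$qc_b)
    jsonlite::write_json(
      list(n_individuals_in = res$report$n_individuals_in,
           n_snps_in = res$report$n_snps_in,
           n_individuals_kept = length(res$report$kept_individuals),
           n_snps_kept = length(res$report$kept_snps),
           removal_counts = as.list(res$report$removal_counts)),
      file.path(out_dir, "qc_report.json"), auto_unbox = TRUE,
      pretty = TRUE)
    .write_tsv(res$report$snp_stats, file.path(out_dir, "snp_stats.tsv"))
    .stage_metadata(out_dir, "qc", cfg$seed,
                    file.path(out_dir, c("qc_report.json",
                                         "snp_stats.tsv")))
    res
  })

  cohort <- run_stage("trait", {
    co <- build_cohort(sim_out$phenotypes, cfg$trait, sim_out$covariates,
                       qc_out$genotypes$individual_ids)
    write_labels(co$labels, file.path(out_dir, "labels.tsv"))
    .write_tsv(co$summary, file.path(out_dir, "cohort_summary.tsv"))
    .stage_metadata(out_dir, "trait", cfg$seed,
                    file.path(out_dir, c("labels.tsv",
                                         "cohort_summary.tsv")))
    co
  })

  scan <- run_stage("scan", {
    genes <- cfg$genes
    if (is.null(genes)) {
      genes <- utils::head(unique(qc_out$genotypes$snp_meta$gene), 2)
    }
    if (length(genes) < 2) stop("need two gene labels to scan")
    sc <- cross_gene_scan(qc_out$genotypes, genes[1], genes[2],
                          sim_out$covariates, cohort$labels, cfg$scan)
    write_scan_results(sc, file.path(out_dir, "scan_results.tsv"))
    .stage_metadata(out_dir, "scan", cfg$seed,
                    file.path(out_dir, "scan_results.tsv"))
    sc
  })

  clumped <- run_stage("clump", {
    genes <- cfg$genes
    if (is.null(genes)) {
      genes <- utils::head(unique(qc_out$genotypes$snp_meta$gene), 2)
    }
    cl <- clump_pairs(scan, qc_out$genotypes, genes[1], genes[2],
                      r2 = cfg$clump_r2, alpha = cfg$alpha)
    .write_tsv(as.data.frame(cl),
               file.path(out_dir, "independent_pairs.tsv"))
    membership <- do.call(rbind, lapply(
      list(A = attr(cl, "clustersA"), B = attr(cl, "clustersB")),
      function(cls) do.call(rbind, lapply(seq_along(cls), function(i) {
        data.frame(cluster = i, seed = cls[[i]]$seed,
                   rsid = cls[[i]]$members, stringsAsFactors = FALSE)
      }))))
    .write_tsv(membership, file.path(out_dir, "cluster_membership.tsv"))
    .stage_metadata(out_dir, "clump", cfg$seed,
                    file.path(out_dir, c("independent_pairs.tsv",
                                         "cluster_membership.tsv")))
    cl
  })

  siprs <- run_stage("siprs", {
    fixed <- cfg$siprs_fixed
    if (is.null(fixed)) fixed <- clumped$rsid1[1]
    an <- siprs_analysis(qc_out$genotypes, fixed, cohort$labels,
                         sim_out$covariates, grid = cfg$siprs_grid,
                         weighting = cfg$siprs_weighting,
                         split_sample = cfg$split_sample,
                         seed = cfg$seed, cfg = cfg$scan)
    .write_tsv(as.data.frame(an$sweep),
               file.path(out_dir, "siprs_sweep.tsv"))
    .stage_metadata(out_dir, "siprs", cfg$seed,
                    file.path(out_dir, "siprs_sweep.tsv"))
    an
  })

  invisible(structure(list(cohort = sim_out, qc = qc_out,
                           trait_cohort = cohort, scan = scan,
                           independent_pairs = clumped, siprs = siprs,
                           out_dir = out_dir),
                      class = "episurv_pipeline"))
}

#' @export
print.episurv_pipeline <- function(x, ...) {
  cat("episurv pipeline run ->", x$out_dir, "\n")
  print(x$independent_pairs)
  print(x$siprs$sweep)
  invisible(x)
}
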