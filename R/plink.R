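#' Write genotypes as PLINK bed/bim/fam
#'
#' Writes PLINK 1 binary files (v1.00 magic bytes, SNP-major). The bed
#' 2-bit codes follow the PLINK convention with A1 = the minor allele:
#' 00 = homozygous A1 (genotype 2), 10 = heterozygous (1), 11 = homozygous
#' A2 (0), 01 = missing; four samples per byte, first sample in the two
#' lowest bits. The bim records chromosome, rsid, 0 cM, 1-based position,
#' A1 (minor) and A2 alleles.
#'
#' @param geno a `genotype_matrix`.
#' @param prefix output path prefix (writes `prefix.bed/.bim/.fam`).
#' @return the prefix, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  g <- geno$genotypes
  n <- nrow(g)
  m <- ncol(g)
  meta <- geno$snp_meta
  # bed codes per additive genotype: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(1L, n, m)
  code[!is.na(g) & g == 2L] <- 0L
  code[!is.na(g) & g == 1L] <- 2L
  code[!is.na(g) & g == 0L] <- 3L
  bpv <- ceiling(n / 4)
  pad <- bpv * 4 - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  i1 <- seq.int(1, bpv * 4, by = 4)
  bytes <- code[i1, , drop = FALSE] +
    4L * code[i1 + 1, , drop = FALSE] +
    16L * code[i1 + 2, , drop = FALSE] +
    64L * code[i1 + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  a2 <- ifelse(meta$minor_allele == meta$ea, meta$nea, meta$ea)
  bim <- data.frame(meta$chrom, meta$rsid, 0L, meta$pos,
                    meta$minor_allele, a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(geno$individual_ids, geno$individual_ids, 0L, 0L, 0L,
                    -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK bed/bim/fam genotypes
#'
#' Reads PLINK 1 binary genotypes (SNP-major) into additive minor-allele
#' counts, with missing calls preserved as NA. Round-trips bit-exactly
#' with [write_plink()]. Gene labels are recovered from the rsid prefix
#' (text before the last `_snpNN` suffix) when present, else set to NA.
#'
#' @param prefix path prefix of the `.bed/.bim/.fam` triple.
#' @return a `genotype_matrix`.
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  for (ext in c(".bed", ".bim", ".fam")) {
    if (!file.exists(paste0(prefix, ext))) {
      stop("missing PLINK file: ", paste0(prefix, ext))
    }
  }
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           colClasses = "character")
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           colClasses = c("character", "character",
                                          "character", "integer",
                                          "character", "character"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK bed file (magic bytes mismatch): ", bed_path)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major bed files are supported: ", bed_path)
  }
  bpv <- ceiling(n / 4)
  if (length(raw) - 3 != bpv * m) {
    stop(sprintf(paste0("bed size mismatch (truncated file or fam/bim ",
                        "disagreement): expected %d genotype bytes, ",
                        "found %d"), bpv * m, length(raw) - 3))
  }
  bytes <- as.integer(raw[-(1:3)])
  # expand each byte into its four 2-bit fields
  codes <- rbind(bytes %% 4L, (bytes %/% 4L) %% 4L,
                 (bytes %/% 16L) %% 4L, (bytes %/% 64L) %% 4L)
  codes <- matrix(as.integer(codes), nrow = bpv * 4, ncol = m)
  codes <- codes[seq_len(n), , drop = FALSE]
  g <- matrix(NA_integer_, n, m)
  g[codes == 0L] <- 2L
  g[codes == 2L] <- 1L
  g[codes == 3L] <- 0L
  ids <- fam[[2]]
  gene <- sub("_snp[0-9]+$", "", bim[[2]])
  gene[gene == bim[[2]]] <- NA
  meta <- data.frame(rsid = bim[[2]], gene = gene, chrom = bim[[1]],
                     pos = bim[[4]], ea = bim[[5]], nea = bim[[6]],
                     minor_allele = bim[[5]], stringsAsFactors = FALSE)
  genotype_matrix(g, meta, ids)
}

# shared TSV dialect: tab-separated, UTF-8, '.' decimal, NA for missing
.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
}

.read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop(path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x
}

#' Read/write phenotype, covariate and label tables
#'
#' Phenotype TSVs have columns `individual_id`, `age`, `died`; covariate
#' TSVs have `individual_id`, `education`, `smoking`, `sex`, `PC1`..`PC5`;
#' label TSVs have `individual_id`, `label` (1 = case).
#'
#' @param x table to write.
#' @param path file path.
#' @name tsv_io
NULL

#' @rdname tsv_io
#' @export
write_phenotypes <- function(x, path) .write_tsv(x, path)

#' @rdname tsv_io
#' @export
read_phenotypes <- function(path) {
  .read_tsv(path, c("individual_id", "age", "died"))
}

#' @rdname tsv_io
#' @export
write_covariates <- function(x, path) .write_tsv(x, path)

#' @rdname tsv_io
#' @export
read_covariates <- function(path) {
  .read_tsv(path, c("individual_id"))
}

#' @rdname tsv_io
#' @export
write_labels <- function(labels, path) {
  .write_tsv(data.frame(individual_id = names(labels),
                        label = unname(labels)), path)
}

#' @rdname tsv_io
#' @export
read_labels <- function(path) {
  x <- .read_tsv(path, c("individual_id", "label"))
  stats::setNames(x$label, x$individual_id)
}

#' @rdname tsv_io
#' @export
write_scan_results <- function(x, path) {
  .write_tsv(as.data.frame(x), path)
}

#' @rdname tsv_io
#' @export
read_scan_results <- function(path) {
  x <- .read_tsv(path, c("rsid1", "rsid2", "b12", "p12"))
  structure(x, class = c("interaction_scan", "data.frame"))
}
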