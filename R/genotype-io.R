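#' Construct a genotype matrix object
#'
#' Container for hard-call biallelic genotypes stored as additive dosages of
#' the counted allele (0, 1, 2, or `NA` for missing), together with per-SNP
#' metadata and sample identifiers. The counted allele is A1 (column 5 of a
#' PLINK .bim file), matching the PLINK convention: per-SNP effect estimates
#' flip sign if the counted allele is swapped, while heritability and GRM
#' entries are invariant to the choice.
#'
#' @param dosages numeric matrix, individuals in rows, SNPs in columns;
#'   entries in \{0, 1, 2, NA\}.
#' @param snp_meta data.frame with columns `chromosome`, `id`, `position`
#'   (1-based), `allele_counted`, `allele_other`; one row per SNP. Generated
#'   automatically when omitted.
#' @param sample_ids data.frame with columns `family_id`, `individual_id`;
#'   one row per individual. Generated automatically when omitted.
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `snp_meta`, `sample_ids` and `allele_freq` (in-sample frequency of the
#'   counted allele, computed from non-missing dosages as mean/2).
#' @export
genotype_matrix <- function(dosages, snp_meta = NULL, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  m <- ncol(dosages)
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (is.null(snp_meta)) {
    snp_meta <- data.frame(
      chromosome = rep(1L, m),
      id = if (m > 0) paste0("snp", seq_len(m)) else character(0),
      position = seq_len(m),
      allele_counted = rep("A", m),
      allele_other = rep("G", m),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(sample_ids)) {
    sample_ids <- data.frame(
      family_id = paste0("F", seq_len(n)),
      individual_id = paste0("I", seq_len(n)),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(snp_meta) != m) {
    stop("snp_meta rows must match number of SNP columns")
  }
  if (nrow(sample_ids) != n) {
    stop("sample_ids rows must match number of individuals")
  }
  af <- colMeans(dosages, na.rm = TRUE) / 2
  af[is.nan(af)] <- NA_real_
  obj <- list(
    dosages = dosages,
    snp_meta = snp_meta,
    sample_ids = sample_ids,
    allele_freq = af
  )
  class(obj) <- "genotype_matrix"
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d individuals x %d SNPs (%.2f%% missing)\n",
    nrow(x$dosages), ncol(x$dosages),
    100 * mean(is.na(x$dosages))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# 2-bit PLINK codes (SNP-major .bed): 00 = hom A1 (dosage 2), 01 = missing,
# 10 = het (dosage 1), 11 = hom A2 (dosage 0).
.plink_code_to_dosage <- c(2, NA, 1, 0)
.plink_dosage_to_code <- function(d) {
  code <- integer(length(d))
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[!is.na(d) & d == 0] <- 3L
  code
}

# 256 x 4 lookup: dosages of the 4 samples packed in one byte
.plink_byte_lut <- local({
  lut <- matrix(NA_real_, 256, 4)
  for (b in 0:255) {
    for (s in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2L * s), 3L)
      lut[b + 1L, s + 1L] <- .plink_code_to_dosage[code + 1L]
    }
  }
  lut
})

#' Read a PLINK 1 binary fileset
#'
#' Reads `<prefix>.bed`, `<prefix>.bim` and `<prefix>.fam` into a
#' [genotype_matrix]. Only SNP-major .bed files (third magic byte 0x01) are
#' supported. Dosages count copies of allele A1 (.bim column 5); the missing
#' genotype code is preserved as `NA`.
#'
#' @param path_prefix path to the fileset without extension.
#' @return A [genotype_matrix].
#' @export
read_plink <- function(path_prefix) {
  bed_path <- paste0(path_prefix, ".bed")
  bim_path <- paste0(path_prefix, ".bim")
  fam_path <- paste0(path_prefix, ".fam")
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character")
  bim <- tryCatch(
    utils::read.table(bim_path, header = FALSE, colClasses = "character"),
    error = function(e) {
      # zero-SNP fileset: empty .bim
      data.frame(V1 = character(0), V2 = character(0), V3 = character(0),
                 V4 = character(0), V5 = character(0), V6 = character(0))
    }
  )
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, what = "raw", n = file.info(bed_path)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("bad magic bytes: not a PLINK 1 .bed file")
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major .bed files are supported")
  }
  bytes_per_snp <- ceiling(n / 4)
  payload <- raw[-(1:3)]
  if (length(payload) != bytes_per_snp * m) {
    stop(sprintf(
      ".bed payload (%d bytes) inconsistent with .bim/.fam (%d SNPs x %d bytes)",
      length(payload), m, bytes_per_snp
    ))
  }
  if (m == 0 || n == 0) {
    dos <- matrix(numeric(0), nrow = n, ncol = m)
  } else {
    idx <- as.integer(payload) + 1L
    # decode all bytes at once: (bytes_per_snp*m) x 4, then trim padding
    dec <- .plink_byte_lut[idx, , drop = FALSE]
    dos <- matrix(NA_real_, nrow = n, ncol = m)
    per_snp <- matrix(t(dec), nrow = 4 * bytes_per_snp, ncol = m)
    dos[] <- per_snp[seq_len(n), ]
  }
  snp_meta <- data.frame(
    chromosome = bim$V1,
    id = bim$V2,
    position = as.integer(bim$V4),
    allele_counted = bim$V5,
    allele_other = bim$V6,
    stringsAsFactors = FALSE
  )
  sample_ids <- data.frame(
    family_id = fam$V1,
    individual_id = fam$V2,
    stringsAsFactors = FALSE
  )
  genotype_matrix(dos, snp_meta, sample_ids)
}

#' Write a PLINK 1 binary fileset
#'
#' Writes `<prefix>.bed` (SNP-major), `<prefix>.bim` and `<prefix>.fam`.
#' Round-trips exactly through [read_plink], including the missingness
#' pattern.
#'
#' @param geno a [genotype_matrix].
#' @param path_prefix output path without extension.
#' @return `path_prefix`, invisibly.
#' @export
write_plink <- function(geno, path_prefix) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- nrow(geno$dosages)
  m <- ncol(geno$dosages)
  bed_path <- paste0(path_prefix, ".bed")
  con <- file(bed_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (m > 0 && n > 0) {
    bytes_per_snp <- ceiling(n / 4)
    codes <- matrix(0L, nrow = 4 * bytes_per_snp, ncol = m)
    codes[seq_len(n), ] <- .plink_dosage_to_code(geno$dosages)
    # pack 4 samples per byte, low bits = first sample
    i1 <- seq(1, 4 * bytes_per_snp, by = 4)
    packed <- codes[i1, , drop = FALSE] +
      4L * codes[i1 + 1L, , drop = FALSE] +
      16L * codes[i1 + 2L, , drop = FALSE] +
      64L * codes[i1 + 3L, , drop = FALSE]
    writeBin(as.raw(packed), con)
  }
  bim <- data.frame(
    geno$snp_meta$chromosome, geno$snp_meta$id, rep(0L, m),
    geno$snp_meta$position, geno$snp_meta$allele_counted,
    geno$snp_meta$allele_other
  )
  utils::write.table(bim, paste0(path_prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(
    geno$sample_ids$family_id, geno$sample_ids$individual_id,
    0L, 0L, 0L, -9L
  )
  utils::write.table(fam, paste0(path_prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path_prefix)
}

#' Write a GRM in GCTA binary format
#'
#' Writes the GCTA triad `<prefix>.grm.bin` (lower triangle including the
#' diagonal, row-major, float32), `<prefix>.grm.N.bin` (per-pair SNP counts,
#' float32, same order) and `<prefix>.grm.id` (FID and IID, tab-separated).
#'
#' @param grm a [grm] object (see [compute_grm]).
#' @param path_prefix output path without extension.
#' @return `path_prefix`, invisibly.
#' @export
write_grm_gcta <- function(grm, path_prefix) {
  stopifnot(inherits(grm, "grm"))
  A <- grm$matrix
  if (!isSymmetric(unname(A), tol = 1e-8)) {
    stop("GRM matrix must be symmetric")
  }
  n <- nrow(A)
  lower <- A[upper.tri(A, diag = TRUE)]      # column-major upper == row-major lower
  counts <- grm$pair_counts[upper.tri(grm$pair_counts, diag = TRUE)]
  con <- file(paste0(path_prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4)
  close(con)
  con <- file(paste0(path_prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(counts), con, size = 4)
  close(con)
  utils::write.table(grm$ids, paste0(path_prefix, ".grm.id"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path_prefix)
}

#' Read a GRM in GCTA binary format
#'
#' @param path_prefix path to the `.grm.bin`/`.grm.N.bin`/`.grm.id` triad
#'   without extension.
#' @return A [grm] object.
#' @export
read_grm_gcta <- function(path_prefix) {
  ids <- utils::read.table(paste0(path_prefix, ".grm.id"), header = FALSE,
                           colClasses = "character")
  names(ids) <- c("family_id", "individual_id")
  n <- nrow(ids)
  n_el <- n * (n + 1) / 2
  vals <- readBin(paste0(path_prefix, ".grm.bin"), what = "numeric",
                  n = n_el, size = 4)
  counts <- readBin(paste0(path_prefix, ".grm.N.bin"), what = "numeric",
                    n = n_el, size = 4)
  if (length(vals) != n_el) {
    stop(".grm.bin size inconsistent with .grm.id")
  }
  A <- matrix(0, n, n)
  A[upper.tri(A, diag = TRUE)] <- vals
  A <- A + t(A) - diag(diag(A), n)
  Nmat <- matrix(0, n, n)
  Nmat[upper.tri(Nmat, diag = TRUE)] <- counts
  Nmat <- Nmat + t(Nmat) - diag(diag(Nmat), n)
  new_grm(A, Nmat, ids, m_used = max(counts))
}

#' Read a phenotype or covariate table
#'
#' Tab-delimited text with a header line; the first two columns must be the
#' family and individual identifiers (FID, IID).
#'
#' @param path file path.
#' @return A data.frame whose first two columns are `FID` and `IID`.
#' @export
read_pheno_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(x) < 2) stop("phenotype table needs at least FID and IID columns")
  names(x)[1:2] <- c("FID", "IID")
  x$FID <- as.character(x$FID)
  x$IID <- as.character(x$IID)
  x
}

#' Write a phenotype or covariate table
#'
#' @param x data.frame with FID and IID as first two columns.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pheno_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
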