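new_grm <- function(matrix, pair_counts, ids, m_used) {
  obj <- list(matrix = matrix, pair_counts = pair_counts, ids = ids,
              m_used = m_used)
  class(obj) <- "grm"
  obj
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d individuals, %d SNPs used; mean diagonal %.4f\n",
              nrow(x$matrix), x$m_used, mean(diag(x$matrix))))
  invisible(x)
}

#' Compute a genomic relationship matrix
#'
#' Builds the standard allele-sharing GRM from hard-call dosages,
#' \deqn{A_{jk} = \frac{1}{m}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}
#'   {2p_i(1-p_i)},}
#' with allele frequencies \eqn{p_i} computed in-sample from non-missing
#' dosages. SNPs failing the frequency or missingness filters are excluded;
#' missing dosages are mean-imputed at \eqn{2p_i} (contributing zero to the
#' numerator), and each pair is averaged over the SNPs at which both
#' individuals were genotyped.
#'
#' @param geno a [genotype_matrix].
#' @param maf_min minimum minor allele frequency (SNPs below are dropped).
#' @param max_missing maximum per-SNP missing fraction.
#' @return A `grm` object with elements `matrix` (n x n), `pair_counts`
#'   (SNPs used per pair), `ids`, and `m_used`.
#' @export
compute_grm <- function(geno, maf_min = 0.01, max_missing = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"))
  X <- geno$dosages
  p <- geno$allele_freq
  maf <- pmin(p, 1 - p)
  miss <- colMeans(is.na(X))
  keep <- !is.na(maf) & maf >= maf_min & miss <= max_missing
  if (!any(keep)) stop("no SNPs survive the MAF/missingness filters")
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  m <- ncol(X)
  Z <- sweep(X, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  has_missing <- anyNA(Z)
  if (has_missing) {
    miss_mask <- is.na(Z)
    Z[miss_mask] <- 0
    obs <- 1 - miss_mask
    storage.mode(obs) <- "double"
    pair_counts <- tcrossprod(obs)
  } else {
    pair_counts <- matrix(m, nrow(Z), nrow(Z))
  }
  A <- tcrossprod(Z) / pair_counts
  A[pair_counts == 0] <- 0
  new_grm(A, pair_counts, geno$sample_ids, m_used = m)
}
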