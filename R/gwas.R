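#' Per-SNP association scan of a latent factor score
#'
#' Ordinary least squares of the (already residualized) factor score on
#' each SNP's additive dosage, with an intercept and no further covariates
#' (a covariate matrix can be supplied for standalone use). Missing dosages
#' are mean-imputed per SNP by default, or the cases dropped per SNP.
#' Monomorphic SNPs are skipped with a reason code. Output columns mirror
#' the PLINK 2 `--glm` additive table.
#'
#' @param scores a `factor_scores` data.frame (or any data.frame with
#'   `FID`/`IID` and the score column).
#' @param geno a [genotype_matrix].
#' @param latent name of the score column to analyse.
#' @param impute_missing mean-impute missing dosages (default) instead of
#'   dropping those cases per SNP.
#' @param covariates optional numeric covariate matrix (rows aligned with
#'   `geno`'s samples) to include in each per-SNP model.
#' @return A `gwas_result`: data.frame with CHROM, POS, ID, A1, A1_FREQ,
#'   BETA, SE, T_STAT, P, N, SKIP_REASON; attribute `lambda_gc`.
#' @export
run_gwas <- function(scores, geno, latent, impute_missing = TRUE,
                     covariates = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (!latent %in% names(scores)) {
    stop("score column '", latent, "' not found")
  }
  gkey <- paste(geno$sample_ids$family_id, geno$sample_ids$individual_id)
  if (all(c("FID", "IID") %in% names(scores))) {
    skey <- paste(scores$FID, scores$IID)
    idx <- match(gkey, skey)
  } else {
    if (nrow(scores) != length(gkey)) {
      stop("scores lack FID/IID and do not align with the genotypes")
    }
    idx <- seq_along(gkey)
  }
  y <- scores[[latent]][idx]
  keep <- which(!is.na(y))
  if (length(keep) == 0) stop("no overlapping ids between scores and genotypes")
  y <- y[keep]
  X <- geno$dosages[keep, , drop = FALSE]
  n <- length(y)
  m <- ncol(X)
  if (!is.null(covariates)) {
    # residualize the phenotype and dosages on the covariates up front
    C <- cbind(1, as.matrix(covariates)[keep, , drop = FALSE])
    qc <- qr(C)
    y <- qr.resid(qc, y)
  } else {
    qc <- NULL
  }
  has_na <- anyNA(X)
  if (has_na && !impute_missing && !is.null(covariates)) {
    stop("per-SNP case dropping is not supported together with covariates; ",
         "use impute_missing = TRUE")
  }
  if (has_na && impute_missing) {
    mu_snp <- colMeans(X, na.rm = TRUE)
    na_idx <- which(is.na(X))
    X[na_idx] <- mu_snp[((na_idx - 1) %/% n) + 1]
    has_na <- FALSE
  }
  beta <- se <- tstat <- pval <- rep(NA_real_, m)
  n_used <- rep(n, m)
  skip <- rep(NA_character_, m)
  if (!has_na) {
    if (!is.null(qc)) X <- qr.resid(qc, X)
    xm <- colMeans(X)
    sxx <- colSums(X^2) - n * xm^2
    yc <- y - mean(y)
    sxy <- drop(crossprod(X, yc))
    syy <- sum(yc^2)
    ok <- sxx > 1e-12
    dfree <- n - 2 - if (is.null(qc)) 0 else (ncol(qc$qr) - 1)
    beta[ok] <- sxy[ok] / sxx[ok]
    s2 <- pmax(syy - beta[ok] * sxy[ok], 0) / dfree
    se[ok] <- sqrt(s2 / sxx[ok])
    tstat[ok] <- beta[ok] / se[ok]
    pval[ok] <- 2 * stats::pt(abs(tstat[ok]), dfree, lower.tail = FALSE)
    skip[!ok] <- "monomorphic"
  } else {
    for (j in seq_len(m)) {
      xj <- X[, j]
      obs <- !is.na(xj)
      nj <- sum(obs)
      if (nj < 3 || stats::var(xj[obs]) < 1e-12) {
        skip[j] <- if (nj < 3) "too_few_calls" else "monomorphic"
        n_used[j] <- nj
        next
      }
      fit <- stats::lm.fit(cbind(1, xj[obs]), y[obs])
      rdf <- nj - 2
      s2 <- sum(fit$residuals^2) / rdf
      xv <- sum((xj[obs] - mean(xj[obs]))^2)
      beta[j] <- fit$coefficients[2]
      se[j] <- sqrt(s2 / xv)
      tstat[j] <- beta[j] / se[j]
      pval[j] <- 2 * stats::pt(abs(tstat[j]), rdf, lower.tail = FALSE)
      n_used[j] <- nj
    }
  }
  out <- data.frame(
    CHROM = geno$snp_meta$chromosome,
    POS = geno$snp_meta$position,
    ID = geno$snp_meta$id,
    A1 = geno$snp_meta$allele_counted,
    A1_FREQ = geno$allele_freq,
    BETA = beta, SE = se, T_STAT = tstat, P = pval,
    N = n_used, SKIP_REASON = skip,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gwas_result", "data.frame")
  if (sum(!is.na(tstat)) >= 100) {
    attr(out, "lambda_gc") <- genomic_inflation(out)
  }
  out
}

#' Genomic inflation factor
#'
#' Median of the observed 1-df association chi-squares divided by the
#' theoretical null median (0.4549...); values near 1 indicate a calibrated
#' scan.
#'
#' @param result a `gwas_result` (or any data.frame with a `T_STAT`
#'   column).
#' @return lambda_GC as a single number.
#' @export
genomic_inflation <- function(result) {
  t2 <- result$T_STAT[!is.na(result$T_STAT)]^2
  if (length(t2) < 100) {
    stop("need at least 100 tests for a stable inflation estimate")
  }
  stats::median(t2) / stats::qchisq(0.5, df = 1)
}

#' QQ-plot coordinates for a GWAS
#'
#' Expected versus observed -log10 p under the uniform null, ready for
#' plotting.
#'
#' @param result a `gwas_result`.
#' @return data.frame with `expected` and `observed` columns, sorted.
#' @export
qq_data <- function(result) {
  p <- sort(result$P[!is.na(result$P)])
  k <- length(p)
  data.frame(
    expected = -log10((seq_len(k) - 0.5) / k),
    observed = -log10(p)
  )
}
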