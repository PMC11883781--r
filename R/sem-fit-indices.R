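#' Fit indices for a fitted covariance-structure model
#'
#' Computes RMSEA, CFI, TLI and SRMR. The baseline is the independence
#' model (free variances and means, zero covariances) fitted to the same
#' cases; it is computed in closed form from the fit's stored data when not
#' supplied.
#'
#' \deqn{RMSEA = \sqrt{\max(\chi^2 - df, 0) / (df (N - 1))}}
#' with RMSEA defined as 0 (and flagged) when `df = 0`;
#' \deqn{CFI = 1 - \max(\chi^2_m - df_m, 0) /
#'   \max(\chi^2_b - df_b, \chi^2_m - df_m, 0)}
#' TLI from the \eqn{\chi^2/df} ratios; SRMR as the root mean square of the
#' residual correlations (lower triangle plus diagonal) between the
#' saturated and model-implied covariance matrices.
#'
#' @param fit a `sem_fit` from [fit_cfa_fiml].
#' @param baseline optional `sem_fit`-like list with elements `chi2` and
#'   `df` for the independence model on the same cases.
#' @return A list with `rmsea`, `cfi`, `tli`, `srmr`, `chi2`, `df`,
#'   `n_used`, and `rmsea_df_zero` flag.
#' @export
compute_fit_indices <- function(fit, baseline = NULL) {
  stopifnot(inherits(fit, "sem_fit"))
  if (is.null(baseline)) {
    p <- length(fit$spec$indicators)
    ind <- fit_independence_fiml_from_fit(fit)
    chi2_b <- 2 * (fit$loglik_sat - ind$loglik)
    df_b <- as.integer(p * (p + 3) / 2 - ind$n_par)
  } else {
    chi2_b <- baseline$chi2
    df_b <- baseline$df
  }
  chi2_m <- fit$chi2
  df_m <- fit$df
  n <- fit$n_used
  df_zero <- df_m == 0
  rmsea <- if (df_zero) 0 else sqrt(max(chi2_m - df_m, 0) / (df_m * (n - 1)))
  denom <- max(chi2_b - df_b, chi2_m - df_m, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chi2_m - df_m, 0) / denom
  rb <- chi2_b / df_b
  rm_ <- if (df_m > 0) chi2_m / df_m else 1
  tli <- if (rb - 1 == 0) 1 else (rb - rm_) / (rb - 1)
  S <- fit$sat_cov
  Sig <- fit$implied_cov
  Rs <- stats::cov2cor(S)
  Ri <- stats::cov2cor(Sig)
  res <- (Rs - Ri)[lower.tri(Rs, diag = TRUE)]
  srmr <- sqrt(mean(res^2))
  list(rmsea = rmsea, cfi = cfi, tli = tli, srmr = srmr,
       chi2 = chi2_m, df = df_m, n_used = n, rmsea_df_zero = df_zero)
}

# independence baseline recomputed from the fit's pattern data
fit_independence_fiml_from_fit <- function(fit) {
  if (is.null(fit$Y_data)) {
    # reconstruct from saturated moments when raw data were not kept:
    # only exact for complete data; fits store data by default
    stop("fit does not carry its data; refit with keep_data = TRUE")
  }
  fit_independence_fiml(fit$Y_data)
}
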