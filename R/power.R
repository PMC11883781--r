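# Closed-form power for GREML designs on unrelated individuals. The
# sampling variances come from the equivalence between (co)heritability
# REML estimates and Haseman-Elston regression on the off-diagonal GRM
# entries: with var_offdiag the variance of those entries (about 1/m for m
# independent SNPs; 2e-5 is the conventional value for unrelateds on
# genome-wide data),
#   var(h2_hat)  = 2 / (N^2 var_offdiag)
#   var(rG_hat)  = [(1 - rG rP)^2 + (rG - rP)^2] /
#                  (h2_1 h2_2 N^2 var_offdiag)        (full sample overlap)
# and the test of rG = 0 is a 1-df chi-square with noncentrality
# rG^2 / var(rG_hat).

#' Sampling variance of a univariate GREML SNP-heritability estimate
#'
#' @param n sample size.
#' @param var_offdiag variance of the off-diagonal GRM entries (default
#'   2e-5, the conventional value for unrelated samples).
#' @return The approximate sampling variance of the h2 estimate.
#' @export
var_h2_greml <- function(n, var_offdiag = 2e-5) {
  2 / (n^2 * var_offdiag)
}

#' Sampling variance of a bivariate GREML genetic-correlation estimate
#'
#' Full-sample-overlap, quantitative-trait case.
#'
#' @param n sample size (both traits measured on the same individuals).
#' @param h2_1,h2_2 SNP heritabilities of the two traits.
#' @param rG true genetic correlation.
#' @param rP phenotypic correlation between the traits.
#' @param var_offdiag variance of the off-diagonal GRM entries.
#' @return The approximate sampling variance of the rG estimate.
#' @export
var_rg_greml <- function(n, h2_1, h2_2, rG, rP, var_offdiag = 2e-5) {
  ((1 - rG * rP)^2 + (rG - rP)^2) / (h2_1 * h2_2 * n^2 * var_offdiag)
}

#' Power to detect a genetic correlation by bivariate GREML
#'
#' Closed-form power of the 1-df likelihood-ratio/Wald test of `rG = 0` in
#' a bivariate GREML analysis of two quantitative traits measured on the
#' same `n` unrelated individuals: the noncentrality parameter is
#' `rG^2 / var(rG_hat)` with the sampling variance from [var_rg_greml],
#' and power is the upper tail of the noncentral chi-square beyond the
#' central critical value at `alpha`.
#'
#' @param n sample size (full overlap).
#' @param h2_1,h2_2 SNP heritabilities of the two traits (each in (0, 1]).
#' @param rG genetic correlation to detect.
#' @param rP phenotypic correlation between the traits.
#' @param var_offdiag variance of the off-diagonal GRM entries (default
#'   2e-5 for unrelateds).
#' @param alpha type-I error rate.
#' @return A list with `power`, `ncp`, `se_rg` (the implied standard error
#'   of the rG estimate), and `degenerate` (TRUE when a zero heritability
#'   makes the variance infinite, in which case power equals `alpha`).
#' @export
compute_power_bivariate <- function(n, h2_1, h2_2, rG, rP,
                                    var_offdiag = 2e-5, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (var_offdiag <= 0) stop("var_offdiag must be positive")
  if (h2_1 <= 0 || h2_2 <= 0) {
    return(list(power = alpha, ncp = 0, se_rg = Inf, degenerate = TRUE))
  }
  v <- var_rg_greml(n, h2_1, h2_2, rG, rP, var_offdiag)
  ncp <- rG^2 / v
  crit <- stats::qchisq(alpha, df = 1, lower.tail = FALSE)
  pow <- stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
  list(power = pow, ncp = ncp, se_rg = sqrt(v), degenerate = FALSE)
}
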