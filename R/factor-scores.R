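#' Extract per-individual factor scores from a fitted model
#'
#' Regression (Thomson) scores
#' \deqn{\hat F = \Phi \Lambda' \Sigma^{-1} (y - \mu)}
#' computed per missing-data pattern on each case's observed indicator
#' subset; Bartlett scores
#' \deqn{\hat F = (\Lambda'\Theta^{-1}\Lambda)^{-1}\Lambda'\Theta^{-1}(y-\mu)}
#' as the documented alternative. The per-latent determinacy (the model-
#' implied correlation between the score and the latent variable, for
#' complete data) is reported alongside.
#'
#' @param fit a converged `sem_fit`.
#' @param table the table to score; must contain the fit's indicator
#'   columns. Cases with all indicators missing get missing scores.
#' @param method `"regression"` or `"Bartlett"`.
#' @return An object of class `factor_scores`: a data.frame of ids (when
#'   present in `table`) and one column per latent, with attributes
#'   `method` and `determinacy`.
#' @export
extract_factor_scores <- function(fit, table,
                                  method = c("regression", "Bartlett")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged) {
    warning("scoring a non-converged fit; interpret with caution")
  }
  m <- fit$matrices
  L <- m$Lambda
  Phi <- m$Phi
  Th <- m$Theta
  mu <- m$mu
  Sigma <- fit$implied_cov
  p <- nrow(L)
  k <- ncol(L)
  Y <- as.matrix(as.data.frame(table)[, fit$spec$indicators, drop = FALSE])
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  scores <- matrix(NA_real_, n, k,
                   dimnames = list(NULL, fit$spec$latents))
  miss <- is.na(Y)
  key <- apply(miss, 1, function(r) paste(as.integer(r), collapse = ""))
  for (pat in unique(key)) {
    rows <- which(key == pat)
    obs <- which(!miss[rows[1], ])
    if (length(obs) == 0) next
    D <- sweep(Y[rows, obs, drop = FALSE], 2, mu[obs], "-")
    if (method == "regression") {
      W <- Phi %*% t(L[obs, , drop = FALSE]) %*%
        solve(Sigma[obs, obs, drop = FALSE])
    } else {
      Th_o <- Th[obs, obs, drop = FALSE]
      diag(Th_o) <- pmax(diag(Th_o), 1e-8)   # guard zero residuals
      iTh <- solve(Th_o)
      Lo <- L[obs, , drop = FALSE]
      W <- solve(crossprod(Lo, iTh %*% Lo) + diag(1e-10, k),
                 crossprod(Lo, iTh))
    }
    scores[rows, ] <- D %*% t(W)
  }
  determinacy <- sqrt(pmax(
    diag(Phi %*% crossprod(L, solve(Sigma, L)) %*% Phi) / diag(Phi), 0
  ))
  names(determinacy) <- fit$spec$latents
  id_cols <- intersect(c("FID", "IID"), names(table))
  out <- data.frame(as.data.frame(table)[, id_cols, drop = FALSE],
                    scores, check.names = FALSE)
  attr(out, "method") <- method
  attr(out, "determinacy") <- determinacy
  class(out) <- c("factor_scores", "data.frame")
  out
}
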