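# Exploratory factor analysis: maximum-likelihood extraction via
# stats::factanal on the correlation matrix, followed by an oblique
# quartimin (oblimin with gamma = 0) rotation implemented with the
# gradient-projection algorithm.

#' Exploratory factor analysis with oblique rotation
#'
#' Maximum-likelihood factor extraction on the correlation matrix of the
#' requested variables, followed by an oblimin (quartimin) rotation.
#' Complete cases are used for the correlation matrix. Factors are returned
#' in decreasing order of explained variance, with each factor's sign fixed
#' so its largest-magnitude loading is positive, making the output
#' deterministic.
#'
#' @param table data.frame or `phenotype_table` holding the variables.
#' @param n_factors number of factors to extract (must be admissible for
#'   the number of variables).
#' @param rotation `"oblimin"` (oblique quartimin) or `"none"`.
#' @param variables which columns to analyse; defaults to the table's item
#'   roles.
#' @param seed integer seed (rotation starts are deterministic; the seed
#'   only matters for `factanal`'s optional multiple starts).
#' @return A list with `loadings` (rotated pattern), `factor_correlation`,
#'   `proportions` (variance explained per factor), `uniquenesses`, and a
#'   `heywood` flag (communality within numerical reach of 1).
#' @export
fit_efa <- function(table, n_factors, rotation = c("oblimin", "none"),
                    variables = NULL, seed = 1L) {
  rotation <- match.arg(rotation)
  if (is.null(variables)) {
    variables <- attr(table, "items")
    if (is.null(variables)) {
      variables <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                           c("FID", "IID"))
    }
  }
  Y <- as.matrix(as.data.frame(table)[, variables, drop = FALSE])
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  p <- ncol(Y)
  dof <- 0.5 * ((p - n_factors)^2 - p - n_factors)
  if (n_factors >= p || dof < 0) {
    stop("n_factors = ", n_factors, " leaves no degrees of freedom for p = ",
         p, " variables")
  }
  R <- stats::cor(Y)
  set.seed(seed)
  fa <- stats::factanal(covmat = R, factors = n_factors, n.obs = nrow(Y),
                        rotation = "none")
  A <- matrix(fa$loadings, p, n_factors,
              dimnames = list(variables, NULL))
  heywood <- any(fa$uniquenesses <= 0.005 + 1e-12)
  if (rotation == "oblimin" && n_factors > 1) {
    rot <- rotate_oblimin(A)
    L <- rot$loadings
    Phi <- rot$Phi
  } else {
    L <- A
    Phi <- diag(n_factors)
  }
  # order by explained variance, fix signs
  ssq <- colSums(L^2)
  ord <- order(ssq, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  Phi <- Phi[ord, ord, drop = FALSE]
  sgn <- vapply(seq_len(ncol(L)), function(j) {
    sign(L[which.max(abs(L[, j])), j])
  }, numeric(1))
  sgn[sgn == 0] <- 1
  L <- sweep(L, 2, sgn, "*")
  Phi <- diag(sgn) %*% Phi %*% diag(sgn)
  colnames(L) <- paste0("F", seq_len(ncol(L)))
  dimnames(Phi) <- list(colnames(L), colnames(L))
  list(
    loadings = L,
    factor_correlation = Phi,
    proportions = colSums(L^2) / p,
    uniquenesses = fa$uniquenesses,
    heywood = heywood,
    n_used = nrow(Y)
  )
}

# quartimin criterion and gradient for the gradient-projection rotation
vgQ_quartimin <- function(L) {
  k <- ncol(L)
  L2 <- L^2
  N <- matrix(1, k, k) - diag(k)
  X <- L2 %*% N
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

#' Oblique quartimin rotation by gradient projection
#'
#' Rotates an unrotated loading matrix to the quartimin criterion over
#' oblique rotation matrices with unit-length columns, returning the rotated
#' pattern and the implied factor correlation matrix.
#'
#' @param A unrotated p x k loading matrix.
#' @param max_iter iteration cap.
#' @param eps gradient-norm convergence tolerance.
#' @return list with `loadings`, `Phi`, `converged`.
#' @export
rotate_oblimin <- function(A, max_iter = 1000, eps = 1e-6) {
  k <- ncol(A)
  Tmat <- diag(k)
  L <- A %*% t(solve(Tmat))
  vg <- vgQ_quartimin(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% solve(Tmat))
  al <- 1
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < eps) {
      converged <- TRUE
      break
    }
    al <- 2 * al
    for (half in 1:20) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Lt <- A %*% t(solve(Tt))
      vgt <- vgQ_quartimin(Lt)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    L <- Lt
    f <- vgt$f
    G <- -t(t(L) %*% vgt$Gq %*% solve(Tmat))
  }
  list(loadings = L, Phi = crossprod(Tmat), converged = converged)
}

#' Parallel analysis for the number of factors
#'
#' Compares the eigenvalues of the observed correlation matrix with the
#' mean eigenvalues of correlation matrices of random normal data of the
#' same dimensions (seeded resampling). Provided as a helper; the pipeline
#' never auto-selects the factor count.
#'
#' @param table data.frame holding the variables.
#' @param variables columns to analyse; defaults to the item roles.
#' @param n_iter number of random datasets.
#' @param seed integer RNG seed.
#' @return list with `observed_eigenvalues`, `random_means`,
#'   `suggested_factors`.
#' @export
parallel_analysis <- function(table, variables = NULL, n_iter = 50,
                              seed = 1L) {
  if (is.null(variables)) {
    variables <- attr(table, "items")
  }
  Y <- as.matrix(as.data.frame(table)[, variables, drop = FALSE])
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  n <- nrow(Y)
  p <- ncol(Y)
  obs <- eigen(stats::cor(Y), symmetric = TRUE, only.values = TRUE)$values
  set.seed(seed)
  rnd <- matrix(0, n_iter, p)
  for (i in seq_len(n_iter)) {
    Z <- matrix(stats::rnorm(n * p), n, p)
    rnd[i, ] <- eigen(stats::cor(Z), symmetric = TRUE,
                      only.values = TRUE)$values
  }
  rm_ <- colMeans(rnd)
  list(
    observed_eigenvalues = obs,
    random_means = rm_,
    suggested_factors = sum(obs > rm_)
  )
}

#' Tucker congruence coefficients between two loading matrices
#'
#' Column-wise congruence after greedy matching, a standard measure of
#' factor-pattern recovery.
#'
#' @param L estimated p x k loadings.
#' @param L_true reference p x k loadings.
#' @return numeric vector of best-match absolute congruences, one per
#'   reference factor.
#' @export
tucker_congruence <- function(L, L_true) {
  k <- ncol(L_true)
  cong <- abs(crossprod(L, L_true) /
                sqrt(tcrossprod(colSums(L^2), colSums(L_true^2))))
  out <- numeric(k)
  used <- integer(0)
  for (j in seq_len(k)) {
    cand <- setdiff(order(cong[, j], decreasing = TRUE), used)
    out[j] <- cong[cand[1], j]
    used <- c(used, cand[1])
  }
  out
}
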