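# Full-information maximum likelihood engine for covariance-structure
# models with saturated means. Cases are grouped by missing-data pattern;
# each pattern contributes through its sufficient statistics
# (n_p, pattern mean, pattern ML scatter), which makes the casewise
# likelihood and its analytic gradient cheap:
#   l = sum_p -n_p/2 [ k_p log 2pi + log|Sigma_p| + tr(Sigma_p^-1 S_p)
#                      + (ybar_p - mu_p)' Sigma_p^-1 (ybar_p - mu_p) ].

prepare_patterns <- function(Y) {
  miss <- is.na(Y)
  keep <- rowSums(!miss) > 0
  Y <- Y[keep, , drop = FALSE]
  miss <- miss[keep, , drop = FALSE]
  key <- apply(miss, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(nrow(Y)), key)
  pats <- lapply(groups, function(rows) {
    obs <- which(!miss[rows[1], ])
    Yp <- Y[rows, obs, drop = FALSE]
    n_p <- length(rows)
    ybar <- colMeans(Yp)
    S <- if (n_p > 1) {
      crossprod(sweep(Yp, 2, ybar, "-")) / n_p
    } else {
      matrix(0, length(obs), length(obs))
    }
    list(obs = obs, n = n_p, ybar = ybar, S = S, rows = rows)
  })
  list(patterns = pats, n_used = nrow(Y), Y = Y)
}

# -loglik; returns a large finite value on non-PD Sigma so optimizers can
# back off (counted as the "ridge-and-retry" path).
fiml_negloglik <- function(theta, spec, pats) {
  m <- build_model_matrices(spec, theta)
  Sigma <- m$Lambda %*% m$Phi %*% t(m$Lambda) + m$Theta
  total <- 0
  for (pt in pats) {
    So <- Sigma[pt$obs, pt$obs, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(1e12)
    iS <- chol2inv(ch)
    d <- pt$ybar - m$mu[pt$obs]
    k_o <- length(pt$obs)
    total <- total + pt$n / 2 * (
      k_o * log(2 * pi) + 2 * sum(log(diag(ch))) +
        sum(iS * pt$S) + drop(crossprod(d, iS %*% d))
    )
  }
  total
}

fiml_gradient <- function(theta, spec, pats) {
  m <- build_model_matrices(spec, theta)
  p <- length(spec$indicators)
  Sigma <- m$Lambda %*% m$Phi %*% t(m$Lambda) + m$Theta
  G <- matrix(0, p, p)
  gmu <- numeric(p)
  for (pt in pats) {
    So <- Sigma[pt$obs, pt$obs, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, spec$n_par))
    iS <- chol2inv(ch)
    d <- pt$ybar - m$mu[pt$obs]
    iSd <- iS %*% d
    T1 <- iS - iS %*% (pt$S + tcrossprod(d)) %*% iS
    G[pt$obs, pt$obs] <- G[pt$obs, pt$obs] + pt$n / 2 * T1
    gmu[pt$obs] <- gmu[pt$obs] - pt$n * iSd
  }
  g <- numeric(spec$n_par)
  # loadings: dF = 2 (G Lambda Phi)_ij
  GLP <- 2 * G %*% m$Lambda %*% m$Phi
  sel <- which(spec$lambda_id > 0)
  for (s in sel) {
    id <- spec$lambda_id[s]
    g[id] <- g[id] + GLP[s]
  }
  M <- crossprod(m$Lambda, G %*% m$Lambda)
  if (!is.null(spec$second_order)) {
    gam <- m$gamma
    k <- length(gam)
    gid <- spec$second_order$gamma_id
    for (a in seq_len(k)) {
      if (gid[a] > 0) {
        val <- 2 * sum(M[a, -a] * gam[-a])
        g[gid[a]] <- g[gid[a]] + val
      }
    }
  } else {
    psel <- which(spec$phi_id > 0 & upper.tri(spec$phi_id), arr.ind = TRUE)
    if (nrow(psel) > 0) {
      for (r in seq_len(nrow(psel))) {
        id <- spec$phi_id[psel[r, 1], psel[r, 2]]
        g[id] <- g[id] + 2 * M[psel[r, 1], psel[r, 2]]
      }
    }
  }
  tsel <- which(spec$theta_id > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(tsel))) {
    i <- tsel[r, 1]
    j <- tsel[r, 2]
    if (i > j) next
    id <- spec$theta_id[i, j]
    g[id] <- g[id] + if (i == j) G[i, i] else 2 * G[i, j]
  }
  for (i in seq_along(spec$mu_id)) {
    id <- spec$mu_id[i]
    if (id > 0) g[id] <- g[id] + gmu[i]
  }
  g
}

# Starting values: principal-axis-flavored. Loadings scaled by indicator SD,
# staggered across the latents an indicator loads on so symmetric structures
# (general + specific) start asymmetric.
fiml_start_values <- function(spec, Y) {
  p <- length(spec$indicators)
  sds <- apply(Y, 2, stats::sd, na.rm = TRUE)
  sds[!is.finite(sds) | sds == 0] <- 1
  mus <- colMeans(Y, na.rm = TRUE)
  theta <- numeric(spec$n_par)
  lscale <- c(0.6, 0.35, 0.25, 0.2)
  for (i in seq_len(p)) {
    free_j <- which(spec$lambda_id[i, ] > 0)
    for (a in seq_along(free_j)) {
      id <- spec$lambda_id[i, free_j[a]]
      theta[id] <- lscale[min(a, length(lscale))] * sds[i]
    }
  }
  if (!is.null(spec$second_order)) {
    for (id in unique(spec$second_order$gamma_id)) {
      if (id > 0) theta[id] <- 0.6
    }
  } else {
    theta[unique(spec$phi_id[spec$phi_id > 0])] <- 0.3
  }
  dsel <- which(diag(spec$theta_id) > 0)
  for (i in dsel) theta[diag(spec$theta_id)[i]] <- 0.5 * sds[i]^2
  for (i in seq_len(p)) {
    if (spec$mu_id[i] > 0) theta[spec$mu_id[i]] <- mus[i]
  }
  theta
}

#' Fit a confirmatory model by full-information maximum likelihood
#'
#' Maximizes the casewise (missing-data) Gaussian log-likelihood of a
#' covariance-structure model with saturated means, using a quasi-Newton
#' optimizer with analytic gradients on the free parameters. The
#' likelihood-ratio statistic is computed against the saturated
#' mean/covariance model (estimated in closed form for complete data, by EM
#' otherwise), and standard errors come from the inverse observed
#' information.
#'
#' @param table a `phenotype_table` or data.frame holding the model's
#'   indicator columns (binary items are treated as continuous, a documented
#'   modeling approximation).
#' @param spec a `model_spec` from [make_model_spec] (or hand-built).
#' @param se compute standard errors (numerical Jacobian of the analytic
#'   gradient); disable for speed in simulations.
#' @param max_iter optimizer iteration cap.
#' @return An object of class `sem_fit`: parameter `estimates` (+`se`),
#'   `loglik`, `loglik_sat`, `chi2`, `df`, `n_used`, `converged`,
#'   `implied_cov`, `implied_means`, `matrices` (Lambda, Phi, Theta, mu),
#'   and a `heywood` flag (negative residual variance or non-PSD latent
#'   covariance; reported, never silently repaired).
#' @export
fit_cfa_fiml <- function(table, spec, se = TRUE, max_iter = 500) {
  stopifnot(inherits(spec, "model_spec"))
  miss_ind <- setdiff(spec$indicators, names(table))
  if (length(miss_ind) > 0) {
    stop("indicator column(s) not in table: ",
         paste(miss_ind, collapse = ", "))
  }
  Y <- as.matrix(as.data.frame(table)[, spec$indicators, drop = FALSE])
  storage.mode(Y) <- "double"
  pp <- prepare_patterns(Y)
  pats <- pp$patterns
  start <- fiml_start_values(spec, pp$Y)
  obj <- function(th) fiml_negloglik(th, spec, pats)
  gr <- function(th) fiml_gradient(th, spec, pats)
  opt <- stats::nlminb(start, obj, gr,
                       control = list(iter.max = max_iter,
                                      eval.max = 4 * max_iter,
                                      rel.tol = 1e-12))
  par <- opt$par
  val <- opt$objective
  # alternate BFGS / nlminb polish cycles: the bifactor structures have
  # nearly flat directions and a single optimizer pass can stop early
  for (cycle in 1:4) {
    pol <- stats::optim(par, obj, gr, method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-15))
    if (pol$value < val) {
      par <- pol$par
      val <- pol$value
    }
    pol2 <- stats::nlminb(par, obj, gr,
                          control = list(iter.max = max_iter,
                                         rel.tol = 1e-14))
    improved <- val - pol2$objective
    if (pol2$objective < val) {
      par <- pol2$par
      val <- pol2$objective
    }
    if (improved < 1e-9 * max(1, abs(val))) break
  }
  gnorm <- sqrt(sum(gr(par)^2))
  converged <- is.finite(val) && val < 1e11 && gnorm < 1e-5 * max(1, abs(val))
  m <- build_model_matrices(spec, par)
  Sigma <- m$Lambda %*% m$Phi %*% t(m$Lambda) + m$Theta
  sat <- fit_saturated_mvn(pp$Y)
  loglik <- -val
  chi2 <- 2 * (sat$loglik - loglik)
  if (chi2 < 0 && chi2 > -1e-4) chi2 <- 0
  chi2 <- max(chi2, 0)
  se_vec <- rep(NA_real_, spec$n_par)
  vcov <- NULL
  if (se) {
    H <- tryCatch(stats::optimHess(par, obj, gr), error = function(e) NULL)
    if (!is.null(H)) {
      vcov <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vcov) && any(!is.finite(diag(vcov)) | diag(vcov) <= 0)) {
        vcov <- NULL
      }
      if (is.null(vcov)) {
        # flat directions: invert on the numerically informative subspace
        eh <- eigen((H + t(H)) / 2, symmetric = TRUE)
        pos <- eh$values > max(eh$values) * 1e-10
        vcov <- eh$vectors[, pos, drop = FALSE] %*%
          diag(1 / eh$values[pos], sum(pos)) %*%
          t(eh$vectors[, pos, drop = FALSE])
      }
      dv <- diag(vcov)
      ok <- is.finite(dv) & dv > 0
      se_vec[ok] <- sqrt(dv[ok])
    }
  }
  nm <- model_par_names(spec)
  est <- stats::setNames(par, nm)
  names(se_vec) <- nm
  phi_eigen <- eigen(m$Phi, symmetric = TRUE, only.values = TRUE)$values
  heywood <- any(diag(m$Theta) < -1e-8) || min(phi_eigen) < -1e-8 ||
    any(abs(m$Phi[upper.tri(m$Phi)]) > 1 + 1e-8)
  out <- list(
    estimates = est, se = se_vec, vcov = vcov,
    loglik = loglik, loglik_sat = sat$loglik,
    chi2 = chi2, df = model_df(spec), n_used = pp$n_used,
    converged = converged, gradient_norm = gnorm,
    implied_cov = Sigma, implied_means = m$mu,
    sat_cov = sat$Sigma, sat_means = sat$mu,
    matrices = m, spec = spec, heywood = heywood,
    Y_data = pp$Y
  )
  class(out) <- "sem_fit"
  out
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf(
    "sem_fit '%s': logLik = %.3f, chi2 = %.3f on df = %d, n = %d%s%s\n",
    x$spec$structure, x$loglik, x$chi2, x$df, x$n_used,
    if (x$converged) "" else " [NOT CONVERGED]",
    if (x$heywood) " [Heywood]" else ""
  ))
  invisible(x)
}

# Saturated multivariate-normal fit under arbitrary missingness.
# Complete data: closed form. Otherwise EM on (mu, Sigma).
fit_saturated_mvn <- function(Y, tol = 1e-8, max_iter = 1000) {
  n <- nrow(Y)
  p <- ncol(Y)
  if (!anyNA(Y)) {
    mu <- colMeans(Y)
    S <- crossprod(sweep(Y, 2, mu, "-")) / n
    ll <- -n / 2 * (p * log(2 * pi) + determinant(S)$modulus[1] + p)
    return(list(mu = mu, Sigma = S, loglik = as.numeric(ll), n = n))
  }
  pp <- prepare_patterns(Y)
  pats <- pp$patterns
  mu <- colMeans(Y, na.rm = TRUE)
  # pairwise-complete start, ridged to PD
  S <- stats::cov(Y, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-6) S <- S + diag(1e-6 - ev_min, p)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    ll <- 0
    for (pt in pats) {
      o <- pt$obs
      q <- setdiff(seq_len(p), o)
      Yp <- pp$Y[pt$rows, o, drop = FALSE]
      So <- S[o, o, drop = FALSE]
      ch <- chol(So)
      iS <- chol2inv(ch)
      d <- pt$ybar - mu[o]
      ll <- ll - pt$n / 2 * (length(o) * log(2 * pi) +
                               2 * sum(log(diag(ch))) +
                               sum(iS * pt$S) +
                               drop(crossprod(d, iS %*% d)))
      Yc <- matrix(0, pt$n, p)
      Yc[, o] <- Yp
      Cq <- matrix(0, p, p)
      if (length(q) > 0) {
        B <- S[q, o, drop = FALSE] %*% iS
        Yc[, q] <- matrix(mu[q], pt$n, length(q), byrow = TRUE) +
          sweep(Yp, 2, mu[o], "-") %*% t(B)
        Cq[q, q] <- S[q, q, drop = FALSE] -
          B %*% S[o, q, drop = FALSE]
      }
      T1 <- T1 + colSums(Yc)
      T2 <- T2 + crossprod(Yc) + pt$n * Cq
    }
    mu <- T1 / pp$n_used
    S <- T2 / pp$n_used - tcrossprod(mu)
    S <- (S + t(S)) / 2
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  # one final likelihood evaluation at the last update
  ll <- 0
  for (pt in pats) {
    So <- S[pt$obs, pt$obs, drop = FALSE]
    ch <- chol(So)
    iS <- chol2inv(ch)
    d <- pt$ybar - mu[pt$obs]
    ll <- ll - pt$n / 2 * (length(pt$obs) * log(2 * pi) +
                             2 * sum(log(diag(ch))) +
                             sum(iS * pt$S) +
                             drop(crossprod(d, iS %*% d)))
  }
  list(mu = mu, Sigma = S, loglik = ll, n = pp$n_used)
}

# Independence (baseline) model under FIML: Sigma diagonal, free means.
# The casewise likelihood factorizes over variables, so the ML solution is
# each variable's observed-case mean and ML variance.
fit_independence_fiml <- function(Y) {
  p <- ncol(Y)
  ll <- 0
  mu <- numeric(p)
  v <- numeric(p)
  for (j in seq_len(p)) {
    yj <- Y[, j]
    yj <- yj[!is.na(yj)]
    nj <- length(yj)
    mu[j] <- mean(yj)
    v[j] <- mean((yj - mu[j])^2)
    ll <- ll - nj / 2 * (log(2 * pi) + log(v[j]) + 1)
  }
  n_par <- 2L * p
  list(mu = mu, var = v, loglik = ll, n_par = n_par)
}
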