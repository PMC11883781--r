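# Average-information REML for the model y = g + e, V = A sigma2_g +
# I sigma2_e (and its two-trait extension with 2x2 genetic and residual
# (co)variance blocks). All computations run in the eigenbasis of the GRM:
# after one symmetric eigendecomposition A = U D U', V is diagonal
# (univariate) or block-diagonal in 2x2 site matrices (bivariate), so REML
# likelihoods, exact score vectors and average-information matrices cost
# O(n) per iteration. Fixed effects are an intercept per trait (phenotypes
# are expected to arrive residualized); a covariate matrix can be supplied
# for standalone use.

grm_eigen <- function(grm, keep = NULL) {
  A <- grm$matrix
  if (!is.null(keep)) A <- A[keep, keep, drop = FALSE]
  eigen(A, symmetric = TRUE)
}

#' Univariate average-information REML
#'
#' Estimates (sigma2_g, sigma2_e) for `y = g + e`, `V = A sigma2_g +
#' I sigma2_e`, by restricted maximum likelihood: starting values
#' `var(y)/2` for both components, one EM step, then average-information
#' updates `theta <- theta + AI^{-1} score` with step-halving whenever a
#' step would decrease the restricted log-likelihood or leave the parameter
#' space. Variance components are floored at `1e-6 * var(y)` with
#' active-constraint handling; convergence when the log-likelihood change
#' drops below `tol`.
#'
#' @param grm a `grm` object.
#' @param y numeric phenotype vector aligned with `grm$ids` (missing values
#'   drop the individual from the analysis).
#' @param covariates optional numeric matrix of fixed-effect covariates
#'   (an intercept is always included).
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the restricted log-likelihood.
#' @param eig optional precomputed `eigen()` of the (complete-case) GRM,
#'   for repeated fits against the same relatedness structure.
#' @return A `varcomp_result` with `components` (sigma2_g, sigma2_e),
#'   `se_components` (from the inverse average-information matrix), `h2`
#'   and its delta-method `h2_se`, the accepted log-likelihood trace,
#'   `converged`, `n_used`, and constraint flags.
#' @export
fit_aireml_univariate <- function(grm, y, covariates = NULL,
                                  max_iter = 100, tol = 1e-4, eig = NULL) {
  stopifnot(inherits(grm, "grm"))
  keep <- which(!is.na(y))
  if (length(keep) < 3) stop("need at least 3 non-missing phenotypes")
  subsetted <- length(keep) < length(y)
  y <- y[keep]
  if (stats::var(y) <= 0) stop("phenotype has zero variance")
  if (is.null(eig) || subsetted) {
    eig <- grm_eigen(grm, keep = if (subsetted) keep else NULL)
  }
  n <- length(y)
  d <- eig$values
  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    X <- cbind(X, as.matrix(covariates)[keep, , drop = FALSE])
  }
  yt <- crossprod(eig$vectors, y)[, 1]
  Xt <- crossprod(eig$vectors, X)
  vary <- stats::var(y)
  floor_v <- 1e-6 * vary
  th <- c(sigma2_g = vary / 2, sigma2_e = vary / 2)

  core <- function(th) {
    w <- th[1] * d + th[2]
    if (any(w <= 0)) return(NULL)
    iw <- 1 / w
    Xw <- Xt * iw
    C <- crossprod(Xt, Xw)
    cC <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(cC)) return(NULL)
    iC <- chol2inv(cC)
    b <- crossprod(Xw, yt)
    beta <- iC %*% b
    u <- yt * iw - Xw %*% beta
    ypy <- sum(yt^2 * iw) - drop(crossprod(b, beta))
    ll <- -0.5 * (sum(log(w)) + 2 * sum(log(diag(cC))) + ypy)
    list(ll = ll, iw = iw, u = drop(u), iC = iC, Xw = Xw, Xt = Xt)
  }
  score_ai <- function(st) {
    vi <- list(d, rep(1, n))
    tr_pv <- numeric(2)
    upu <- numeric(2)
    tvec <- vector("list", 2)
    for (c_ in 1:2) {
      v <- vi[[c_]]
      Mc <- crossprod(st$Xt, st$Xt * (v * st$iw^2))
      tr_pv[c_] <- sum(v * st$iw) - sum(st$iC * Mc)
      upu[c_] <- sum(v * st$u^2)
      tvec[[c_]] <- v * st$u
    }
    score <- -0.5 * (tr_pv - upu)
    AI <- matrix(0, 2, 2)
    svec <- lapply(tvec, function(t_) t_ * st$iw)
    hvec <- lapply(svec, function(s_) crossprod(st$Xt, s_))
    for (a in 1:2) {
      for (b_ in a:2) {
        AI[a, b_] <- AI[b_, a] <- 0.5 *
          (sum(tvec[[a]] * svec[[b_]]) -
             drop(crossprod(hvec[[a]], st$iC %*% hvec[[b_]])))
      }
    }
    list(score = score, AI = AI, upu = upu, tr_pv = tr_pv)
  }

  st <- core(th)
  if (is.null(st)) stop("invalid starting values (non-PD V)")
  ll_trace <- st$ll
  sa <- score_ai(st)
  # one EM step
  th_new <- th + th^2 * (sa$upu - sa$tr_pv) / n
  th_new <- pmax(th_new, floor_v)
  st_new <- core(th_new)
  if (!is.null(st_new) && st_new$ll >= st$ll - 1e-8) {
    th <- th_new
    st <- st_new
  }
  ll_trace <- c(ll_trace, st$ll)
  converged <- FALSE
  clamped <- c(FALSE, FALSE)
  for (it in seq_len(max_iter)) {
    sa <- score_ai(st)
    at_floor <- th <= floor_v * (1 + 1e-12)
    free <- !(at_floor & sa$score < 0)
    if (!any(free)) break
    delta <- numeric(2)
    AIf <- sa$AI[free, free, drop = FALSE]
    sol <- tryCatch(solve(AIf, sa$score[free]), error = function(e) NULL)
    if (is.null(sol)) {
      sol <- sa$score[free] / (diag(AIf) + 1e-8)
    }
    delta[free] <- sol
    step <- 1
    accepted <- FALSE
    for (half in 1:30) {
      th_try <- pmax(th + step * delta, floor_v)
      st_try <- core(th_try)
      if (!is.null(st_try) && st_try$ll >= st$ll - 1e-10) {
        th <- th_try
        ll_change <- st_try$ll - st$ll
        st <- st_try
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    ll_trace <- c(ll_trace, st$ll)
    clamped <- clamped | (th <= floor_v * (1 + 1e-12))
    if (abs(ll_change) < tol) {
      converged <- TRUE
      break
    }
  }
  sa <- score_ai(st)
  iAI <- tryCatch(solve(sa$AI), error = function(e) NULL)
  identifiable <- TRUE
  if (is.null(iAI) || !all(is.finite(iAI)) || rcond(sa$AI) < 1e-12) {
    identifiable <- FALSE
    iAI <- matrix(NA_real_, 2, 2)
  }
  se_comp <- sqrt(pmax(diag(iAI), 0))
  s <- sum(th)
  h2 <- th[1] / s
  g_h2 <- c(th[2], -th[1]) / s^2
  h2_se <- if (identifiable) {
    sqrt(max(drop(crossprod(g_h2, iAI %*% g_h2)), 0))
  } else {
    NA_real_
  }
  out <- list(
    components = stats::setNames(th, c("sigma2_g", "sigma2_e")),
    se_components = stats::setNames(se_comp, c("sigma2_g", "sigma2_e")),
    h2 = unname(h2), h2_se = unname(h2_se),
    loglik_trace = ll_trace, loglik = st$ll,
    converged = converged, n_used = n,
    clamped = clamped, identifiable = identifiable,
    type = "univariate"
  )
  class(out) <- "varcomp_result"
  out
}

#' Bivariate average-information REML
#'
#' Six-component REML for two traits measured on the same individuals
#' (complete overlap required): `V` is built from 2x2 genetic and residual
#' (co)variance blocks, `Sigma_g (x) A + Sigma_e (x) I`. Uses damped
#' average-information updates with step-halving, variance floors with
#' active-constraint handling, and covariance clamping that keeps both the
#' genetic and residual correlations inside (-1, 1); clamping is flagged.
#' The genetic correlation `rG = sigma_g12 / sqrt(sigma2_g1 sigma2_g2)` and
#' its delta-method standard error come from the inverse
#' average-information matrix.
#'
#' @param grm a `grm` object.
#' @param y1,y2 numeric phenotype vectors aligned with `grm$ids`;
#'   individuals missing either trait are dropped.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the restricted log-likelihood.
#' @param eig optional precomputed `eigen()` of the complete-case GRM.
#' @return A `varcomp_result` with the six `components`
#'   (sigma2_g1, sigma2_g2, sigma_g12, sigma2_e1, sigma2_e2, sigma_e12),
#'   their SEs, per-trait `h2` (+SEs), `rG` (+SE, clamping flagged),
#'   the log-likelihood trace, `converged` and `n_used`.
#' @export
fit_aireml_bivariate <- function(grm, y1, y2, max_iter = 100, tol = 1e-4,
                                 eig = NULL) {
  stopifnot(inherits(grm, "grm"))
  keep <- which(!is.na(y1) & !is.na(y2))
  if (length(keep) < 4) stop("need at least 4 complete pairs")
  subsetted <- length(keep) < length(y1)
  y1 <- y1[keep]
  y2 <- y2[keep]
  if (stats::var(y1) <= 0 || stats::var(y2) <= 0) {
    stop("both phenotypes need positive variance")
  }
  if (is.null(eig) || subsetted) {
    eig <- grm_eigen(grm, keep = if (subsetted) keep else NULL)
  }
  n <- length(y1)
  d <- eig$values
  yt1 <- crossprod(eig$vectors, y1)[, 1]
  yt2 <- crossprod(eig$vectors, y2)[, 1]
  xt <- crossprod(eig$vectors, rep(1, n))[, 1]
  S0 <- stats::cov(cbind(y1, y2))
  floor_v <- 1e-6 * diag(S0)
  # theta = (g1, g2, g12, e1, e2, e12)
  th <- c(S0[1, 1] / 2, S0[2, 2] / 2, S0[1, 2] / 2,
          S0[1, 1] / 2, S0[2, 2] / 2, S0[1, 2] / 2)
  names(th) <- c("sigma2_g1", "sigma2_g2", "sigma_g12",
                 "sigma2_e1", "sigma2_e2", "sigma_e12")
  # per-site 2x2 derivative coefficients (a11, a12, a22), scaled by d or 1
  coefs <- list(
    list(a11 = TRUE, a12 = FALSE, a22 = FALSE, gen = TRUE),
    list(a11 = FALSE, a12 = FALSE, a22 = TRUE, gen = TRUE),
    list(a11 = FALSE, a12 = TRUE, a22 = FALSE, gen = TRUE),
    list(a11 = TRUE, a12 = FALSE, a22 = FALSE, gen = FALSE),
    list(a11 = FALSE, a12 = FALSE, a22 = TRUE, gen = FALSE),
    list(a11 = FALSE, a12 = TRUE, a22 = FALSE, gen = FALSE)
  )

  core <- function(th) {
    W11 <- th[1] * d + th[4]
    W22 <- th[2] * d + th[5]
    W12 <- th[3] * d + th[6]
    det <- W11 * W22 - W12^2
    if (any(det <= 0) || any(W11 <= 0) || any(W22 <= 0)) return(NULL)
    I11 <- W22 / det
    I22 <- W11 / det
    I12 <- -W12 / det
    r1 <- I11 * yt1 + I12 * yt2
    r2 <- I12 * yt1 + I22 * yt2
    C <- matrix(c(sum(xt^2 * I11), sum(xt^2 * I12),
                  sum(xt^2 * I12), sum(xt^2 * I22)), 2, 2)
    cC <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(cC)) return(NULL)
    iC <- chol2inv(cC)
    b <- c(sum(xt * r1), sum(xt * r2))
    beta <- drop(iC %*% b)
    u1 <- r1 - xt * (I11 * beta[1] + I12 * beta[2])
    u2 <- r2 - xt * (I12 * beta[1] + I22 * beta[2])
    ypy <- sum(yt1 * r1 + yt2 * r2) - sum(b * beta)
    ll <- -0.5 * (sum(log(det)) + 2 * sum(log(diag(cC))) + ypy)
    list(ll = ll, I11 = I11, I12 = I12, I22 = I22,
         u1 = u1, u2 = u2, iC = iC)
  }
  site_quants <- function(st, cf) {
    scl <- if (cf$gen) d else rep(1, n)
    a11 <- if (cf$a11) scl else 0
    a12 <- if (cf$a12) scl else 0
    a22 <- if (cf$a22) scl else 0
    list(a11 = a11, a12 = a12, a22 = a22)
  }
  score_ai <- function(st) {
    score <- numeric(6)
    tmat <- vector("list", 6)
    smat <- vector("list", 6)
    hmat <- vector("list", 6)
    for (c_ in 1:6) {
      a <- site_quants(st, coefs[[c_]])
      # tr(W^-1 B) and the fixed-effect correction
      trWB <- sum(a$a11 * st$I11) + 2 * sum(a$a12 * st$I12) +
        sum(a$a22 * st$I22)
      K11 <- a$a11 * st$I11^2 + 2 * a$a12 * st$I11 * st$I12 +
        a$a22 * st$I12^2
      K12 <- a$a11 * st$I11 * st$I12 + a$a12 * (st$I11 * st$I22 +
                                                  st$I12^2) +
        a$a22 * st$I12 * st$I22
      K22 <- a$a11 * st$I12^2 + 2 * a$a12 * st$I12 * st$I22 +
        a$a22 * st$I22^2
      Mc <- matrix(c(sum(xt^2 * K11), sum(xt^2 * K12),
                     sum(xt^2 * K12), sum(xt^2 * K22)), 2, 2)
      tr_pv <- trWB - sum(st$iC * Mc)
      upu <- sum(a$a11 * st$u1^2) + 2 * sum(a$a12 * st$u1 * st$u2) +
        sum(a$a22 * st$u2^2)
      score[c_] <- -0.5 * (tr_pv - upu)
      t1 <- a$a11 * st$u1 + a$a12 * st$u2
      t2 <- a$a12 * st$u1 + a$a22 * st$u2
      s1 <- st$I11 * t1 + st$I12 * t2
      s2 <- st$I12 * t1 + st$I22 * t2
      tmat[[c_]] <- cbind(t1, t2)
      smat[[c_]] <- cbind(s1, s2)
      hmat[[c_]] <- c(sum(xt * s1), sum(xt * s2))
    }
    AI <- matrix(0, 6, 6)
    for (a_ in 1:6) {
      for (b_ in a_:6) {
        AI[a_, b_] <- AI[b_, a_] <- 0.5 *
          (sum(tmat[[a_]] * smat[[b_]]) -
             drop(crossprod(hmat[[a_]], st$iC %*% hmat[[b_]])))
      }
    }
    list(score = score, AI = AI)
  }
  clamp <- function(th) {
    flag <- FALSE
    th[c(1, 4)] <- pmax(th[c(1, 4)], floor_v[1])
    th[c(2, 5)] <- pmax(th[c(2, 5)], floor_v[2])
    gmax <- 0.999 * sqrt(th[1] * th[2])
    if (abs(th[3]) > gmax) {
      th[3] <- sign(th[3]) * gmax
      flag <- TRUE
    }
    emax <- 0.999 * sqrt(th[4] * th[5])
    if (abs(th[6]) > emax) {
      th[6] <- sign(th[6]) * emax
      flag <- TRUE
    }
    attr(th, "clamped") <- flag
    th
  }

  th <- clamp(th)
  st <- core(th)
  if (is.null(st)) stop("invalid starting values (non-PD V)")
  ll_trace <- st$ll
  converged <- FALSE
  any_clamp <- FALSE
  for (it in seq_len(max_iter)) {
    sa <- score_ai(st)
    at_floor <- c(th[1] <= floor_v[1] * (1 + 1e-12),
                  th[2] <= floor_v[2] * (1 + 1e-12),
                  FALSE,
                  th[4] <= floor_v[1] * (1 + 1e-12),
                  th[5] <= floor_v[2] * (1 + 1e-12),
                  FALSE)
    free <- !(at_floor & sa$score < 0)
    delta <- numeric(6)
    AIf <- sa$AI[free, free, drop = FALSE]
    sol <- tryCatch(solve(AIf, sa$score[free]), error = function(e) NULL)
    if (is.null(sol)) sol <- sa$score[free] / (abs(diag(AIf)) + 1e-8)
    delta[free] <- sol
    step <- if (it == 1) 0.5 else 1    # damped opener
    accepted <- FALSE
    for (half in 1:30) {
      th_try <- clamp(th + step * delta)
      st_try <- core(th_try)
      if (!is.null(st_try) && st_try$ll >= st$ll - 1e-10) {
        any_clamp <- any_clamp || attr(th_try, "clamped")
        th <- th_try
        ll_change <- st_try$ll - st$ll
        st <- st_try
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    ll_trace <- c(ll_trace, st$ll)
    if (abs(ll_change) < tol) {
      converged <- TRUE
      break
    }
  }
  sa <- score_ai(st)
  iAI <- tryCatch(solve(sa$AI), error = function(e) NULL)
  identifiable <- !is.null(iAI) && all(is.finite(iAI)) &&
    rcond(sa$AI) >= 1e-12
  if (!identifiable) iAI <- matrix(NA_real_, 6, 6)
  se_comp <- sqrt(pmax(diag(iAI), 0))
  h2_1 <- th[1] / (th[1] + th[4])
  h2_2 <- th[2] / (th[2] + th[5])
  se_h2 <- function(gi, ei) {
    s <- th[gi] + th[ei]
    g <- numeric(6)
    g[gi] <- th[ei] / s^2
    g[ei] <- -th[gi] / s^2
    sqrt(max(drop(crossprod(g, iAI %*% g)), 0))
  }
  rg_raw <- th[3] / sqrt(th[1] * th[2])
  rg_clamped <- abs(rg_raw) > 1
  rg <- max(min(rg_raw, 1), -1)
  g_rg <- numeric(6)
  g_rg[1] <- -rg_raw / (2 * th[1])
  g_rg[2] <- -rg_raw / (2 * th[2])
  g_rg[3] <- 1 / sqrt(th[1] * th[2])
  rg_se <- if (identifiable) {
    sqrt(max(drop(crossprod(g_rg, iAI %*% g_rg)), 0))
  } else {
    NA_real_
  }
  out <- list(
    components = th,
    se_components = stats::setNames(se_comp, names(th)),
    h2 = c(trait1 = unname(h2_1), trait2 = unname(h2_2)),
    h2_se = c(trait1 = if (identifiable) se_h2(1, 4) else NA_real_,
              trait2 = if (identifiable) se_h2(2, 5) else NA_real_),
    rG = unname(rg), rG_se = unname(rg_se),
    rG_clamped = rg_clamped || any_clamp,
    loglik_trace = ll_trace, loglik = st$ll,
    converged = converged, n_used = n,
    identifiable = identifiable,
    type = "bivariate"
  )
  class(out) <- "varcomp_result"
  out
}

#' @export
print.varcomp_result <- function(x, ...) {
  if (x$type == "univariate") {
    cat(sprintf(
      "AI-REML (univariate, n = %d): sigma2_g = %.4f (%.4f), sigma2_e = %.4f (%.4f)\n  h2 = %.4f (SE %.4f)%s\n",
      x$n_used, x$components[1], x$se_components[1],
      x$components[2], x$se_components[2], x$h2, x$h2_se,
      if (x$converged) "" else "  [NOT CONVERGED]"
    ))
  } else {
    cat(sprintf(
      "AI-REML (bivariate, n = %d): h2 = (%.4f, %.4f), rG = %.4f (SE %.4f)%s%s\n",
      x$n_used, x$h2[1], x$h2[2], x$rG, x$rG_se,
      if (x$rG_clamped) "  [clamped]" else "",
      if (x$converged) "" else "  [NOT CONVERGED]"
    ))
  }
  invisible(x)
}
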