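# Confirmatory model specifications.
#
# A model_spec stores, for each parameter matrix, an integer id matrix
# (0 = fixed at the value in the companion *_fix matrix, > 0 = free
# parameter; equal ids impose equality constraints) over
#   Lambda (p x k loadings), Phi (k x k latent covariance, unit diagonal),
#   Theta (p x p residual covariance), mu (p means).
# All latents are identified by unit variance. A second-order structure
# replaces Phi by gamma gamma' off the diagonal (unit total first-order
# variances, so first-order disturbances are 1 - gamma^2 by construction);
# with only two first-order factors the two second-order loadings share one
# parameter, the minimal identifying constraint.

new_model_spec <- function(indicators, latents, lambda_id, lambda_fix,
                           phi_id, phi_fix, theta_id, theta_fix,
                           mu_id, second_order = NULL,
                           structure = "custom", variant = "none") {
  p <- length(indicators)
  k <- length(latents)
  ids <- c(lambda_id, phi_id, theta_id, mu_id,
           if (!is.null(second_order)) second_order$gamma_id)
  n_par <- length(unique(ids[ids > 0]))
  used <- sort(unique(ids[ids > 0]))
  if (!identical(used, seq_len(n_par))) {
    stop("parameter ids must be consecutive integers starting at 1")
  }
  free_load <- rowSums(matrix(lambda_id > 0 | lambda_fix != 0, p, k)) >= 0
  for (j in seq_len(k)) {
    if (!any(lambda_id[, j] > 0 | lambda_fix[, j] != 0)) {
      stop("latent '", latents[j], "' has no nonzero loading")
    }
  }
  obj <- list(
    indicators = indicators, latents = latents,
    lambda_id = lambda_id, lambda_fix = lambda_fix,
    phi_id = phi_id, phi_fix = phi_fix,
    theta_id = theta_id, theta_fix = theta_fix,
    mu_id = mu_id, second_order = second_order,
    n_par = n_par, structure = structure, variant = variant
  )
  class(obj) <- "model_spec"
  obj
}

#' @export
print.model_spec <- function(x, ...) {
  p <- length(x$indicators)
  cat(sprintf(
    "model_spec '%s' (psychopathology: %s): %d indicators, %d latents, %d free parameters, df = %d\n",
    x$structure, x$variant, p, length(x$latents), x$n_par, model_df(x)
  ))
  invisible(x)
}

#' Model degrees of freedom
#'
#' Observed first and second moments, `p(p+3)/2`, minus the number of free
#' parameters (means included; the mean structure is saturated in all
#' shipped models, so means never contribute misfit).
#'
#' @param spec a `model_spec`.
#' @return Integer degrees of freedom.
#' @export
model_df <- function(spec) {
  p <- length(spec$indicators)
  as.integer(p * (p + 3) / 2 - spec$n_par)
}

# sequential id allocator used by make_model_spec
id_counter <- function() {
  env <- new.env()
  env$i <- 0L
  function(n = 1L) {
    out <- env$i + seq_len(n)
    env$i <- env$i + n
    as.integer(out)
  }
}

#' Build the confirmatory model zoo
#'
#' Returns the loading, latent-covariance and residual patterns for the
#' structures compared in the pipeline, on the six core indicators (three
#' eating-disorder symptom scores `AN_score`, `BN_score`, `BED_score` and
#' three suicidality items `TAF1`-`TAF3`), optionally extended with the
#' depression and anxiety sum scores `PHQ8` and `GAD7`:
#'
#' \describe{
#'   \item{`efa_two_factor`}{two correlated first-order factors (eating
#'     disorders; suicidal ideation).}
#'   \item{`hierarchical`}{the same two first-order factors loading on a
#'     second-order general-susceptibility factor (unit variance; with two
#'     first-order factors the second-order loadings are constrained equal
#'     for identification).}
#'   \item{`residual`}{a bifactor ("residual") model: one general
#'     susceptibility factor over all indicators plus domain-specific
#'     factors for eating disorders and suicidal ideation, all mutually
#'     orthogonal.}
#'   \item{`four_factor`}{four correlated factors: restricting (AN),
#'     purging (BN), bingeing (BED) and suicidal ideation (TAF items); the
#'     single-indicator factors have free loading and zero residual.}
#' }
#'
#' Psychopathology variants: `"replace_general"` adds `PHQ8`/`GAD7` to the
#' common factor (the suicidal-ideation factor for the first-order
#' structures, the general factor for the bifactor); `"separate_factor"`
#' gives them their own factor (correlated for first-order structures;
#' loading on the second-order factor for the hierarchical structure; an
#' additional orthogonal specific factor, with equality-constrained
#' loadings, for the bifactor).
#'
#' @param structure one of `"efa_two_factor"`, `"hierarchical"`,
#'   `"residual"`, `"four_factor"`.
#' @param with_psychopathology one of `"none"`, `"replace_general"`,
#'   `"separate_factor"`.
#' @param constrain_specific logical; constrain each specific factor's
#'   loadings equal in the bifactor model (a remedy for empirically
#'   under-identified three-indicator specific factors; off by default).
#' @return A `model_spec`.
#' @export
make_model_spec <- function(structure = c("efa_two_factor", "hierarchical",
                                          "residual", "four_factor"),
                            with_psychopathology = c("none",
                                                     "replace_general",
                                                     "separate_factor"),
                            constrain_specific = FALSE) {
  structure <- match.arg(structure)
  with_psychopathology <- match.arg(with_psychopathology)
  psych <- with_psychopathology != "none"
  if (structure == "four_factor" && with_psychopathology == "replace_general") {
    stop("four_factor has no general factor to replace; ",
         "use with_psychopathology = 'separate_factor'")
  }
  ind <- indicator_names(psych)
  p <- length(ind)
  nxt <- id_counter()
  ed <- 1:3
  si <- 4:6
  pp <- if (psych) 7:8 else integer(0)

  if (structure %in% c("efa_two_factor", "hierarchical")) {
    latents <- c("ED", "SI")
    if (psych && with_psychopathology == "separate_factor") {
      latents <- c(latents, "PSY")
    }
    k <- length(latents)
    lambda_id <- matrix(0L, p, k, dimnames = list(ind, latents))
    lambda_fix <- matrix(0, p, k)
    lambda_id[ed, 1] <- nxt(3)
    lambda_id[si, 2] <- nxt(3)
    if (psych) {
      if (with_psychopathology == "replace_general") {
        lambda_id[pp, 2] <- nxt(2)
      } else {
        lambda_id[pp, 3] <- nxt(2)
      }
    }
    phi_id <- matrix(0L, k, k)
    phi_fix <- diag(k)
    second_order <- NULL
    if (structure == "hierarchical") {
      gamma_id <- if (k == 2) rep(nxt(1), 2) else nxt(k)
      second_order <- list(gamma_id = as.integer(gamma_id),
                           gamma_fix = rep(0, k))
    } else {
      for (a in seq_len(k - 1)) {
        for (b in (a + 1):k) {
          phi_id[a, b] <- phi_id[b, a] <- nxt(1)
        }
      }
    }
    theta_id <- diag_ids(p, nxt)
    theta_fix <- matrix(0, p, p)
  } else if (structure == "residual") {
    latents <- c("G", "sED", "sSI")
    if (psych && with_psychopathology == "separate_factor") {
      latents <- c(latents, "sPSY")
    }
    k <- length(latents)
    lambda_id <- matrix(0L, p, k, dimnames = list(ind, latents))
    lambda_fix <- matrix(0, p, k)
    lambda_id[1:6, 1] <- nxt(6)
    if (psych) lambda_id[pp, 1] <- nxt(2)
    lambda_id[ed, 2] <- if (constrain_specific) rep(nxt(1), 3) else nxt(3)
    lambda_id[si, 3] <- if (constrain_specific) rep(nxt(1), 3) else nxt(3)
    if (psych && with_psychopathology == "separate_factor") {
      # two-indicator specific factor: loadings constrained equal
      lambda_id[pp, 4] <- rep(nxt(1), 2)
    }
    phi_id <- matrix(0L, k, k)
    phi_fix <- diag(k)   # general and specifics mutually orthogonal
    second_order <- NULL
    theta_id <- diag_ids(p, nxt)
    theta_fix <- matrix(0, p, p)
  } else {  # four_factor
    latents <- c("restricting", "purging", "bingeing", "SI")
    if (psych) latents <- c(latents, "PSY")
    k <- length(latents)
    lambda_id <- matrix(0L, p, k, dimnames = list(ind, latents))
    lambda_fix <- matrix(0, p, k)
    lambda_id[1, 1] <- nxt(1)
    lambda_id[2, 2] <- nxt(1)
    lambda_id[3, 3] <- nxt(1)
    lambda_id[si, 4] <- nxt(3)
    if (psych) lambda_id[pp, 5] <- nxt(2)
    phi_id <- matrix(0L, k, k)
    phi_fix <- diag(k)
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        phi_id[a, b] <- phi_id[b, a] <- nxt(1)
      }
    }
    second_order <- NULL
    theta_id <- matrix(0L, p, p)
    theta_fix <- matrix(0, p, p)
    free_resid <- c(si, pp)   # single-indicator factors: residual fixed at 0
    diag(theta_id)[free_resid] <- nxt(length(free_resid))
  }
  mu_id <- nxt(p)
  new_model_spec(ind, latents, lambda_id, lambda_fix, phi_id, phi_fix,
                 theta_id, theta_fix, mu_id, second_order,
                 structure = structure, variant = with_psychopathology)
}

diag_ids <- function(p, nxt) {
  m <- matrix(0L, p, p)
  diag(m) <- nxt(p)
  m
}

# Materialize (Lambda, Phi, Theta, mu) from the free-parameter vector.
build_model_matrices <- function(spec, theta) {
  L <- spec$lambda_fix
  sel <- spec$lambda_id > 0
  L[sel] <- theta[spec$lambda_id[sel]]
  k <- length(spec$latents)
  if (!is.null(spec$second_order)) {
    g <- spec$second_order$gamma_fix
    gsel <- spec$second_order$gamma_id > 0
    g[gsel] <- theta[spec$second_order$gamma_id[gsel]]
    Phi <- tcrossprod(g)
    diag(Phi) <- 1
    gamma <- g
  } else {
    Phi <- spec$phi_fix
    psel <- spec$phi_id > 0
    Phi[psel] <- theta[spec$phi_id[psel]]
    gamma <- NULL
  }
  Th <- spec$theta_fix
  tsel <- spec$theta_id > 0
  Th[tsel] <- theta[spec$theta_id[tsel]]
  mu <- theta[spec$mu_id]
  list(Lambda = L, Phi = Phi, Theta = Th, mu = mu, gamma = gamma)
}

# Human-readable names for the free-parameter vector.
model_par_names <- function(spec) {
  nm <- character(spec$n_par)
  lab <- function(idm, make, canonical = FALSE) {
    w <- which(idm > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(w))) {
      ij <- w[r, ]
      if (canonical && ij[1] > ij[2]) ij <- rev(ij)
      id <- idm[ij[1], ij[2]]
      if (nm[id] == "") nm[id] <<- make(ij)
    }
  }
  lab(spec$lambda_id, function(ij) {
    paste0("lambda[", spec$indicators[ij[1]], ",", spec$latents[ij[2]], "]")
  })
  if (!is.null(spec$second_order)) {
    gid <- spec$second_order$gamma_id
    for (a in seq_along(gid)) {
      if (gid[a] > 0 && nm[gid[a]] == "") {
        nm[gid[a]] <- paste0("gamma[", spec$latents[a], "]")
      }
    }
  } else {
    lab(spec$phi_id, function(ij) {
      paste0("phi[", spec$latents[ij[1]], ",", spec$latents[ij[2]], "]")
    }, canonical = TRUE)
  }
  lab(spec$theta_id, function(ij) {
    if (ij[1] == ij[2]) paste0("theta[", spec$indicators[ij[1]], "]")
    else paste0("theta[", spec$indicators[ij[1]], ",",
                spec$indicators[ij[2]], "]")
  }, canonical = TRUE)
  for (i in seq_along(spec$mu_id)) {
    id <- spec$mu_id[i]
    if (id > 0 && nm[id] == "") nm[id] <- paste0("mu[", spec$indicators[i], "]")
  }
  nm
}
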