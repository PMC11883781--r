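# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

# Two-factor phenotype table (six indicators, purely phenotypic).
make_two_factor_table <- function(n, phi12 = 0.5, loading = 0.7, seed = 1,
                                  missing = 0) {
  L <- matrix(0, 6, 2,
              dimnames = list(indicator_names(), c("ED", "SI")))
  L[1:3, 1] <- loading
  L[4:6, 2] <- loading
  params <- generative_params(
    n = n, m = 10, true_loadings = L,
    factor_corr = matrix(c(1, phi12, phi12, 1), 2, 2),
    h2_per_latent = c(0, 0), genetic_corr = diag(2),
    missing_rate = missing, seed = seed
  )
  truth <- simulate_latent_structure(NULL, params)
  tab <- generate_observed_items(truth, params)
  if (missing > 0) tab <- inject_missingness(tab, missing, seed = seed + 3L)
  list(table = tab, truth = truth, params = params)
}

# Single-factor spec (k latents are not all reachable via make_model_spec).
one_factor_spec <- function(indicators) {
  p <- length(indicators)
  semgreml:::new_model_spec(
    indicators = indicators, latents = "F1",
    lambda_id = matrix(seq_len(p), p, 1),
    lambda_fix = matrix(0, p, 1),
    phi_id = matrix(0L, 1, 1), phi_fix = matrix(1, 1, 1),
    theta_id = diag(p + seq_len(p)), theta_fix = matrix(0, p, p),
    mu_id = 2L * p + seq_len(p)
  )
}

# Independent dense REML log-likelihood (the brute-force oracle):
# -1/2 [ log|V| + log|X'V^-1 X| + y'Py ], V = A sg + I se, X = intercept.
dense_reml_loglik <- function(A, y, sg, se) {
  n <- length(y)
  V <- sg * A + diag(se, n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  iV <- chol2inv(ch)
  X <- matrix(1, n, 1)
  C <- crossprod(X, iV %*% X)
  P <- iV - iV %*% X %*% solve(C) %*% crossprod(X, iV)
  -0.5 * (2 * sum(log(diag(ch))) + log(C[1, 1]) +
            drop(crossprod(y, P %*% y)))
}

# indicator_names is internal; re-export for fixtures
indicator_names <- semgreml:::indicator_names
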