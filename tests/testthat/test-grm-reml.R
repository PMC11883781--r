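# GRM construction and AI-REML variance components.

test_that("GRM matches the standardization formula on a hand fixture", {
  # two individuals, two SNPs, dosages (0,2) and (2,0), p = (0.5, 0.5):
  # z = (x - 1)/sqrt(0.5), A = ZZ'/2 = [[2, -2], [-2, 2]]
  g <- genotype_matrix(matrix(c(0, 2, 2, 0), nrow = 2))
  A <- compute_grm(g, maf_min = 0, max_missing = 1)
  expect_equal(A$matrix, matrix(c(2, -2, -2, 2), 2, 2))
  expect_equal(unique(as.vector(A$pair_counts)), 2)

  # duplicated individual: off-diagonal equals the shared diagonal
  g2 <- simulate_genotypes(50, 200, seed = 111)
  dup <- genotype_matrix(rbind(g2$dosages, g2$dosages[1, ]))
  A2 <- compute_grm(dup, maf_min = 0, max_missing = 1)$matrix
  expect_equal(A2[1, 51], A2[1, 1], tolerance = 1e-12)

  expect_error(compute_grm(g, maf_min = 0.6), "no SNPs")
})

test_that("GRM sampling moments and spectrum behave as theory predicts", {
  geno <- simulate_genotypes(1000, 5000, seed = 112)
  grm <- compute_grm(geno)
  A <- grm$matrix
  expect_gt(mean(diag(A)), 0.95)
  expect_lt(mean(diag(A)), 1.05)
  off <- A[upper.tri(A)]
  expect_lt(abs(mean(off)), 0.005)
  # var(A_jk) ~ 1/m for independent SNPs, within 20%
  expect_gt(var(off) / (1 / grm$m_used), 0.8)
  expect_lt(var(off) / (1 / grm$m_used), 1.2)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("missing dosages are mean-imputed and pair counts recorded", {
  set.seed(113)
  g <- simulate_genotypes(60, 80, seed = 113)
  d <- g$dosages
  d[sample(length(d), 200)] <- NA
  gm <- genotype_matrix(d)
  grm <- compute_grm(gm, maf_min = 0.01, max_missing = 1)
  expect_true(all(grm$pair_counts <= grm$m_used))
  expect_true(isSymmetric(grm$matrix))
  expect_true(all(is.finite(grm$matrix)))
})

test_that("univariate AI-REML agrees with a dense grid search on a toy problem", {
  geno <- simulate_genotypes(40, 300, seed = 41)
  grm <- compute_grm(geno)
  p <- generative_params(n = 40, m = 300,
                         true_loadings = matrix(1, 1, 1,
                                                dimnames = list("Y", "F")),
                         factor_corr = NULL, h2_per_latent = 0.5, seed = 41)
  tr <- simulate_latent_structure(geno, p)
  y <- tr$factor_values[, 1]
  fit <- fit_aireml_univariate(grm, y)
  expect_true(fit$converged)
  # the comparison needs an interior optimum (the grid cannot represent the
  # variance floor)
  expect_true(all(fit$components > 0.01 & fit$components < 1.5))

  grid <- seq(0.005, 1.5, by = 0.005)
  best <- c(NA, NA)
  bv <- -Inf
  for (sg in grid) {
    lls <- vapply(grid, function(se) dense_reml_loglik(grm$matrix, y, sg, se),
                  numeric(1))
    i <- which.max(lls)
    if (lls[i] > bv) {
      bv <- lls[i]
      best <- c(sg, grid[i])
    }
  }
  expect_lt(max(abs(fit$components - best)), 0.005)
})

test_that("REML log-likelihood is non-decreasing over accepted iterations", {
  geno <- simulate_genotypes(500, 1000, seed = 115)
  grm <- compute_grm(geno)
  p <- generative_params(n = 500, m = 1000, h2_per_latent = c(0.4, 0.4),
                         genetic_corr = matrix(c(1, .5, .5, 1), 2),
                         factor_corr = NULL, seed = 115)
  tr <- simulate_latent_structure(geno, p)
  f1 <- fit_aireml_univariate(grm, tr$factor_values[, 1])
  expect_true(all(diff(f1$loglik_trace) >= -1e-9))
  f2 <- fit_aireml_bivariate(grm, tr$factor_values[, 1],
                             tr$factor_values[, 2])
  expect_true(all(diff(f2$loglik_trace) >= -1e-9))
  expect_true(f2$converged)
})

test_that("univariate heritability is recovered across replicates", {
  h2s <- vapply(1:12, function(s) {
    geno <- simulate_genotypes(1000, 2000, seed = 300 + s)
    grm <- compute_grm(geno)
    p <- generative_params(n = 1000, m = 2000,
                           true_loadings = matrix(1, 1, 1,
                                                  dimnames = list("Y", "F")),
                           factor_corr = NULL, h2_per_latent = 0.5,
                           seed = 300 + s)
    tr <- simulate_latent_structure(geno, p)
    fit_aireml_univariate(grm, tr$factor_values[, 1])$h2
  }, numeric(1))
  mc_se <- sd(h2s) / sqrt(length(h2s))
  expect_lt(abs(mean(h2s) - 0.5), 3 * mc_se)
})

test_that("permuted phenotypes estimate heritability near the null floor", {
  geno <- simulate_genotypes(400, 800, seed = 116)
  grm <- compute_grm(geno)
  eig <- eigen(grm$matrix, symmetric = TRUE)
  p <- generative_params(n = 400, m = 800,
                         true_loadings = matrix(1, 1, 1,
                                                dimnames = list("Y", "F")),
                         factor_corr = NULL, h2_per_latent = 0.5, seed = 116)
  tr <- simulate_latent_structure(geno, p)
  set.seed(117)
  h2s <- vapply(1:20, function(i) {
    fit_aireml_univariate(grm, sample(tr$factor_values[, 1]), eig = eig)$h2
  }, numeric(1))
  # estimates are floored at ~0, so the null mean is small and the median
  # sits at the boundary
  expect_lt(mean(h2s), 0.06)
  expect_lt(median(h2s), 0.03)
})

test_that("bivariate marginals agree with the univariate fit", {
  # with y2 pure independent noise the joint REML decouples (up to O(1/n)
  # coupling through the estimated cross-covariances), so the genetic
  # variance of trait 1 must match the univariate fit
  geno <- simulate_genotypes(2000, 4000, seed = 118)
  grm <- compute_grm(geno)
  p <- generative_params(n = 2000, m = 4000,
                         true_loadings = matrix(1, 1, 1,
                                                dimnames = list("Y", "F")),
                         factor_corr = NULL, h2_per_latent = 0.4, seed = 118)
  tr <- simulate_latent_structure(geno, p)
  y1 <- tr$factor_values[, 1]
  set.seed(119)
  y2 <- rnorm(2000)    # independent noise
  eig <- eigen(grm$matrix, symmetric = TRUE)
  uni <- fit_aireml_univariate(grm, y1, tol = 1e-9, eig = eig)
  biv <- fit_aireml_bivariate(grm, y1, y2, tol = 1e-9, eig = eig)
  expect_lt(abs(uni$components["sigma2_g"] - biv$components["sigma2_g1"]),
            1e-3)
})

test_that("identical traits hit the rG boundary and are flagged", {
  geno <- simulate_genotypes(300, 600, seed = 120)
  grm <- compute_grm(geno)
  p <- generative_params(n = 300, m = 600,
                         true_loadings = matrix(1, 1, 1,
                                                dimnames = list("Y", "F")),
                         factor_corr = NULL, h2_per_latent = 0.5, seed = 120)
  tr <- simulate_latent_structure(geno, p)
  y <- tr$factor_values[, 1]
  fit <- fit_aireml_bivariate(grm, y, y)
  expect_gt(fit$rG, 0.99)
  expect_true(fit$rG_clamped)
})

test_that("closed-form var(rG) matches the empirical REML sampling variance", {
  # synthetic GRM whose off-diagonal variance is set directly (identity plus
  # independent symmetric noise), the regime the closed form describes;
  # phenotypes are simulated from the exact bivariate model in the GRM
  # eigenbasis, h2 = 0.5 both traits, rG = rP = 0.5
  set.seed(99)
  n <- 1000
  var_pi <- 2e-4
  E <- matrix(rnorm(n * n, 0, sqrt(var_pi)), n, n)
  E <- (E + t(E)) / sqrt(2)
  A <- diag(n) + E
  diag(A) <- 1
  eig <- eigen(A, symmetric = TRUE)
  expect_gt(min(eig$values), 0)
  grm <- semgreml:::new_grm(A, matrix(5000, n, n),
                            data.frame(family_id = paste0("F", 1:n),
                                       individual_id = paste0("I", 1:n),
                                       stringsAsFactors = FALSE), 5000)
  Sg <- matrix(c(.5, .25, .25, .5), 2)
  Se <- matrix(c(.5, .25, .25, .5), 2)
  n_rep <- 100
  rgs <- vapply(seq_len(n_rep), function(s) {
    set.seed(3000 + s)
    Z <- matrix(rnorm(2 * n), n, 2)
    Y <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      W <- eig$values[i] * Sg + Se
      Y[i, ] <- drop(t(chol(W)) %*% Z[i, ])
    }
    Yo <- eig$vectors %*% Y
    fit_aireml_bivariate(grm, Yo[, 1], Yo[, 2], eig = eig)$rG
  }, numeric(1))
  v_closed <- var_rg_greml(n, 0.5, 0.5, 0.5, 0.5,
                           var_offdiag = var(A[upper.tri(A)]))
  ratio <- var(rgs) / v_closed
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.33)
  # and the estimator is centered on the generative value
  expect_lt(abs(mean(rgs) - 0.5), 3 * sd(rgs) / sqrt(n_rep))
})
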