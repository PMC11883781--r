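# Per-SNP association scan and calibration diagnostics.

test_that("per-SNP OLS matches lm on a hand-sized fixture", {
  x <- c(0, 1, 2, 1)
  y <- c(0.1, 0.2, 0.35, 0.2)
  geno <- genotype_matrix(matrix(x, 4, 1))
  sc <- data.frame(FID = geno$sample_ids$family_id,
                   IID = geno$sample_ids$individual_id,
                   F1 = y, stringsAsFactors = FALSE)
  res <- run_gwas(sc, geno, "F1")
  ref <- summary(lm(y ~ x))$coefficients
  expect_equal(res$BETA, ref[2, 1], tolerance = 1e-12)
  expect_equal(res$SE, ref[2, 2], tolerance = 1e-12)
  expect_equal(res$T_STAT, ref[2, 3], tolerance = 1e-12)
  expect_equal(res$P, ref[2, 4], tolerance = 1e-12)
})

test_that("beta flips sign but keeps magnitude when the counted allele swaps", {
  geno <- simulate_genotypes(300, 20, seed = 131)
  set.seed(132)
  sc <- data.frame(FID = geno$sample_ids$family_id,
                   IID = geno$sample_ids$individual_id,
                   F1 = rnorm(300), stringsAsFactors = FALSE)
  res1 <- run_gwas(sc, geno, "F1")
  swapped <- genotype_matrix(2 - geno$dosages, geno$snp_meta,
                             geno$sample_ids)
  res2 <- run_gwas(sc, swapped, "F1")
  expect_equal(res2$BETA, -res1$BETA, tolerance = 1e-10)
  expect_equal(res2$SE, res1$SE, tolerance = 1e-10)
})

test_that("monomorphic SNPs are skipped with a reason code", {
  set.seed(130)
  d <- cbind(rep(1, 50), rbinom(50, 2, 0.4) + 0)
  d[1, 2] <- 1   # ensure polymorphic second column
  geno <- genotype_matrix(d)
  sc <- data.frame(FID = geno$sample_ids$family_id,
                   IID = geno$sample_ids$individual_id,
                   F1 = rnorm(50), stringsAsFactors = FALSE)
  res <- run_gwas(sc, geno, "F1")
  expect_equal(res$SKIP_REASON[1], "monomorphic")
  expect_true(is.na(res$BETA[1]))
  expect_false(is.na(res$BETA[2]))
})

test_that("genomic inflation is scale-equivariant and refuses tiny scans", {
  # exactly uniform p-values -> lambda ~ 1
  k <- 1001
  p_grid <- (seq_len(k) - 0.5) / k
  fake <- data.frame(T_STAT = sqrt(qchisq(p_grid, 1)))
  lam <- genomic_inflation(fake)
  expect_equal(lam, 1, tolerance = 0.01)
  fake2 <- data.frame(T_STAT = fake$T_STAT * sqrt(2))
  expect_equal(genomic_inflation(fake2), 2 * lam, tolerance = 1e-10)
  expect_error(genomic_inflation(data.frame(T_STAT = rnorm(50))),
               "at least 100")
})

test_that("a null scan is calibrated: lambda near 1, type-I error near alpha", {
  # m large enough that the median-based lambda has SE ~ 0.018
  geno <- simulate_genotypes(1000, 20000, seed = 133)
  set.seed(134)
  sc <- data.frame(FID = geno$sample_ids$family_id,
                   IID = geno$sample_ids$individual_id,
                   F1 = rnorm(1000), stringsAsFactors = FALSE)
  res <- run_gwas(sc, geno, "F1")
  lam <- attr(res, "lambda_gc")
  expect_gt(lam, 0.95)
  expect_lt(lam, 1.05)
  t1e <- mean(res$P < 0.05, na.rm = TRUE)
  se <- sqrt(0.05 * 0.95 / 20000)
  expect_lt(abs(t1e - 0.05), 4 * se)
  qq <- qq_data(res)
  expect_equal(nrow(qq), 20000)
})

test_that("missing dosages are handled by imputation or per-SNP dropping", {
  geno <- simulate_genotypes(500, 150, seed = 135)
  d <- geno$dosages
  set.seed(136)
  d[sample(length(d), 1500)] <- NA
  gm <- genotype_matrix(d)
  sc <- data.frame(FID = gm$sample_ids$family_id,
                   IID = gm$sample_ids$individual_id,
                   F1 = rnorm(500), stringsAsFactors = FALSE)
  r_imp <- run_gwas(sc, gm, "F1", impute_missing = TRUE)
  r_drop <- run_gwas(sc, gm, "F1", impute_missing = FALSE)
  expect_true(all(r_imp$N == 500))
  expect_true(all(r_drop$N <= 500))
  # the two handling schemes agree closely at this missingness
  expect_gt(cor(r_imp$BETA, r_drop$BETA, use = "complete.obs"), 0.98)
})

test_that("factor-score GWAS is attenuated relative to the true latent", {
  # all SNPs causal on one latent: the scan on extracted scores shows
  # smaller mean association chi-square than the scan on the true factor,
  # and the single-SNP effect is shrunk by the squared determinacy
  geno <- simulate_genotypes(2000, 300, seed = 137)
  L <- matrix(0.7, 6, 1, dimnames = list(indicator_names(), "F"))
  p <- generative_params(n = 2000, m = 300, true_loadings = L,
                         factor_corr = matrix(1, 1, 1),
                         h2_per_latent = 0.5, seed = 137)
  tr <- simulate_latent_structure(geno, p)
  tab <- generate_observed_items(tr, p)
  fit <- fit_cfa_fiml(tab, one_factor_spec(rownames(L)), se = FALSE)
  sc <- extract_factor_scores(fit, tab)
  truth_sc <- data.frame(FID = tab$FID, IID = tab$IID,
                         F1 = tr$factor_values[, 1],
                         stringsAsFactors = FALSE)
  r_true <- run_gwas(truth_sc, geno, "F1")
  names(sc)[3] <- "F1"
  r_score <- run_gwas(sc, geno, "F1")
  expect_gt(mean(r_true$T_STAT^2), mean(r_score$T_STAT^2))
  # mean per-SNP slope ratio ~ determinacy^2
  rho2 <- attr(sc, "determinacy")[1]^2
  ratio <- coef(lm(r_score$BETA ~ 0 + r_true$BETA))[1]
  expect_equal(unname(ratio), unname(rho2), tolerance = 0.05)
})

test_that("single-SNP effect on the score equals determinacy^2 times the true effect", {
  b <- 0.15
  betas <- numeric(10)
  expected <- numeric(10)
  for (s in 1:10) {
    geno <- simulate_genotypes(5000, 40, seed = 500 + s)
    z1 <- scale(geno$dosages[, 1])[, 1]
    set.seed(600 + s)
    f <- b * z1 + rnorm(5000, 0, sqrt(1 - b^2))
    truth <- structure(list(
      factor_values = matrix(f, dimnames = list(NULL, "F")),
      factor_cov = matrix(1, 1, 1)
    ), class = "latent_truth")
    L <- matrix(0.7, 6, 1, dimnames = list(indicator_names(), "F"))
    p <- generative_params(n = 5000, m = 40, true_loadings = L,
                           factor_corr = matrix(1, 1, 1), h2_per_latent = 0,
                           seed = 600 + s)
    tab <- generate_observed_items(truth, p)
    fit <- fit_cfa_fiml(tab, one_factor_spec(rownames(L)), se = FALSE)
    sc <- extract_factor_scores(fit, tab)
    rho2 <- attr(sc, "determinacy")[1]^2
    names(sc)[3] <- "F1"
    res <- run_gwas(sc, geno, "F1")
    betas[s] <- res$BETA[1]
    expected[s] <- rho2 * b / sd(geno$dosages[, 1])
  }
  mc_se <- sd(betas - expected) / sqrt(10)
  expect_lt(abs(mean(betas - expected)), 3 * mc_se)
})
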