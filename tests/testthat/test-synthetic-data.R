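# Synthetic-data generator: genotypes, latent structure, observed items,
# missingness.

test_that("genotype simulation is seeded, bounded and binomially calibrated", {
  g1 <- simulate_genotypes(200, 50, seed = 3)
  g2 <- simulate_genotypes(200, 50, seed = 3)
  expect_identical(g1$dosages, g2$dosages)
  expect_error(simulate_genotypes(100, 10, maf_range = c(0, 0.5)),
               "maf_range")
  expect_error(simulate_genotypes(100, 10, maf_range = c(0.1, 0.6)),
               "maf_range")

  # forced p = 0.5: sample frequencies concentrate at 0.5
  g <- simulate_genotypes(10000, 20, maf_range = c(0.5, 0.5), seed = 4)
  se <- sqrt(0.5 * 0.5 / (2 * 10000))
  expect_true(all(abs(g$allele_freq - 0.5) < 4 * se))

  # n = 5000, single SNP at p = 0.3: mean dosage within 3 SE of 0.6
  g <- simulate_genotypes(5000, 1, maf_range = c(0.3, 0.3), seed = 5)
  se <- sqrt(2 * 0.3 * 0.7 / 5000)
  expect_lt(abs(mean(g$dosages) - 0.6), 3 * se)

  # no monomorphic SNPs even at low frequency and small n
  g <- simulate_genotypes(30, 200, maf_range = c(0.01, 0.05), seed = 6)
  expect_true(all(apply(g$dosages, 2, var) > 0))
})

test_that("latent genetic values honor heritability and genetic correlation", {
  geno <- simulate_genotypes(500, 800, seed = 11)
  # zero-heritability latent has identically zero genetic values
  p0 <- generative_params(n = 500, m = 800,
                          h2_per_latent = c(0, 0.3), genetic_corr = diag(2),
                          factor_corr = NULL, seed = 11)
  tr0 <- simulate_latent_structure(geno, p0)
  expect_true(all(tr0$genetic_values[, 1] == 0))
  expect_equal(var(tr0$genetic_values[, 2]), 0.3, tolerance = 1e-10)
  expect_equal(apply(tr0$factor_values, 2, var), c(ED = 1, SI = 1),
               tolerance = 0.05)

  # identity genetic correlation: cross-latent genetic correlation near 0
  cors <- sapply(1:10, function(s) {
    gg <- simulate_genotypes(800, 1000, seed = 100 + s)
    pp <- generative_params(n = 800, m = 1000, h2_per_latent = c(0.5, 0.5),
                            genetic_corr = diag(2), factor_corr = NULL,
                            seed = 100 + s)
    tt <- simulate_latent_structure(gg, pp)
    cor(tt$genetic_values[, 1], tt$genetic_values[, 2])
  })
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(10) + 0.02)

  # generative rG = 0.7 recovered by the realized genetic-value correlation
  cors <- sapply(1:20, function(s) {
    gg <- simulate_genotypes(1000, 2000, seed = 200 + s)
    pp <- generative_params(n = 1000, m = 2000, h2_per_latent = c(0.5, 0.5),
                            genetic_corr = matrix(c(1, .7, .7, 1), 2),
                            factor_corr = NULL, seed = 200 + s)
    tt <- simulate_latent_structure(gg, pp)
    cor(tt$genetic_values[, 1], tt$genetic_values[, 2])
  })
  expect_gt(mean(cors), 0.65)
  expect_lt(mean(cors), 0.75)

  # invalid correlation matrices are rejected
  bad <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  expect_error(generative_params(genetic_corr = bad), "positive semidefinite")
})

test_that("observed items follow the requested measurement model", {
  # a zero-loadings indicator is pure noise
  L <- matrix(0, 6, 2, dimnames = list(indicator_names(), c("ED", "SI")))
  L[1:3, 1] <- 0.7
  L[5:6, 2] <- 0.7   # TAF1 (row 4) loads on nothing
  pp <- generative_params(n = 20000, m = 10, true_loadings = L,
                          factor_corr = matrix(c(1, .5, .5, 1), 2),
                          h2_per_latent = c(0, 0), seed = 31)
  tr <- simulate_latent_structure(NULL, pp)
  tab <- generate_observed_items(tr, pp)
  expect_lt(max(abs(cor(tab$TAF1, tr$factor_values))), 0.03)

  # single factor, loading 0.8: indicator-factor correlation near 0.8
  L1 <- matrix(0.8, 6, 1, dimnames = list(indicator_names(), "F"))
  p1 <- generative_params(n = 20000, m = 10, true_loadings = L1,
                          factor_corr = matrix(1, 1, 1),
                          h2_per_latent = 0, seed = 32)
  t1 <- simulate_latent_structure(NULL, p1)
  tb1 <- generate_observed_items(t1, p1)
  r <- cor(tb1$AN_score, t1$factor_values[, 1])
  expect_gt(r, 0.78)
  expect_lt(r, 0.82)

  # liability-threshold TAF items hit the requested prevalence
  p2 <- generative_params(n = 10000, m = 10, taf_prevalence = 0.5,
                          h2_per_latent = c(0, 0), seed = 33)
  t2 <- simulate_latent_structure(NULL, p2)
  tb2 <- generate_observed_items(t2, p2)
  expect_true(all(sort(unique(tb2$TAF1)) %in% c(0, 1)))
  expect_lt(abs(mean(tb2$TAF2) - 0.5), 3 * sqrt(0.25 / 10000) + 1e-4)

  # communality > 1 is a parameter error
  Lbad <- matrix(0.9, 6, 2, dimnames = list(indicator_names(), c("A", "B")))
  pbad <- generative_params(n = 100, m = 10, true_loadings = Lbad,
                            factor_corr = matrix(c(1, .5, .5, 1), 2),
                            h2_per_latent = c(0, 0), seed = 34)
  tbad <- simulate_latent_structure(NULL, pbad)
  expect_error(generate_observed_items(tbad, pbad), "communality")
})

test_that("indicator covariance converges to Lambda Phi Lambda' + Theta", {
  n <- 50000
  fx <- make_two_factor_table(n, phi12 = 0.5, loading = 0.7, seed = 41)
  L <- fx$params$true_loadings
  Phi <- fx$params$factor_corr
  Sigma <- L %*% Phi %*% t(L)
  diag(Sigma) <- 1
  S <- cov(as.matrix(as.data.frame(fx$table)[, rownames(L)]))
  se_ij <- sqrt((outer(diag(Sigma), diag(Sigma)) + Sigma^2) / n)
  expect_true(all(abs(S - Sigma) < 3.5 * se_ij))
})

test_that("MCAR injection is seeded, item-only and calibrated", {
  fx <- make_two_factor_table(2000, seed = 51)
  t0 <- inject_missingness(fx$table, 0, seed = 1)
  expect_identical(t0, fx$table)

  t1 <- inject_missingness(fx$table, 0.2, seed = 2)
  t2 <- inject_missingness(fx$table, 0.2, seed = 2)
  expect_identical(t1, t2)
  items <- attr(fx$table, "items")
  frac <- mean(is.na(as.matrix(as.data.frame(t1)[, items])))
  se <- sqrt(0.2 * 0.8 / (2000 * length(items)))
  expect_lt(abs(frac - 0.2), 3 * se)
  expect_false(anyNA(t1$age))
  expect_false(anyNA(t1$IID))
  expect_error(inject_missingness(fx$table, 1), "rate")
})

test_that("genotype PCs have unit variance and align with the GRM eigenspace", {
  geno <- simulate_genotypes(300, 400, seed = 61)
  P <- compute_genotype_pcs(geno, k = 5)
  expect_equal(dim(P), c(300L, 5L))
  expect_equal(unname(apply(P, 2, var)), rep(1, 5), tolerance = 1e-8)
})
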