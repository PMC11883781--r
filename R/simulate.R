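#' Simulate independent biallelic genotypes
#'
#' Draws per-SNP allele frequencies from `Uniform(maf_range)` and hard-call
#' dosages from `Binomial(2, p)` under Hardy-Weinberg equilibrium, with SNPs
#' independent (no linkage disequilibrium). Monomorphic SNPs are redrawn so
#' the output contains none.
#'
#' @param n number of individuals (>= 2).
#' @param m number of SNPs (>= 1).
#' @param maf_range length-2 numeric within (0, 0.5], frequency bounds for
#'   the counted allele.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return A [genotype_matrix].
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5), seed = NULL) {
  if (n < 2 || m < 1) stop("need n >= 2 and m >= 1")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(m, maf_range[1], maf_range[2])
  X <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  repeat {
    mono <- which(matrixStats_colVars(X) == 0)
    if (length(mono) == 0) break
    p[mono] <- stats::runif(length(mono), maf_range[1], maf_range[2])
    X[, mono] <- stats::rbinom(n * length(mono), 2L,
                               rep(p[mono], each = n))
  }
  geno <- genotype_matrix(X)
  attr(geno, "generative_freq") <- p
  geno
}

# column variances without extra copies (no matrixStats dependency)
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  (colSums(X^2) - n * colMeans(X)^2) / (n - 1)
}

#' Generative parameters for the synthetic COPING-style data
#'
#' Bundles every knob of the generator: the latent phenotypic structure
#' (loadings and factor correlations), the genetic architecture acting on the
#' latent factors (per-latent SNP heritability, genetic correlations, causal
#' fraction), the measurement layer (binary suicidality items via a liability
#' threshold, covariate effects), and missingness.
#'
#' Defaults follow the study conditions the pipeline is designed around: six
#' indicators (three eating-disorder symptom scores, three suicidality items)
#' with loadings 0.7 on two factors correlated at 0.5, per-latent SNP
#' heritability 0.09 and genetic correlation 0.71 between the latent genetic
#' components.
#'
#' @param n individuals.
#' @param m SNPs.
#' @param maf_range allele-frequency bounds, within (0, 0.5].
#' @param causal_fraction fraction of SNPs with nonzero effects (the causal
#'   subset is shared across latent genetic components).
#' @param latent_structure one of `"two_factor"`, `"hierarchical"`,
#'   `"residual"`, `"four_factor"`.
#' @param true_loadings optional p x k loadings matrix with indicator
#'   rownames; a structure-specific default is built when `NULL`.
#' @param factor_corr optional k x k phenotypic factor correlation matrix;
#'   `NULL` means environmental components independent across latents (the
#'   factor correlation then equals the genetically induced one). Defaults
#'   per structure (e.g. 0.5 between the two factors).
#' @param h2_per_latent per-latent SNP heritability, in `[0, 1]`.
#' @param genetic_corr k x k genetic correlation matrix among the latent
#'   genetic components.
#' @param taf_prevalence per-item endorsement probability for the three
#'   binary suicidality items, or `NULL` to keep them continuous.
#' @param with_psychopathology add continuous PHQ-8 and GAD-7 sum-score
#'   indicators loading on the last latent factor.
#' @param covariate_effects named numeric vector of additive effects of
#'   `age` (per standardized year), `sex` and `batch` on every indicator.
#' @param missing_rate MCAR missingness fraction applied to item columns.
#' @param seed master RNG seed; stage-specific seeds are derived from it.
#' @return An object of class `generative_params`.
#' @export
generative_params <- function(n = 2000, m = 5000,
                              maf_range = c(0.05, 0.5),
                              causal_fraction = 1,
                              latent_structure = c("two_factor",
                                                   "hierarchical",
                                                   "residual",
                                                   "four_factor"),
                              true_loadings = NULL,
                              factor_corr = NULL,
                              h2_per_latent = NULL,
                              genetic_corr = NULL,
                              taf_prevalence = NULL,
                              with_psychopathology = FALSE,
                              covariate_effects = NULL,
                              missing_rate = 0,
                              seed = 1L) {
  latent_structure <- match.arg(latent_structure)
  def <- default_structure(latent_structure, with_psychopathology)
  if (is.null(true_loadings)) true_loadings <- def$loadings
  k <- ncol(true_loadings)
  if (missing(factor_corr)) factor_corr <- def$phi
  if (is.null(h2_per_latent)) h2_per_latent <- rep(0.09, k)
  if (length(h2_per_latent) == 1) h2_per_latent <- rep(h2_per_latent, k)
  if (is.null(genetic_corr)) {
    genetic_corr <- matrix(0.71, k, k)
    diag(genetic_corr) <- 1
  }
  if (any(h2_per_latent < 0 | h2_per_latent > 1)) {
    stop("h2_per_latent must lie in [0, 1]")
  }
  check_corr_matrix(genetic_corr, "genetic_corr")
  if (!is.null(factor_corr)) check_corr_matrix(factor_corr, "factor_corr")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  obj <- list(
    n = n, m = m, maf_range = maf_range,
    causal_fraction = causal_fraction,
    latent_structure = latent_structure,
    true_loadings = true_loadings,
    factor_corr = factor_corr,
    h2_per_latent = h2_per_latent,
    genetic_corr = genetic_corr,
    taf_prevalence = taf_prevalence,
    with_psychopathology = with_psychopathology,
    covariate_effects = covariate_effects,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  class(obj) <- "generative_params"
  obj
}

check_corr_matrix <- function(R, name) {
  if (!isSymmetric(unname(R), tol = 1e-8) || any(abs(diag(R) - 1) > 1e-8)) {
    stop(name, " must be symmetric with unit diagonal")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop(name, " must be positive semidefinite")
  invisible(TRUE)
}

indicator_names <- function(with_psychopathology = FALSE) {
  base <- c("AN_score", "BN_score", "BED_score", "TAF1", "TAF2", "TAF3")
  if (with_psychopathology) c(base, "PHQ8", "GAD7") else base
}

# Default loadings/factor-correlation per generative structure.
default_structure <- function(structure, with_psychopathology = FALSE) {
  ind <- indicator_names(with_psychopathology)
  p <- length(ind)
  if (structure %in% c("two_factor", "hierarchical")) {
    k <- 2
    L <- matrix(0, p, k, dimnames = list(ind, c("ED", "SI")))
    L[1:3, 1] <- 0.7
    L[4:6, 2] <- 0.7
    if (with_psychopathology) L[7:8, 2] <- 0.7
    phi <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
    # hierarchical: two first-order factors sharing a second-order loading
    # gamma = 0.7, hence factor correlation gamma^2
    if (structure == "hierarchical") phi[1, 2] <- phi[2, 1] <- 0.49
  } else if (structure == "residual") {
    k <- 3
    L <- matrix(0, p, k, dimnames = list(ind, c("G", "sED", "sSI")))
    # heterogeneous loadings: with equal loadings per block the bifactor,
    # hierarchical and correlated-factors structures are covariance-
    # equivalent (compound-symmetric blocks) and cannot be distinguished
    L[1:6, 1] <- c(0.65, 0.50, 0.55, 0.45, 0.60, 0.50)
    L[1:3, 2] <- c(0.35, 0.55, 0.45)
    L[4:6, 3] <- c(0.55, 0.35, 0.45)
    if (with_psychopathology) L[7:8, 1] <- 0.6
    phi <- diag(k)
  } else {
    k <- 4
    L <- matrix(0, p, k,
                dimnames = list(ind, c("restricting", "purging",
                                       "bingeing", "SI")))
    L[1, 1] <- 0.9
    L[2, 2] <- 0.9
    L[3, 3] <- 0.9
    L[4:6, 4] <- 0.7
    if (with_psychopathology) L[7:8, 4] <- 0.7
    phi <- matrix(0.5, k, k)
    diag(phi) <- 1
  }
  list(loadings = L, phi = phi)
}

#' Simulate latent genetic and environmental factor values
#'
#' For each latent genetic component, draws per-SNP additive effects for the
#' causal subset from a multivariate normal across latents with correlation
#' `genetic_corr`, forms genetic values from standardized genotypes, and
#' rescales them so the realized genetic variance equals `h2_per_latent`
#' exactly. Environmental components are drawn multivariate normal with the
#' covariance required for the total factor correlation to equal
#' `factor_corr` (or independent across latents when `factor_corr` is
#' `NULL`), scaled so each latent has total variance 1.
#'
#' @param geno a [genotype_matrix], or `NULL` for a purely phenotypic
#'   simulation (requires all heritabilities zero).
#' @param params a [generative_params] object.
#' @return An object of class `latent_truth` with `genetic_values`,
#'   `env_values`, `factor_values` (all n x k), `causal_effects` (m x k, on
#'   the standardized-genotype scale) and `factor_cov` (the expected latent
#'   covariance used downstream).
#' @export
simulate_latent_structure <- function(geno, params) {
  stopifnot(inherits(params, "generative_params"))
  L <- params$true_loadings
  k <- ncol(L)
  h2 <- params$h2_per_latent
  set.seed(params$seed + 1L)
  if (is.null(geno)) {
    if (any(h2 > 0)) {
      stop("geno = NULL requires h2_per_latent = 0 for every latent")
    }
    n <- params$n
    G <- matrix(0, n, k)
    eff <- NULL
  } else {
    X <- geno$dosages
    n <- nrow(X)
    m <- ncol(X)
    p <- geno$allele_freq
    Z <- sweep(X, 2, 2 * p, "-")
    Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
    if (anyNA(Z)) Z[is.na(Z)] <- 0
    m_c <- max(1L, ceiling(params$causal_fraction * m))
    causal <- sort(sample.int(m, m_c))
    B <- matrix(stats::rnorm(m_c * k), m_c, k) %*%
      chol(params$genetic_corr)
    G <- Z[, causal, drop = FALSE] %*% B
    scl <- numeric(k)
    for (j in seq_len(k)) {
      vj <- stats::var(G[, j])
      scl[j] <- if (h2[j] > 0 && vj > 0) sqrt(h2[j] / vj) else 0
      G[, j] <- G[, j] * scl[j]
    }
    eff <- matrix(0, m, k)
    eff[causal, ] <- sweep(B, 2, scl, "*")
  }
  # environmental covariance implied by the requested total factor
  # correlation and the genetic architecture
  Hs <- sqrt(h2)
  gen_cov <- params$genetic_corr * tcrossprod(Hs)
  if (is.null(params$factor_corr)) {
    env_cov <- diag(1 - h2, k)
    fac_cov <- gen_cov
    diag(fac_cov) <- 1
  } else {
    env_cov <- params$factor_corr - gen_cov
    diag(env_cov) <- 1 - h2
    fac_cov <- params$factor_corr
  }
  ev <- eigen(env_cov, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop("factor_corr is not attainable: environmental covariance not PSD")
  }
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k) %*% t(ev$vectors)
  E <- matrix(stats::rnorm(n * k), n, k) %*% rt
  for (j in seq_len(k)) {
    target <- 1 - h2[j]
    vj <- stats::var(E[, j])
    if (target > 0 && vj > 0) E[, j] <- E[, j] * sqrt(target / vj)
    else E[, j] <- 0
  }
  colnames(G) <- colnames(E) <- colnames(L)
  obj <- list(
    genetic_values = G,
    env_values = E,
    factor_values = G + E,
    causal_effects = eff,
    factor_cov = fac_cov,
    params = params
  )
  class(obj) <- "latent_truth"
  obj
}

#' Generate observed item-level phenotypes from latent truth
#'
#' Continuous indicators are formed as `y = Lambda f + e` with residual
#' variance `1 - communality`, so every indicator has unit total variance.
#' The three suicidality (TAF) items are optionally dichotomized by
#' thresholding their continuous liability at the quantile implied by
#' `taf_prevalence`. Covariate effects, when requested, are added to every
#' indicator so that residualization has signal to remove.
#'
#' @param truth a `latent_truth` from [simulate_latent_structure].
#' @param params the same [generative_params] used to create `truth`.
#' @return A `phenotype_table`: a data.frame with `FID`, `IID`, one column
#'   per indicator, and covariate columns `age`, `sex`, `batch`; column roles
#'   are recorded in attributes `items` and `covariates`.
#' @export
generate_observed_items <- function(truth, params) {
  stopifnot(inherits(truth, "latent_truth"))
  L <- params$true_loadings
  p <- nrow(L)
  n <- nrow(truth$factor_values)
  set.seed(params$seed + 2L)
  communality <- diag(L %*% truth$factor_cov %*% t(L))
  if (any(communality > 1 + 1e-10)) {
    stop("communality exceeds 1 for indicator(s): ",
         paste(rownames(L)[communality > 1 + 1e-10], collapse = ", "))
  }
  res_sd <- sqrt(pmax(1 - communality, 0))
  Y <- truth$factor_values %*% t(L) +
    matrix(stats::rnorm(n * p), n, p) %*% diag(res_sd, p)
  colnames(Y) <- rownames(L)
  # binary suicidality items via liability threshold
  if (!is.null(params$taf_prevalence)) {
    taf_cols <- grep("^TAF", colnames(Y))
    prev <- rep_len(params$taf_prevalence, length(taf_cols))
    for (i in seq_along(taf_cols)) {
      thr <- stats::quantile(Y[, taf_cols[i]], probs = 1 - prev[i])
      Y[, taf_cols[i]] <- as.numeric(Y[, taf_cols[i]] > thr)
    }
  }
  age <- stats::rnorm(n, 49.3, 17.56)
  sex <- stats::rbinom(n, 1, 0.71)
  batch <- stats::rbinom(n, 1, 0.5)
  if (!is.null(params$covariate_effects)) {
    ce <- params$covariate_effects
    shift <- 0
    if (!is.na(ce["age"])) shift <- shift + ce[["age"]] * scale(age)[, 1]
    if (!is.na(ce["sex"])) shift <- shift + ce[["sex"]] * sex
    if (!is.na(ce["batch"])) shift <- shift + ce[["batch"]] * batch
    Y <- Y + shift
  }
  tab <- data.frame(
    FID = paste0("F", seq_len(n)),
    IID = paste0("I", seq_len(n)),
    Y,
    age = age, sex = sex, batch = batch,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  as_phenotype_table(tab, items = colnames(Y),
                     covariates = c("age", "sex", "batch"))
}

#' Mark a data.frame as a phenotype table
#'
#' @param df data.frame with `FID` and `IID` columns.
#' @param items character vector of measurement column names (eligible for
#'   missingness injection and residualization).
#' @param covariates character vector of covariate column names.
#' @return `df` with class `phenotype_table` and role attributes.
#' @export
as_phenotype_table <- function(df, items, covariates = character(0)) {
  stopifnot(all(c("FID", "IID") %in% names(df)),
            all(items %in% names(df)),
            all(covariates %in% names(df)))
  attr(df, "items") <- items
  attr(df, "covariates") <- covariates
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Inject missing-completely-at-random missingness
#'
#' Applies an MCAR mask to the measurement (item) columns only; identifiers
#' and covariates are never masked.
#'
#' @param table a `phenotype_table`.
#' @param rate missing fraction in `[0, 1)`.
#' @param seed integer RNG seed (same seed, same mask).
#' @return The table with `NA`s injected.
#' @export
inject_missingness <- function(table, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(table)
  if (!is.null(seed)) set.seed(seed)
  items <- attr(table, "items")
  n <- nrow(table)
  mask <- matrix(stats::runif(n * length(items)) < rate, n, length(items))
  for (j in seq_along(items)) {
    table[[items[j]]][mask[, j]] <- NA
  }
  table
}

#' Principal components of the standardized genotype matrix
#'
#' Top eigenvectors of the genotype covariance among individuals (i.e. of
#' the GRM), scaled to unit variance; the synthetic analogue of ancestry
#' principal components.
#'
#' @param geno a [genotype_matrix].
#' @param k number of components (default 10).
#' @return n x k matrix with columns `PC1..PCk`.
#' @export
compute_genotype_pcs <- function(geno, k = 10) {
  A <- compute_grm(geno, maf_min = 0, max_missing = 1)$matrix
  es <- eigen(A, symmetric = TRUE)
  pcs <- es$vectors[, seq_len(k), drop = FALSE]
  pcs <- scale(pcs)
  colnames(pcs) <- paste0("PC", seq_len(k))
  pcs
}

#' Simulate a complete COPING-style dataset
#'
#' Runs the whole generator: genotypes, latent structure, observed items,
#' covariates (with genotype-derived ancestry PCs), and MCAR missingness.
#'
#' @param params a [generative_params].
#' @param pcs number of genotype principal components to attach (0 for
#'   none).
#' @return A list with `geno`, `truth`, and `table` (phenotype table with
#'   covariates and PCs).
#' @export
simulate_coping_dataset <- function(params, pcs = 10) {
  geno <- if (any(params$h2_per_latent > 0) || pcs > 0) {
    simulate_genotypes(params$n, params$m, params$maf_range,
                       seed = params$seed)
  } else {
    NULL
  }
  truth <- simulate_latent_structure(geno, params)
  tab <- generate_observed_items(truth, params)
  if (pcs > 0 && !is.null(geno)) {
    P <- compute_genotype_pcs(geno, k = pcs)
    for (j in seq_len(ncol(P))) tab[[colnames(P)[j]]] <- P[, j]
    attr(tab, "covariates") <- c(attr(tab, "covariates"), colnames(P))
  }
  if (params$missing_rate > 0) {
    tab <- inject_missingness(tab, params$missing_rate,
                              seed = params$seed + 3L)
  }
  list(geno = geno, truth = truth, table = tab)
}
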