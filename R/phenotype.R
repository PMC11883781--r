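#' Define symptom-score construction
#'
#' A mapping from score name to the ordered list of item columns that are
#' summed to form it. Item lists may overlap (disjointness is not required).
#'
#' @param ... named character vectors, e.g.
#'   `symptom_score_spec(AN_score = c("an1","an2"), BN_score = c("bn1"))`.
#' @return An object of class `symptom_score_spec`.
#' @export
symptom_score_spec <- function(...) {
  mapping <- list(...)
  if (length(mapping) == 0 || is.null(names(mapping)) ||
      any(names(mapping) == "")) {
    stop("all score sets must be named")
  }
  if (any(lengths(mapping) == 0)) stop("item lists must be non-empty")
  structure(mapping, class = "symptom_score_spec")
}

#' Build summed symptom scores from item responses
#'
#' Each score is the row-sum of its items; higher scores indicate more, or
#' more severe, symptoms. Under the default strict rule a row with any
#' missing item yields a missing score; under proration the mean of the
#' observed items is multiplied by the item count (requires at least one
#' observed item).
#'
#' @param table a `phenotype_table` (or plain data.frame) holding the item
#'   columns.
#' @param spec a [symptom_score_spec].
#' @param prorate logical; prorate partially observed item sets instead of
#'   setting the score missing.
#' @return The table with one appended (or replaced) column per score; score
#'   columns are added to the table's item roles.
#' @export
build_symptom_scores <- function(table, spec, prorate = FALSE) {
  stopifnot(inherits(spec, "symptom_score_spec"))
  for (score in names(spec)) {
    items <- spec[[score]]
    missing_cols <- setdiff(items, names(table))
    if (length(missing_cols) > 0) {
      stop("unknown item column(s): ", paste(missing_cols, collapse = ", "))
    }
    M <- as.matrix(table[, items, drop = FALSE])
    if (prorate) {
      n_obs <- rowSums(!is.na(M))
      s <- rowMeans(M, na.rm = TRUE) * length(items)
      s[n_obs == 0] <- NA_real_
    } else {
      s <- rowSums(M)   # NA if any item missing
    }
    table[[score]] <- s
  }
  if (inherits(table, "phenotype_table")) {
    attr(table, "items") <- union(attr(table, "items"), names(spec))
  }
  table
}

#' Residualize analysis variables on covariates
#'
#' Replaces each analysis variable by its OLS residual from a regression on
#' an intercept plus the named covariates. Rows with a missing covariate are
#' excluded from fitting and get a missing residual (these rows are flagged
#' in the `dropped_covariate_rows` attribute). Residuals have mean zero and
#' zero sample correlation with every covariate among the fitted rows.
#' Residualizing twice on the same covariates is a no-op.
#'
#' @param table a `phenotype_table` (or data.frame).
#' @param covariate_names character vector of covariate columns; factors or
#'   characters are expanded to dummies.
#' @param variables which columns to residualize; defaults to the table's
#'   item roles, or all non-ID, non-covariate numeric columns.
#' @return The table with the chosen columns replaced by residuals.
#' @export
residualize <- function(table, covariate_names, variables = NULL) {
  if (is.null(variables)) {
    variables <- attr(table, "items")
    if (is.null(variables)) {
      variables <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                           c("FID", "IID", covariate_names))
    }
  }
  missing_cov <- setdiff(covariate_names, names(table))
  if (length(missing_cov) > 0) {
    stop("unknown covariate column(s): ",
         paste(missing_cov, collapse = ", "))
  }
  fml <- stats::as.formula(
    paste("~", paste(covariate_names, collapse = " + "))
  )
  mf <- stats::model.frame(fml, data = table, na.action = stats::na.pass)
  X <- stats::model.matrix(fml, mf)
  cov_ok <- stats::complete.cases(table[, covariate_names, drop = FALSE])
  qr_x <- qr(X[cov_ok, , drop = FALSE])
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("covariate design is rank-deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  Xf <- X[cov_ok, , drop = FALSE]
  for (v in variables) {
    y <- table[[v]]
    res <- rep(NA_real_, nrow(table))
    yf <- y[cov_ok]
    obs <- !is.na(yf)
    if (sum(obs) > ncol(X)) {
      fit <- stats::lm.fit(Xf[obs, , drop = FALSE], yf[obs])
      res_f <- rep(NA_real_, length(yf))
      res_f[obs] <- fit$residuals
      res[cov_ok] <- res_f
    }
    table[[v]] <- res
  }
  attr(table, "dropped_covariate_rows") <- which(!cov_ok)
  table
}

#' @export
`[.phenotype_table` <- function(x, i, j, drop = FALSE) {
  items <- attr(x, "items")
  covs <- attr(x, "covariates")
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "items") <- intersect(items, names(out))
    attr(out, "covariates") <- intersect(covs, names(out))
    class(out) <- c("phenotype_table", "data.frame")
  }
  out
}

#' Split a sample into training and holdout parts
#'
#' Simple random, seeded, disjoint and exhaustive partition; the training
#' part has `round(n * train_fraction)` rows.
#'
#' @param table a `phenotype_table` (or data.frame).
#' @param train_fraction fraction in (0, 1) allocated to the first part.
#' @param seed integer RNG seed.
#' @return A list with elements `train` and `test`.
#' @export
split_sample <- function(table, train_fraction, seed = NULL) {
  n <- nrow(table)
  if (n < 2) stop("need at least 2 rows to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  n_train <- round(n * train_fraction)
  idx <- sample.int(n, n_train)
  list(
    train = table[sort(idx), , drop = FALSE],
    test = table[-sort(idx), , drop = FALSE]
  )
}
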