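#' Rank-inverse normal transformation
#'
#' Maps values monotonically to normal scores via
#' \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))} where \eqn{r} is the rank (Blom
#' offset). Ties receive the average rank, so tied inputs map to the same
#' normal score.
#'
#' @param x Numeric vector, length at least 3, no missing values.
#' @return Numeric vector of normal scores, same length and order as `x`.
#' @examples
#' rint(c(3, 1, 4, 1, 5))
#' @export
rint <- function(x) {
  if (anyNA(x)) stop("rint: input contains missing values", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("rint: need at least 3 values, got ", n, call. = FALSE)
  if (length(unique(x)) == 1L) {
    stop("rint: all values identical; ranks carry no ordering information",
         call. = FALSE)
  }
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Standardize a vector to mean 0, sd 1
#'
#' Uses the sample standard deviation (denominator n - 1).
#'
#' @param x Numeric vector.
#' @return Standardized vector.
#' @export
standardize <- function(x) {
  if (anyNA(x)) stop("standardize: input contains missing values", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("standardize: zero variance; cannot scale to unit sd", call. = FALSE)
  }
  (x - mean(x)) / s
}

# Build a full-rank design matrix from a covariate table, treating character /
# factor / logical columns (sex, centre, ...) as factors. Errors name the
# offending columns on rank deficiency.
build_design <- function(covariates, covariate_names) {
  missing_cols <- setdiff(covariate_names, names(covariates))
  if (length(missing_cols) > 0) {
    stop("covariate column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- covariates[covariate_names]
  for (nm in covariate_names) {
    if (anyNA(df[[nm]])) {
      stop("covariate '", nm, "' has missing values", call. = FALSE)
    }
    if (is.character(df[[nm]]) || is.logical(df[[nm]])) {
      df[[nm]] <- factor(df[[nm]])
    }
  }
  X <- stats::model.matrix(~., data = df)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  X
}

#' Residualise, transform, and standardize a phenotype or score
#'
#' Computes ordinary-least-squares residuals of `values` on an intercept plus
#' the requested covariates, optionally applies the rank-inverse normal
#' transformation ([rint()]), and scales the result to mean 0, sd 1 (sample
#' sd). This is the adjustment applied both to measured phenotypes (age, sex,
#' assessment centre, medication) and to raw polygenic scores (leading
#' principal components) before any classification.
#'
#' @param values Numeric vector, one entry per individual.
#' @param covariates Data frame of covariates aligned row-wise with `values`,
#'   or `NULL` for no adjustment (intercept only).
#' @param covariate_names Character vector of columns of `covariates` to
#'   adjust for. Character/factor columns are expanded to dummy variables.
#' @param transform `"none"` or `"rint"`; with `"rint"` the residuals are
#'   rank-inverse normalised before the final standardisation
#'   (residualise, then RINT, then standardize).
#' @return Standardized numeric vector, same order as `values`.
#' @export
adjust_and_standardize <- function(values, covariates = NULL,
                                   covariate_names = character(),
                                   transform = c("none", "rint")) {
  transform <- match.arg(transform)
  if (anyNA(values)) stop("values contain missing entries", call. = FALSE)
  n <- length(values)
  if (is.null(covariates) || length(covariate_names) == 0) {
    res <- values - mean(values)
  } else {
    if (nrow(covariates) != n) {
      stop("covariate table has ", nrow(covariates), " rows but ", n,
           " values", call. = FALSE)
    }
    X <- build_design(covariates, covariate_names)
    if (n < ncol(X) + 2) {
      stop("insufficient data: n = ", n, " with ", ncol(X),
           " design columns", call. = FALSE)
    }
    fit <- stats::lm.fit(X, values)
    res <- fit$residuals
  }
  if (stats::sd(res) < 1e-10 * max(stats::sd(values), 1)) {
    stop("residuals have (numerically) zero variance: values are fully ",
         "explained by the covariates", call. = FALSE)
  }
  if (transform == "rint") res <- rint(res)
  standardize(res)
}
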