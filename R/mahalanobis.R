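#' Construct a Mahalanobis model directly
#'
#' @param center Length-2 numeric vector: means of (ps_z, pheno_z).
#' @param covariance 2x2 symmetric positive-definite covariance matrix.
#' @return A `mahalanobis_model`.
#' @export
mahalanobis_model <- function(center, covariance) {
  stopifnot(length(center) == 2, all(dim(covariance) == c(2, 2)))
  if (abs(covariance[1, 2] - covariance[2, 1]) > 1e-10) {
    stop("covariance must be symmetric", call. = FALSE)
  }
  if (det(covariance) <= 1e-12) {
    stop("covariance is singular (|correlation| = 1); Mahalanobis distances ",
         "are undefined", call. = FALSE)
  }
  structure(list(center = as.numeric(center), covariance = covariance),
            class = "mahalanobis_model")
}

#' Fit the Mahalanobis model from a simulated null cohort
#'
#' The model is calibrated on simulation, not on the observed cohort: the
#' center is the component means and the covariance the sample covariance
#' (denominator n - 1) of the simulated standardized (score, phenotype)
#' pairs. With standardized inputs the diagonal is ~1 and the off-diagonal
#' estimates the score-phenotype correlation \eqn{\sqrt{r^2}}.
#'
#' @param sim_pairs A [standardized_pairs()] table from a null simulation
#'   (>= 3 rows).
#' @return A `mahalanobis_model`.
#' @export
fit_mahalanobis <- function(sim_pairs) {
  x <- cbind(sim_pairs$ps_z, sim_pairs$pheno_z)
  if (nrow(x) < 3) stop("need at least 3 simulated pairs", call. = FALSE)
  mahalanobis_model(colMeans(x), stats::cov(x))
}

#' Squared Mahalanobis distances and chi-squared p-values
#'
#' \eqn{D^2_i = (x_i - \mu)^\top \Sigma^{-1} (x_i - \mu)} for each
#' standardized (score, phenotype) pair, converted to the upper tail of the
#' chi-squared distribution with 2 degrees of freedom -- under bivariate
#' normality this tail probability equals \eqn{\exp(-D^2/2)}.
#'
#' @param pairs A [standardized_pairs()] table.
#' @param model A `mahalanobis_model` (see [fit_mahalanobis()]).
#' @return Data frame: `individual_id`, `d2`, `p`.
#' @export
mahalanobis_pvalues <- function(pairs, model) {
  stopifnot(inherits(model, "mahalanobis_model"))
  x <- cbind(pairs$ps_z, pairs$pheno_z)
  bad <- which(!is.finite(x[, 1]) | !is.finite(x[, 2]))
  if (length(bad) > 0) {
    stop("non-finite pair values for individual(s): ",
         paste(utils::head(pairs$individual_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  centered <- sweep(x, 2, model$center)
  s <- model$covariance
  inv_det <- 1 / (s[1, 1] * s[2, 2] - s[1, 2]^2)
  # explicit 2x2 quadratic form
  d2 <- inv_det * (s[2, 2] * centered[, 1]^2 -
                     2 * s[1, 2] * centered[, 1] * centered[, 2] +
                     s[1, 1] * centered[, 2]^2)
  data.frame(individual_id = pairs$individual_id,
             d2 = d2,
             p = stats::pchisq(d2, df = 2, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}
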