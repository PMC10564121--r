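#' Compute raw polygenic scores
#'
#' For each individual \eqn{i}, \eqn{PS_i = \sum_j \beta_j G_{ij}} where
#' \eqn{G_{ij}} is the dosage of the effect allele (0-2) and \eqn{\beta_j}
#' the per-allele effect. Variants present in the dosage matrix but absent
#' from the weight table are ignored; missing dosages are imputed to the
#' per-variant mean dosage (or rejected in strict mode).
#'
#' @param dosages Numeric matrix (individuals x variants) with dimnames, as
#'   from [read_dosages()].
#' @param weights A `weight_table` (see [read_weights()]).
#' @param on_missing_variant What to do when a weight variant is absent from
#'   the dosage matrix: `"error"` (default) or `"skip"` (warn and drop it).
#' @param na_action `"impute"` (per-variant mean, default) or `"error"`.
#' @return Named numeric vector of raw scores, in dosage-matrix row order.
#' @export
compute_polygenic_score <- function(dosages, weights,
                                    on_missing_variant = c("error", "skip"),
                                    na_action = c("impute", "error")) {
  on_missing_variant <- match.arg(on_missing_variant)
  na_action <- match.arg(na_action)
  weights <- as_weight_table(as.data.frame(weights))
  absent <- setdiff(weights$variant_id, colnames(dosages))
  if (length(absent) > 0) {
    if (on_missing_variant == "error") {
      stop("weight variant(s) absent from dosage matrix: ",
           paste(utils::head(absent, 10), collapse = ", "),
           if (length(absent) > 10) sprintf(" (and %d more)", length(absent) - 10),
           call. = FALSE)
    }
    warning(length(absent), " weight variant(s) absent from dosage matrix; skipped")
    weights <- weights[!weights$variant_id %in% absent, , drop = FALSE]
  }
  if (nrow(weights) == 0) stop("no usable weight variants", call. = FALSE)
  G <- dosages[, weights$variant_id, drop = FALSE]
  if (anyNA(G)) {
    if (na_action == "error") {
      stop("missing dosages present and na_action = 'error'", call. = FALSE)
    }
    for (j in which(colSums(is.na(G)) > 0)) {
      mu <- mean(G[, j], na.rm = TRUE)
      if (is.nan(mu)) stop("variant ", colnames(G)[j], " entirely missing",
                           call. = FALSE)
      G[is.na(G[, j]), j] <- mu
    }
  }
  drop(G %*% weights$beta)
}

#' Build the standardized (score, phenotype) pair table
#'
#' The object every classifier consumes: one row per individual with the
#' standardized polygenic score `ps_z` and standardized adjusted phenotype
#' `pheno_z`, both mean 0 / sd 1 over the cohort.
#'
#' @param individual_id Character vector of unique ids.
#' @param ps_z,pheno_z Standardized numeric vectors.
#' @return A `standardized_pairs` data frame.
#' @export
standardized_pairs <- function(individual_id, ps_z, pheno_z) {
  stopifnot(length(individual_id) == length(ps_z),
            length(ps_z) == length(pheno_z))
  if (anyDuplicated(individual_id)) {
    stop("individual ids must be unique", call. = FALSE)
  }
  for (v in list(ps_z = ps_z, pheno_z = pheno_z)) {
    if (anyNA(v)) stop("standardized pairs contain missing values", call. = FALSE)
  }
  check_z <- function(x, nm) {
    if (abs(mean(x)) > 1e-8 || abs(stats::sd(x) - 1) > 1e-8) {
      stop(nm, " is not standardized (mean ", signif(mean(x), 3), ", sd ",
           signif(stats::sd(x), 4), ")", call. = FALSE)
    }
  }
  check_z(ps_z, "ps_z")
  check_z(pheno_z, "pheno_z")
  structure(data.frame(individual_id = as.character(individual_id),
                       ps_z = ps_z, pheno_z = pheno_z,
                       stringsAsFactors = FALSE),
            class = c("standardized_pairs", "data.frame"))
}

#' Join raw tables into a standardized pair table
#'
#' Joins dosage, weight and covariate tables on `individual_id`, computes the
#' polygenic score, adjusts the score for the requested score covariates
#' (e.g. principal components) and the phenotype for its covariates, and
#' standardizes both. Individuals absent from any required table are dropped;
#' the number dropped is attached as attribute `n_dropped` and logged.
#'
#' @param dosages Dosage matrix.
#' @param weights Weight table.
#' @param covariates Covariate/phenotype data frame with `individual_id`.
#' @param phenotype Name of the phenotype column in `covariates`.
#' @param pheno_covariates,score_covariates Character vectors of covariate
#'   columns used to adjust the phenotype and the score respectively.
#' @param pheno_transform `"none"` or `"rint"` for the phenotype adjustment.
#' @return A `standardized_pairs` data frame (attribute `n_dropped`).
#' @export
build_pairs <- function(dosages, weights, covariates, phenotype,
                        pheno_covariates = character(),
                        score_covariates = character(),
                        pheno_transform = c("none", "rint")) {
  pheno_transform <- match.arg(pheno_transform)
  ids <- intersect(rownames(dosages), covariates$individual_id)
  n_dropped <- (nrow(dosages) - length(ids)) +
    (nrow(covariates) - length(ids))
  if (length(ids) == 0) stop("no individuals shared across tables", call. = FALSE)
  if (n_dropped > 0) {
    message(n_dropped, " individual record(s) dropped: absent from a required table")
  }
  cov <- covariates[match(ids, covariates$individual_id), , drop = FALSE]
  raw_ps <- compute_polygenic_score(dosages[ids, , drop = FALSE], weights)
  ps_z <- adjust_and_standardize(raw_ps, cov, score_covariates)
  pheno_z <- adjust_and_standardize(cov[[phenotype]], cov, pheno_covariates,
                                    transform = pheno_transform)
  out <- standardized_pairs(ids, ps_z, pheno_z)
  attr(out, "n_dropped") <- n_dropped
  out
}
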