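# One-row result container shared by the three enrichment estimators.
enrichment_result <- function(estimate_type, estimate, ci_low, ci_high, p,
                              n_deviator, n_aligned, covariates, model,
                              converged = TRUE) {
  structure(data.frame(estimate_type = estimate_type, estimate = estimate,
                       ci_low = ci_low, ci_high = ci_high, p = p,
                       n_deviator = n_deviator, n_aligned = n_aligned,
                       covariates = paste(covariates, collapse = ","),
                       model = model, converged = converged,
                       stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"))
}

#' Odds ratio of a binary trait in deviators versus the aligned group
#'
#' The contingency table counts trait-positive ("exposed") and
#' trait-negative individuals among deviators (a, b) and among the aligned
#' comparison group (c, d). The odds ratio is the cross-product ad/bc; when
#' any cell is zero the Haldane-Anscombe correction adds 0.5 to every cell
#' so the estimate and its Wald interval stay finite. The p-value comes from
#' the chosen model: a logistic-regression Wald test or Fisher's exact test.
#'
#' @param a,b Trait-positive / trait-negative deviator counts.
#' @param c,d Trait-positive / trait-negative aligned counts.
#' @param method `"logistic"` (default) or `"fisher_exact"`.
#' @param estimate `"cross_product"` (ad/bc, default) or
#'   `"conditional_mle"` (Fisher's conditional estimate).
#' @return An `enrichment_result` row with the OR, Wald 95% CI and p.
#' @export
binary_enrichment <- function(a, b, c, d,
                              method = c("logistic", "fisher_exact"),
                              estimate = c("cross_product", "conditional_mle")) {
  method <- match.arg(method)
  estimate <- match.arg(estimate)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (a + b == 0 || c + d == 0) {
    stop("empty group: both row totals must be positive", call. = FALSE)
  }
  corr <- if (any(cells == 0)) 0.5 else 0
  ac <- cells + corr
  or <- (ac[1] * ac[4]) / (ac[2] * ac[3])
  se <- sqrt(sum(1 / ac))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  tab <- matrix(cells, 2, byrow = TRUE)
  if (method == "fisher_exact") {
    ft <- stats::fisher.test(tab)
    p <- ft$p.value
    if (estimate == "conditional_mle") {
      or <- unname(ft$estimate)
      ci <- ft$conf.int
    }
  } else {
    # Wald test on the log cross-product (equivalent to the one-predictor
    # logistic-regression Wald z)
    p <- 2 * stats::pnorm(-abs(log(or) / se))
  }
  enrichment_result("odds_ratio", or, ci[1], ci[2], p,
                    n_deviator = a + b, n_aligned = c + d,
                    covariates = character(), model = method)
}

#' Build a contingency table from a call set and a binary trait
#'
#' @param calls A [callset()].
#' @param trait Named logical/0-1 vector keyed by individual id.
#' @param direction Which deviators to compare (`"both"`, `"low"`, `"high"`).
#' @return List with cells `a`, `b`, `c`, `d` (deviator exposed/unexposed,
#'   aligned exposed/unexposed).
#' @export
contingency_table <- function(calls, trait, direction = c("both", "low", "high")) {
  direction <- match.arg(direction)
  dev_ids <- deviators(calls, direction)
  ali_ids <- calls$calls$individual_id[calls$calls$status == "aligned"]
  tr <- function(ids) {
    v <- trait[ids]
    if (anyNA(v)) stop("trait missing for some individuals", call. = FALSE)
    as.logical(v)
  }
  dv <- tr(dev_ids); al <- tr(ali_ids)
  list(a = sum(dv), b = sum(!dv), c = sum(al), d = sum(!al))
}

#' Covariate-adjusted association of a continuous outcome with deviator
#' status
#'
#' Ordinary least squares of the (optionally rank-inverse normalised)
#' outcome on deviator status plus covariates; reports the status
#' coefficient with its Wald 95% CI. With `rint_outcome = TRUE` (default)
#' effect sizes are on the standard-deviation scale of the outcome.
#'
#' @param outcome Numeric outcome vector.
#' @param status 0/1 (or logical) deviator indicator, aligned individuals 0.
#' @param covariates Optional data frame of covariates (row-aligned).
#' @param covariate_names Columns of `covariates` to adjust for.
#' @param rint_outcome Rank-inverse normalise the outcome first.
#' @return An `enrichment_result` row (`estimate_type = "beta"`).
#' @export
continuous_enrichment <- function(outcome, status, covariates = NULL,
                                  covariate_names = character(),
                                  rint_outcome = TRUE) {
  status <- as.numeric(status)
  if (length(unique(status)) < 2) {
    stop("deviator status is constant; no contrast to estimate", call. = FALSE)
  }
  if (length(outcome) != length(status)) {
    stop("outcome and status lengths differ", call. = FALSE)
  }
  y <- if (rint_outcome) rint(outcome) else outcome
  df <- data.frame(.y = y, status = status)
  if (!is.null(covariates) && length(covariate_names) > 0) {
    build_design(covariates, covariate_names) # errors name collinear columns
    df <- cbind(df, covariates[covariate_names])
  }
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "),
         call. = FALSE)
  }
  df_res <- fit$df.residual
  if (df_res < 1) stop("insufficient residual degrees of freedom", call. = FALSE)
  beta <- unname(stats::coef(fit)["status"])
  sigma2 <- sum(stats::residuals(fit)^2) / df_res
  if (sigma2 < 1e-24) {
    # exact fit: zero residual variance, interval collapses to the point
    return(enrichment_result("beta", beta, beta, beta,
                             NA_real_, sum(status == 1), sum(status == 0),
                             covariate_names, "linear"))
  }
  co <- summary(fit)$coefficients
  se <- co["status", "Std. Error"]
  p <- co["status", "Pr(>|t|)"]
  ci <- beta + c(-1, 1) * stats::qt(0.975, df_res) * se
  enrichment_result("beta", beta, ci[1], ci[2], unname(p),
                    sum(status == 1), sum(status == 0),
                    covariate_names, "linear")
}

#' Covariate-adjusted disease risk of deviator status
#'
#' Logistic regression of a binary disease outcome on deviator status plus
#' covariates (typically including the measured phenotype, age and BMI);
#' reports `exp(coef)` on status with a Wald 95% CI. Complete separation or
#' non-convergence is flagged rather than reported as a spurious estimate.
#'
#' @param outcome Binary (0/1 or logical) disease indicator.
#' @param status 0/1 deviator indicator.
#' @param covariates Optional covariate data frame (row-aligned).
#' @param covariate_names Columns to adjust for.
#' @return An `enrichment_result` row (`estimate_type = "odds_ratio"`,
#'   `model = "logistic"`); `converged = FALSE` with `NA` estimate when the
#'   maximum-likelihood fit is unreliable.
#' @export
disease_risk <- function(outcome, status, covariates = NULL,
                         covariate_names = character()) {
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  status <- as.numeric(status)
  if (length(unique(status)) < 2) {
    stop("deviator status is constant", call. = FALSE)
  }
  df <- data.frame(.y = y, status = status)
  if (!is.null(covariates) && length(covariate_names) > 0) {
    df <- cbind(df, covariates[covariate_names])
  }
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial())
  )
  co <- summary(fit)$coefficients
  est <- co["status", "Estimate"]
  se <- co["status", "Std. Error"]
  separated <- !fit$converged || fit$boundary || se > 100 || abs(est) > 20
  if (separated) {
    return(enrichment_result("odds_ratio", NA_real_, NA_real_, NA_real_,
                             NA_real_, sum(status == 1), sum(status == 0),
                             covariate_names, "logistic", converged = FALSE))
  }
  ci <- exp(est + c(-1, 1) * stats::qnorm(0.975) * se)
  enrichment_result("odds_ratio", exp(est), ci[1], ci[2],
                    co["status", "Pr(>|z|)"],
                    sum(status == 1), sum(status == 0),
                    covariate_names, "logistic")
}
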