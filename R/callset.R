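#' Construct a call set
#'
#' A call set records one classification method's verdict for every
#' individual: `deviator_low` / `deviator_high` (phenotype improbably far
#' below / above the polygenic prediction), `aligned` (consistent with the
#' additive model, the enrichment comparison group), or `intermediate`.
#' The four statuses partition the cohort.
#'
#' @param method One of `"mahalanobis"`, `"residual"`, `"grs_rank"`,
#'   `"centile"`.
#' @param threshold_label Human-readable threshold, e.g. `"P<0.001"`.
#' @param calls Data frame with columns `individual_id`, `status`,
#'   `statistic`, `p` (NA where the method defines no p-value).
#' @return A `callset` object.
#' @export
callset <- function(method, threshold_label, calls) {
  method <- match.arg(method, c("mahalanobis", "residual", "grs_rank", "centile"))
  stopifnot(all(c("individual_id", "status", "statistic", "p") %in% names(calls)))
  ok <- c("deviator_low", "deviator_high", "aligned", "intermediate")
  if (!all(calls$status %in% ok)) {
    stop("invalid status value(s): ",
         paste(unique(setdiff(calls$status, ok)), collapse = ", "),
         call. = FALSE)
  }
  structure(list(method = method, threshold_label = threshold_label,
                 calls = calls),
            class = "callset")
}

#' @export
print.callset <- function(x, ...) {
  tab <- table(factor(x$calls$status,
                      c("deviator_low", "deviator_high", "aligned", "intermediate")))
  cat(sprintf("<callset> method=%s threshold=%s n=%d\n", x$method,
              x$threshold_label, nrow(x$calls)))
  cat(sprintf("  low=%d high=%d aligned=%d intermediate=%d\n",
              tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

#' Deviator ids of a call set
#'
#' @param x A `callset`.
#' @param direction `"both"`, `"low"` or `"high"`.
#' @return Character vector of individual ids.
#' @export
deviators <- function(x, direction = c("both", "low", "high")) {
  direction <- match.arg(direction)
  keep <- switch(direction,
                 both = c("deviator_low", "deviator_high"),
                 low = "deviator_low",
                 high = "deviator_high")
  x$calls$individual_id[x$calls$status %in% keep]
}

#' Write a call set to TSV
#'
#' Columns: individual_id, method, threshold_label, status, statistic, p.
#'
#' @param x A `callset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_callset <- function(x, path) {
  df <- data.frame(individual_id = x$calls$individual_id,
                   method = x$method,
                   threshold_label = x$threshold_label,
                   status = x$calls$status,
                   statistic = x$calls$statistic,
                   p = x$calls$p,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

# Shared standardized residuals from the score~phenotype regression.
# The default direction regresses the standardized score ON the standardized
# phenotype; z is the residual divided by its sample sd.
residual_z <- function(pairs,
                       direction = c("score_on_phenotype", "phenotype_on_score")) {
  direction <- match.arg(direction)
  if (direction == "score_on_phenotype") {
    fit <- stats::lm.fit(cbind(1, pairs$pheno_z), pairs$ps_z)
  } else {
    fit <- stats::lm.fit(cbind(1, pairs$ps_z), pairs$pheno_z)
  }
  r <- fit$residuals
  s <- stats::sd(r)
  if (!is.finite(s) || s < 1e-12) {
    stop("zero residual variance: score and phenotype are perfectly ",
         "correlated", call. = FALSE)
  }
  r / s
}

# Sign of each individual's phenotype deviation used for the direction
# split: the default rule uses the phenotype z itself (below the mean =>
# low); the residual rule uses the regression residual reoriented so that a
# phenotype below its score-implied value is negative. Exact zeros under the
# phenotype rule fall back to the residual sign (logged).
direction_sign <- function(pairs, z,
                           rule = c("phenotype", "residual"),
                           regression = c("score_on_phenotype",
                                          "phenotype_on_score")) {
  rule <- match.arg(rule)
  regression <- match.arg(regression)
  resid_sign <- if (regression == "score_on_phenotype") -z else z
  if (rule == "residual") return(resid_sign)
  s <- pairs$pheno_z
  tie <- s == 0
  if (any(tie)) {
    message(sum(tie), " individual(s) with phenotype exactly at the mean; ",
            "direction assigned by residual sign")
    s[tie] <- resid_sign[tie]
  }
  s
}

# Compose the final status vector from a deviator flag, the shared aligned
# rule (|z| < z_aligned) and a direction sign. Deviator status wins over
# aligned so the statuses partition the cohort.
compose_status <- function(is_dev, z, dir_sign, z_aligned = 1) {
  status <- rep("intermediate", length(is_dev))
  status[abs(z) < z_aligned] <- "aligned"
  status[is_dev & dir_sign < 0] <- "deviator_low"
  status[is_dev & dir_sign >= 0] <- "deviator_high"
  status
}
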