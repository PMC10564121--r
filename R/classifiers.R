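#' Classify deviators by Mahalanobis distance
#'
#' The primary method. An individual is a deviator when the chi-squared
#' p-value of their squared Mahalanobis distance falls below `alpha` AND
#' their standardized regression residual satisfies `|z| > z_dev` -- the
#' joint rule screens out individuals whose distance is large only because
#' both score and phenotype are extreme in a mutually consistent way.
#' Individuals with `|z| < z_aligned` form the aligned comparison group.
#'
#' @param pairs A [standardized_pairs()] table (the observed cohort).
#' @param model A `mahalanobis_model` fitted on an independent null
#'   simulation ([fit_mahalanobis()]).
#' @param alpha P-value threshold in (0, 1); the study default is 0.001, the
#'   stringent sensitivity threshold 0.05/n (see `bonferroni`).
#' @param bonferroni If `TRUE`, `alpha` is replaced by `0.05 / nrow(pairs)`
#'   and the threshold label becomes `"P<0.05/n"`.
#' @param z_dev Residual-z magnitude required of deviators (default 2).
#' @param z_aligned Residual-z magnitude defining the aligned group
#'   (default 1).
#' @param regression Direction of the shared residual regression; the
#'   default regresses the score on the phenotype.
#' @param direction_rule `"phenotype"` (split by the sign of `pheno_z`,
#'   default) or `"residual"`.
#' @return A [callset()]; `statistic` is the squared distance.
#' @export
classify_mahalanobis <- function(pairs, model, alpha = 0.001,
                                 bonferroni = FALSE,
                                 z_dev = 2, z_aligned = 1,
                                 regression = c("score_on_phenotype",
                                                "phenotype_on_score"),
                                 direction_rule = c("phenotype", "residual")) {
  regression <- match.arg(regression)
  direction_rule <- match.arg(direction_rule)
  if (bonferroni) {
    alpha <- 0.05 / nrow(pairs)
    label <- "P<0.05/n"
  } else {
    label <- paste0("P<", format(alpha))
  }
  if (!(alpha > 0 && alpha < 1)) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  mp <- mahalanobis_pvalues(pairs, model)
  z <- residual_z(pairs, regression)
  is_dev <- mp$p < alpha & abs(z) > z_dev
  status <- compose_status(is_dev, z,
                           direction_sign(pairs, z, direction_rule, regression),
                           z_aligned)
  callset("mahalanobis", label,
          data.frame(individual_id = pairs$individual_id, status = status,
                     statistic = mp$d2, p = mp$p, stringsAsFactors = FALSE))
}

#' Classify deviators by standardized regression residuals
#'
#' Standardized residuals z from regressing the polygenic score on the
#' phenotype (default direction); deviators have `|z| > k`, the aligned
#' group `|z| < z_aligned`. The two-sided normal tail probability of z is
#' reported as p.
#'
#' @inheritParams classify_mahalanobis
#' @param k Residual threshold, conventionally 2 or 3.
#' @return A [callset()]; `statistic` is z.
#' @export
classify_residual <- function(pairs, k = 2, z_aligned = 1,
                              regression = c("score_on_phenotype",
                                             "phenotype_on_score"),
                              direction_rule = c("phenotype", "residual")) {
  regression <- match.arg(regression)
  direction_rule <- match.arg(direction_rule)
  if (nrow(pairs) < 3) stop("need at least 3 pairs", call. = FALSE)
  z <- residual_z(pairs, regression)
  is_dev <- abs(z) > k
  status <- compose_status(is_dev, z,
                           direction_sign(pairs, z, direction_rule, regression),
                           z_aligned)
  callset("residual", paste0(">", k, "SD"),
          data.frame(individual_id = pairs$individual_id, status = status,
                     statistic = z, p = 2 * stats::pnorm(-abs(z)),
                     stringsAsFactors = FALSE))
}

#' Classify deviators by rank-matched empirical p-values
#'
#' Individuals are ranked by polygenic score (ties broken by a seeded random
#' permutation). For the observed phenotype y at score rank k, extremity is
#' measured as |y - med_k| about the per-rank null median med_k of the
#' [simulate_rank_null()] store; with r the number of the B replicates at
#' least as extreme, the empirical p-value is (r + 1)/(B + 1), whose minimum
#' attainable value is exactly 1/(B + 1). Direction is the sign of
#' y - med_k.
#'
#' @inheritParams classify_mahalanobis
#' @param null A `rank_null` store with `null$n == nrow(pairs)`.
#' @param alpha Empirical-p threshold (e.g. 0.001, or 1/10000 for the
#'   stringent label).
#' @param sided `"two"` (default: extremity about the per-rank median),
#'   `"lower"` or `"upper"` for one-sided extremity.
#' @param tie_seed Seed for the score-rank tie-break permutation.
#' @return A [callset()]; `statistic` is the extremity |y - med_k|.
#' @export
classify_grs_rank <- function(pairs, null, alpha = 0.001,
                              sided = c("two", "lower", "upper"),
                              z_aligned = 1, tie_seed = 1L,
                              regression = c("score_on_phenotype",
                                             "phenotype_on_score")) {
  sided <- match.arg(sided)
  regression <- match.arg(regression)
  n <- nrow(pairs)
  if (null$n != n) {
    stop("rank-null store built for n = ", null$n,
         " but cohort has n = ", n, call. = FALSE)
  }
  B <- null$B
  set.seed(tie_seed)
  ord <- order(pairs$ps_z, stats::runif(n))
  rank_of <- integer(n)
  rank_of[ord] <- seq_len(n)
  med <- apply(null$mat, 2, stats::median)
  y <- pairs$pheno_z
  med_i <- med[rank_of]
  delta <- y - med_i
  # count replicates at least as extreme, per rank, in column chunks
  r <- integer(n)
  chunk <- max(1L, as.integer(2^24 / B))
  for (start in seq(1L, n, by = chunk)) {
    cols <- start:min(start + chunk - 1L, n)
    dev <- sweep(null$mat[, cols, drop = FALSE], 2, med[cols])
    obs_idx <- ord[cols]
    e_obs <- delta[obs_idx]
    cmp <- switch(sided,
                  two = abs(dev) >= rep(abs(e_obs), each = B),
                  lower = dev <= rep(e_obs, each = B),
                  upper = dev >= rep(e_obs, each = B))
    r[obs_idx] <- colSums(cmp)
  }
  p <- (r + 1) / (B + 1)
  is_dev <- p < alpha
  z <- residual_z(pairs, regression)
  dir_sign <- delta
  dir_sign[dir_sign == 0] <- y[dir_sign == 0] # degenerate tie: phenotype sign
  status <- compose_status(is_dev, z, dir_sign, z_aligned)
  callset("grs_rank", paste0("P<", format(alpha)),
          data.frame(individual_id = pairs$individual_id, status = status,
                     statistic = abs(delta), p = p, stringsAsFactors = FALSE))
}

#' Per-centile Tukey fences of a call set
#'
#' @param x A `callset` from [classify_centile()].
#' @return Data frame of per-bin fences (attribute stored on the callset).
#' @export
centile_fences <- function(x) attr(x, "fences")

#' Classify deviators by Tukey fences within score centiles
#'
#' Non-parametric method: individuals are cut into `bins` equal-count bins
#' of the polygenic score; within each bin, phenotypic outliers lie outside
#' \[Q1 - k_iqr * IQR, Q3 + k_iqr * IQR\] where Q1 and Q3 are the within-bin
#' 25th and 75th phenotype centiles (linear interpolation between order
#' statistics). No distributional assumption is made about the phenotype.
#'
#' @inheritParams classify_mahalanobis
#' @param k_iqr Fence multiplier, conventionally 1.5 or 3.
#' @param bins Number of score bins (default 100, one per centile). A
#'   warning is issued when `nrow(pairs) < 4 * bins`.
#' @return A [callset()]; `statistic` is the fence exceedance (distance
#'   beyond the nearer fence; negative inside the fences), with the per-bin
#'   fence table attached as attribute `"fences"`.
#' @export
classify_centile <- function(pairs, k_iqr = 1.5, bins = 100, z_aligned = 1,
                             regression = c("score_on_phenotype",
                                            "phenotype_on_score")) {
  regression <- match.arg(regression)
  if (bins < 1) stop("bins must be >= 1", call. = FALSE)
  n <- nrow(pairs)
  if (n < bins * 4) {
    warning("fewer than 4 individuals per bin on average (n = ", n,
            ", bins = ", bins, "); fences will be unstable")
  }
  r <- rank(pairs$ps_z, ties.method = "first")
  bin <- pmin(bins, ceiling(bins * r / n))
  q <- tapply(pairs$pheno_z, bin, stats::quantile, probs = c(0.25, 0.75),
              type = 7, simplify = FALSE)
  fences <- data.frame(bin = as.integer(names(q)),
                       q1 = vapply(q, `[`, numeric(1), 1),
                       q3 = vapply(q, `[`, numeric(1), 2))
  fences$iqr <- fences$q3 - fences$q1
  fences$k <- k_iqr
  fences$lower <- fences$q1 - k_iqr * fences$iqr
  fences$upper <- fences$q3 + k_iqr * fences$iqr
  idx <- match(bin, fences$bin)
  below <- pairs$pheno_z < fences$lower[idx]
  above <- pairs$pheno_z > fences$upper[idx]
  exceed <- pmax(fences$lower[idx] - pairs$pheno_z,
                 pairs$pheno_z - fences$upper[idx])
  z <- residual_z(pairs, regression)
  # the fence side fixes the direction for this method
  dir_sign <- ifelse(below, -1, 1)
  status <- compose_status(below | above, z, dir_sign, z_aligned)
  out <- callset("centile", paste0("Q", k_iqr, "IQR"),
                 data.frame(individual_id = pairs$individual_id,
                            status = status, statistic = exceed,
                            p = NA_real_, stringsAsFactors = FALSE))
  attr(out, "fences") <- fences
  out
}

#' Re-split deviator direction of an existing call set
#'
#' Relabels each deviator as `deviator_low` or `deviator_high` according to
#' the chosen rule: `"phenotype"` (below/above the phenotype mean, the study
#' rule) or `"residual"` (sign of the regression residual). Non-deviator
#' statuses are untouched.
#'
#' @param calls A [callset()].
#' @param pairs The [standardized_pairs()] the calls were computed on.
#' @inheritParams classify_mahalanobis
#' @return The relabelled `callset`.
#' @export
split_direction <- function(calls, pairs,
                            direction_rule = c("phenotype", "residual"),
                            regression = c("score_on_phenotype",
                                           "phenotype_on_score")) {
  direction_rule <- match.arg(direction_rule)
  regression <- match.arg(regression)
  stopifnot(identical(calls$calls$individual_id, pairs$individual_id))
  z <- residual_z(pairs, regression)
  s <- direction_sign(pairs, z, direction_rule, regression)
  is_dev <- calls$calls$status %in% c("deviator_low", "deviator_high")
  calls$calls$status[is_dev] <- ifelse(s[is_dev] < 0,
                                       "deviator_low", "deviator_high")
  calls
}

#' Pairwise percentage overlap of deviator calls
#'
#' For each ordered pair of call sets and each direction,
#' `100 * |A intersect B| / |A|` -- the percentage of method A's deviators
#' also flagged by method B (0 when A flags no one, logged).
#'
#' @param callsets Named list of [callset()] objects on the same cohort.
#' @return List with matrices `low` and `high`; rows index A, columns B.
#' @export
method_overlap <- function(callsets) {
  stopifnot(length(callsets) >= 1)
  ids <- lapply(callsets, function(x) sort(x$calls$individual_id))
  if (!all(vapply(ids, identical, logical(1), ids[[1]]))) {
    stop("call sets cover different cohorts", call. = FALSE)
  }
  nms <- names(callsets)
  if (is.null(nms)) {
    nms <- vapply(callsets, function(x)
      paste(x$method, x$threshold_label), character(1))
  }
  one <- function(direction) {
    sets <- lapply(callsets, deviators, direction = direction)
    k <- length(sets)
    m <- matrix(0, k, k, dimnames = list(nms, nms))
    for (i in seq_len(k)) {
      if (length(sets[[i]]) == 0) {
        message("no ", direction, " deviators for '", nms[i],
                "'; overlap row reported as 0")
        next
      }
      for (j in seq_len(k)) {
        m[i, j] <- 100 * length(intersect(sets[[i]], sets[[j]])) /
          length(sets[[i]])
      }
    }
    m
  }
  list(low = one("low"), high = one("high"))
}
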