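#' Simulation configuration for the additive polygenic model
#'
#' @param n Number of individuals (>= 2).
#' @param m Number of variants (>= 1).
#' @param target_r2 Fraction of phenotypic variance explained by the score,
#'   in (0, 1). The study phenotypes this emulates explained 0.316 (height)
#'   and 0.167 (LDL-C) of variance.
#' @param maf Either an explicit length-`m` frequency vector in (0, 0.5], or
#'   a length-2 range within (0.01, 0.5) to draw uniformly from.
#' @param beta Either an explicit length-`m` effect vector or `NULL` for
#'   standard-normal draws.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @param B Number of replicate cohorts for the rank-matched null store.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n, m = 500, target_r2 = 0.316,
                       maf = c(0.01, 0.5), beta = NULL,
                       seed = 1L, B = 1L) {
  if (!(target_r2 > 0 && target_r2 < 1)) {
    stop("target_r2 must lie strictly in (0, 1)", call. = FALSE)
  }
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (length(maf) == m && m != 2) {
    if (any(maf <= 0 | maf > 0.5)) {
      stop("explicit maf values must lie in (0, 0.5]", call. = FALSE)
    }
  } else if (length(maf) == 2) {
    if (maf[1] >= maf[2] || maf[1] < 0.01 || maf[2] > 0.5) {
      stop("maf range must be increasing and within (0.01, 0.5)", call. = FALSE)
    }
  } else {
    stop("maf must be a length-2 range or a length-m vector", call. = FALSE)
  }
  if (!is.null(beta) && length(beta) != m) {
    stop("explicit beta must have length m", call. = FALSE)
  }
  structure(list(n = as.integer(n), m = as.integer(m),
                 target_r2 = target_r2, maf = maf, beta = beta,
                 seed = as.integer(seed), B = as.integer(B)),
            class = "sim_config")
}

# Draw per-variant frequencies and effects for one cohort (RNG state is
# advanced; callers own set.seed).
draw_architecture <- function(config) {
  maf <- if (length(config$maf) == 2 && config$m != 2) {
    stats::runif(config$m, config$maf[1], config$maf[2])
  } else if (length(config$maf) == config$m) {
    config$maf
  } else {
    stats::runif(config$m, config$maf[1], config$maf[2])
  }
  beta <- if (is.null(config$beta)) stats::rnorm(config$m) else config$beta
  list(maf = maf, beta = beta)
}

# Core draw shared by the null and planted simulators. Returns raw
# (pre-standardisation) score and phenotype plus the dosage matrix.
draw_cohort <- function(config, mode = c("genotype", "fast")) {
  mode <- match.arg(mode)
  n <- config$n
  if (mode == "fast") {
    ps_raw <- stats::rnorm(n)
    dosages <- NULL
  } else {
    arch <- draw_architecture(config)
    dosages <- matrix(stats::rbinom(n * config$m, 2L,
                                    rep(arch$maf, each = n)),
                      nrow = n, ncol = config$m)
    rownames(dosages) <- paste0("ind_", seq_len(n))
    colnames(dosages) <- paste0("var_", seq_len(config$m))
    ps_raw <- drop(dosages %*% arch$beta)
  }
  ps_z <- standardize(ps_raw)
  eps <- stats::rnorm(n)
  pheno_raw <- sqrt(config$target_r2) * ps_z +
    sqrt(1 - config$target_r2) * eps
  list(dosages = dosages, ps_raw = ps_raw, ps_z = ps_z,
       pheno_raw = pheno_raw)
}

#' Simulate a null cohort under the additive polygenic model
#'
#' Dosages are drawn per variant as Binomial(2, f_j) under Hardy-Weinberg
#' equilibrium, the raw score is the weighted allele count, and the phenotype
#' is \eqn{\sqrt{r^2}\, z_{PS} + \sqrt{1 - r^2}\,\epsilon} with standard
#' normal environmental noise, so the score explains `target_r2` of
#' phenotypic variance in expectation. Both components are standardized.
#'
#' @param config A [sim_config()].
#' @param mode `"genotype"` simulates explicit dosages (default);
#'   `"fast"` draws the score directly from its implied normal distribution
#'   and carries no dosage matrix.
#' @return A `sim_cohort`: list with `pairs` ([standardized_pairs()]),
#'   `dosages` (or `NULL` in fast mode), and `realized_r2`, the squared
#'   score-phenotype correlation in this draw.
#' @export
simulate_null_cohort <- function(config, mode = c("genotype", "fast")) {
  mode <- match.arg(mode)
  set.seed(config$seed)
  d <- draw_cohort(config, mode)
  pheno_z <- standardize(d$pheno_raw)
  pairs <- standardized_pairs(paste0("ind_", seq_len(config$n)),
                              d$ps_z, pheno_z)
  structure(list(pairs = pairs, dosages = d$dosages,
                 realized_r2 = stats::cor(d$ps_z, pheno_z)^2,
                 config = config),
            class = "sim_cohort")
}

#' Simulate the rank-matched null store
#'
#' Simulates `config$B` independent cohorts; in each, individuals are ranked
#' by polygenic score (ties broken by a seeded random permutation) and the
#' standardized phenotypes are stored in score-rank order. The store is the
#' null reference for [classify_grs_rank()]: column k holds the B simulated
#' phenotypes observed at score rank k.
#'
#' @param config A [sim_config()] with `B >= 1`.
#' @param mode Simulation mode per replicate; `"fast"` (default here) draws
#'   (score, phenotype) from the implied bivariate normal, which is what
#'   makes B = 10,000 replicates tractable; `"genotype"` simulates dosages.
#' @param max_bytes Refuse to materialise a store larger than this many
#'   bytes (default 4 GiB); the error suggests reducing B or n.
#' @return A `rank_null` list: `n`, `B`, and `mat` (B x n matrix).
#' @export
simulate_rank_null <- function(config, mode = c("fast", "genotype"),
                               max_bytes = 4 * 1024^3) {
  mode <- match.arg(mode)
  need <- as.numeric(config$B) * config$n * 8
  if (need > max_bytes) {
    stop("rank-null store would need ", round(need / 1024^3, 1),
         " GiB; reduce B or n, or raise max_bytes", call. = FALSE)
  }
  set.seed(config$seed)
  mat <- matrix(NA_real_, nrow = config$B, ncol = config$n)
  for (b in seq_len(config$B)) {
    d <- draw_cohort(config, mode)
    pheno_z <- standardize(d$pheno_raw)
    ord <- order(d$ps_z, stats::runif(config$n))
    mat[b, ] <- pheno_z[ord]
  }
  structure(list(n = config$n, B = config$B, mat = mat, config = config),
            class = "rank_null")
}

#' Specification of planted deviators
#'
#' Describes individuals injected into a synthetic cohort whose phenotype is
#' shifted away from the additive-model expectation -- stand-ins for
#' large-effect variant carriers or strong environmental causes.
#'
#' @param n_low,n_high Counts of planted low-/high-phenotype deviators.
#' @param shift_sd Magnitude of the additive phenotype shift, in phenotype
#'   SD units (> 0).
#' @param skew If `TRUE`, a monotone exponential transform
#'   \eqn{x \mapsto \exp(\lambda x)} with \eqn{\lambda = 0.5} is applied to
#'   the phenotype before final standardisation, producing an LDL-C-like
#'   right skew.
#' @param sexed If `TRUE`, individuals are assigned a sex and the phenotype
#'   is built with sex-specific variance explained (`r2_male`, `r2_female`).
#' @param r2_male,r2_female Sex-specific variance explained (used only when
#'   `sexed = TRUE`; defaults mirror the LDL-C setting).
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(n_low = 0L, n_high = 0L, shift_sd = 4,
                       skew = FALSE, sexed = FALSE,
                       r2_male = 0.162, r2_female = 0.180) {
  if (n_low < 0 || n_high < 0) stop("plant counts must be >= 0", call. = FALSE)
  if ((n_low + n_high) > 0 && shift_sd <= 0) {
    stop("shift_sd must be > 0", call. = FALSE)
  }
  structure(list(n_low = as.integer(n_low), n_high = as.integer(n_high),
                 shift_sd = shift_sd, skew = isTRUE(skew),
                 sexed = isTRUE(sexed),
                 r2_male = r2_male, r2_female = r2_female),
            class = "plant_spec")
}

#' Generate a synthetic study cohort with planted deviators
#'
#' Draws a null cohort, then adds `-shift_sd` to the pre-standardisation
#' phenotype of `n_low` randomly chosen individuals and `+shift_sd` to
#' `n_high` others. With `skew`, the monotone exponential transform is
#' applied after planting and before standardisation. Truth labels record
#' which individuals were planted.
#'
#' @param config A [sim_config()].
#' @param plant A [plant_spec()].
#' @param mode Passed to the cohort draw (`"genotype"` or `"fast"`).
#' @param rint_pheno If `TRUE`, the phenotype is rank-inverse normalised
#'   before standardisation (the LDL-C-style adjustment); by default a
#'   skewed phenotype stays skewed so that non-parametric classifiers are
#'   exercised on non-normal data.
#' @return List with `cohort` (a `sim_cohort`, whose `covariates` element
#'   carries sex when `sexed`) and `truth` (data frame `individual_id`,
#'   `truth` in {null, planted_low, planted_high}).
#' @export
generate_synthetic_study <- function(config, plant = plant_spec(),
                                     mode = c("genotype", "fast"),
                                     rint_pheno = FALSE) {
  mode <- match.arg(mode)
  n <- config$n
  if (plant$n_low + plant$n_high > n) {
    stop("n_low + n_high exceeds cohort size", call. = FALSE)
  }
  set.seed(config$seed)
  if (plant$sexed) {
    # sex-specific coupling: rebuild the phenotype with per-sex sqrt(r2)
    d <- draw_cohort(config, mode)
    sex <- sample(c("male", "female"), n, replace = TRUE)
    r2_vec <- ifelse(sex == "male", plant$r2_male, plant$r2_female)
    eps <- stats::rnorm(n)
    pheno_raw <- sqrt(r2_vec) * d$ps_z + sqrt(1 - r2_vec) * eps
  } else {
    d <- draw_cohort(config, mode)
    sex <- NULL
    pheno_raw <- d$pheno_raw
  }
  truth <- rep("null", n)
  k <- plant$n_low + plant$n_high
  if (k > 0) {
    idx <- sample(n, k)
    low_idx <- idx[seq_len(plant$n_low)]
    high_idx <- idx[setdiff(seq_len(k), seq_len(plant$n_low))]
    pheno_raw[low_idx] <- pheno_raw[low_idx] - plant$shift_sd
    pheno_raw[high_idx] <- pheno_raw[high_idx] + plant$shift_sd
    truth[low_idx] <- "planted_low"
    truth[high_idx] <- "planted_high"
  }
  if (plant$skew) pheno_raw <- exp(0.5 * pheno_raw)
  ids <- paste0("ind_", seq_len(n))
  pheno_z <- standardize(if (rint_pheno) rint(pheno_raw) else pheno_raw)
  pairs <- standardized_pairs(ids, d$ps_z, pheno_z)
  cohort <- structure(list(pairs = pairs, dosages = d$dosages,
                           realized_r2 = stats::cor(d$ps_z, pheno_z)^2,
                           covariates = if (!is.null(sex)) {
                             data.frame(individual_id = ids, sex = sex,
                                        stringsAsFactors = FALSE)
                           },
                           config = config, plant = plant),
                      class = "sim_cohort")
  list(cohort = cohort,
       truth = data.frame(individual_id = ids, truth = truth,
                          stringsAsFactors = FALSE))
}
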