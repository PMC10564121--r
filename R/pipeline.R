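#' Deviator counts per call set
#'
#' @param callsets List of [callset()] objects.
#' @return Data frame: method, threshold_label, counts of each status, and
#'   the deviator percentages of the cohort.
#' @export
report_counts <- function(callsets) {
  stopifnot(length(callsets) >= 1)
  rows <- lapply(callsets, function(x) {
    tab <- table(factor(x$calls$status,
                        c("deviator_low", "deviator_high",
                          "aligned", "intermediate")))
    n <- nrow(x$calls)
    data.frame(method = x$method, threshold_label = x$threshold_label,
               n_low = as.integer(tab[1]), n_high = as.integer(tab[2]),
               n_aligned = as.integer(tab[3]),
               n_intermediate = as.integer(tab[4]),
               pct_low = round(100 * tab[[1]] / n, 2),
               pct_high = round(100 * tab[[2]] / n, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Derive independent per-stage seeds from the root seed, kept inside the
# 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * k) %% (2^31 - 1))
}

apply_method <- function(spec, pairs, model, null_store, regression,
                         direction_rule) {
  method <- spec$method
  if (method == "mahalanobis") {
    classify_mahalanobis(pairs, model,
                         alpha = spec$alpha %||% 0.001,
                         bonferroni = isTRUE(spec$bonferroni),
                         regression = regression,
                         direction_rule = direction_rule)
  } else if (method == "residual") {
    classify_residual(pairs, k = spec$k %||% 2, regression = regression,
                      direction_rule = direction_rule)
  } else if (method == "grs_rank") {
    classify_grs_rank(pairs, null_store, alpha = spec$alpha %||% 0.001,
                      regression = regression)
  } else if (method == "centile") {
    classify_centile(pairs, k_iqr = spec$k_iqr %||% 1.5,
                     bins = spec$bins %||% 100, regression = regression)
  } else {
    stop("unknown method '", method, "'", call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full deviation-classification pipeline
#'
#' Orchestrates score computation or synthetic-study generation,
#' simulation-based calibration, the requested classification methods,
#' cross-method overlap, deviator counts, and enrichment tests, writing all
#' result tables plus a manifest to `out_dir`. Deterministic given
#' `config$seed`: one root seed is expanded into logged per-stage seeds.
#'
#' @param config Pipeline configuration list (e.g. from
#'   [read_pipeline_config()] or built in code). Exactly one of
#'   `config$simulation` (a block with `n`, `m`, `target_r2`, `B`, optional
#'   `plant` and `mode`) or `config$inputs` (paths `weights`, `dosages`,
#'   `covariates`, plus `phenotype`, `pheno_covariates`, `score_covariates`,
#'   `pheno_transform`) must be present. `config$methods` is a list of
#'   method specs (`method` plus its thresholds); `config$seed`,
#'   `config$regression`, `config$direction_rule` and
#'   `config$sex_stratified` are optional.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `callsets`, `counts`, `overlap`,
#'   `enrichment`, `pairs`, `truth` and the paths written.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.null(config$simulation) == is.null(config$inputs)) {
    stop("config must contain exactly one of 'simulation' or 'inputs'",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  regression <- config$regression %||% "score_on_phenotype"
  direction_rule <- config$direction_rule %||% "phenotype"
  log_lines <- character()
  logf <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  truth <- NULL
  sex <- NULL
  if (!is.null(config$simulation)) {
    sb <- config$simulation
    cfg <- sim_config(n = sb$n, m = sb$m %||% 200,
                      target_r2 = sb$target_r2 %||% 0.316,
                      seed = child_seed(seed, 1), B = sb$B %||% 1000)
    pl <- do.call(plant_spec, sb$plant %||% list())
    study <- generate_synthetic_study(cfg, pl,
                                      mode = sb$mode %||% "genotype",
                                      rint_pheno = isTRUE(sb$rint_pheno))
    pairs <- study$cohort$pairs
    truth <- study$truth
    sex <- study$cohort$covariates$sex
    r2 <- study$cohort$realized_r2
    logf("simulated study: n=%d, m=%d, realized r2=%.4f, planted=%d",
         cfg$n, cfg$m, r2, pl$n_low + pl$n_high)
  } else {
    inp <- config$inputs
    weights <- read_weights(inp$weights)
    dosages <- read_dosages(inp$dosages)
    covars <- read_covariates(inp$covariates)
    pairs <- build_pairs(dosages, weights, covars, inp$phenotype,
                         pheno_covariates = inp$pheno_covariates %||% character(),
                         score_covariates = inp$score_covariates %||% character(),
                         pheno_transform = inp$pheno_transform %||% "none")
    logf("loaded cohort: n=%d analysed, %d dropped (missing from a table)",
         nrow(pairs), attr(pairs, "n_dropped"))
    if (!is.null(covars$sex)) sex <- covars$sex[match(pairs$individual_id,
                                                      covars$individual_id)]
    r2 <- stats::cor(pairs$ps_z, pairs$pheno_z)^2
    cfg <- sim_config(n = nrow(pairs), m = config$calibration_m %||% 500,
                      target_r2 = r2, seed = child_seed(seed, 1),
                      B = config$B %||% 1000)
  }

  strata <- if (isTRUE(config$sex_stratified)) {
    if (is.null(sex)) stop("sex_stratified requested but no sex available",
                           call. = FALSE)
    split(seq_len(nrow(pairs)), sex)
  } else {
    list(all = seq_len(nrow(pairs)))
  }

  all_callsets <- list()
  callsets_by_stratum <- list()
  enrich_rows <- list()
  for (stratum in names(strata)) {
    idx <- strata[[stratum]]
    sp <- if (length(strata) == 1) pairs else {
      standardized_pairs(pairs$individual_id[idx],
                         standardize(pairs$ps_z[idx]),
                         standardize(pairs$pheno_z[idx]))
    }
    # calibration on an independent null simulation matched on n and r2
    calib_cfg <- sim_config(n = nrow(sp), m = cfg$m,
                            target_r2 = stats::cor(sp$ps_z, sp$pheno_z)^2,
                            seed = child_seed(seed, 2 + match(stratum, names(strata))),
                            B = cfg$B)
    calib <- simulate_null_cohort(calib_cfg)
    model <- fit_mahalanobis(calib$pairs)
    logf("[%s] calibration covariance off-diagonal = %.4f", stratum,
         model$covariance[1, 2])
    needs_rank <- any(vapply(config$methods, function(m)
      m$method == "grs_rank", logical(1)))
    null_store <- if (needs_rank) {
      simulate_rank_null(sim_config(n = nrow(sp), m = cfg$m,
                                    target_r2 = calib_cfg$target_r2,
                                    seed = child_seed(seed, 17 + match(stratum, names(strata))),
                                    B = cfg$B),
                         mode = "fast")
    }
    callsets <- lapply(config$methods, apply_method, pairs = sp,
                       model = model, null_store = null_store,
                       regression = regression,
                       direction_rule = direction_rule)
    names(callsets) <- vapply(callsets, function(x)
      paste0(x$method, "_", x$threshold_label), character(1))
    if (length(strata) > 1) names(callsets) <- paste0(names(callsets), "_", stratum)
    for (nm in names(callsets)) {
      write_callset(callsets[[nm]], file.path(out_dir,
                                              paste0("calls_", gsub("[^A-Za-z0-9._-]", "_", nm), ".tsv")))
    }
    all_callsets <- c(all_callsets, callsets)
    callsets_by_stratum[[stratum]] <- callsets

    # enrichment of planted truth (synthetic) or configured binary traits
    if (!is.null(truth)) {
      set.seed(child_seed(seed, 29 + match(stratum, names(strata))))
      tr <- truth$truth[match(sp$individual_id, truth$individual_id)]
      planted <- tr != "null"
      trait <- stats::rbinom(nrow(sp), 1, ifelse(planted, 0.30, 0.02))
      names(trait) <- sp$individual_id
      for (nm in names(callsets)) {
        for (direction in c("low", "high")) {
          ids_dev <- deviators(callsets[[nm]], direction)
          if (length(ids_dev) == 0) next
          ct <- contingency_table(callsets[[nm]], trait, direction)
          res <- binary_enrichment(ct$a, ct$b, ct$c, ct$d)
          res$outcome <- "synthetic_binary_trait"
          res$group <- direction
          res$callset <- nm
          enrich_rows[[length(enrich_rows) + 1]] <- res
        }
      }
    }
  }

  counts <- report_counts(all_callsets)
  write_tsv(counts, file.path(out_dir, "counts.tsv"))
  overlap <- NULL
  for (stratum in names(callsets_by_stratum)) {
    cs_here <- callsets_by_stratum[[stratum]]
    if (length(cs_here) < 2) next
    ov <- method_overlap(cs_here)
    suffix <- if (length(callsets_by_stratum) > 1) paste0("_", stratum) else ""
    for (direction in c("low", "high")) {
      m <- ov[[direction]]
      df <- data.frame(method = rownames(m), round(m, 1),
                       check.names = FALSE, stringsAsFactors = FALSE)
      write_tsv(df, file.path(out_dir,
                              paste0("overlap_", direction, suffix, ".tsv")))
    }
    overlap[[stratum]] <- ov
  }
  if (length(callsets_by_stratum) == 1 && !is.null(overlap)) {
    overlap <- overlap[[1]]
  }
  enrichment <- if (length(enrich_rows) > 0) {
    do.call(rbind, c(enrich_rows, list(make.row.names = FALSE)))
  }
  if (!is.null(enrichment)) {
    write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("polydev")),
    seed = seed,
    methods = config$methods,
    regression = regression,
    direction_rule = direction_rule,
    input_checksums = if (!is.null(config$inputs)) {
      as.list(tools::md5sum(unlist(config$inputs[c("weights", "dosages",
                                                   "covariates")])))
    })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(callsets = all_callsets, counts = counts, overlap = overlap,
                 enrichment = enrichment, pairs = pairs, truth = truth,
                 out_dir = out_dir))
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file with the structure described in
#'   [run_pipeline()].
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  # YAML 1.1 would otherwise read the bare key `n:` as the boolean FALSE
  keep_n <- function(x) {
    if (x %in% c("n", "N", "y", "Y")) x else as.logical(toupper(x) %in%
                                                          c("TRUE", "YES", "ON"))
  }
  yaml::read_yaml(path, handlers = list("bool#yes" = keep_n,
                                        "bool#no" = keep_n))
}

#' Default demonstration configuration
#'
#' A synthetic study of 10,000 individuals with a height-like variance
#' explained (0.316) and 50 planted deviators, classified by all four
#' methods at their lenient and stringent thresholds.
#'
#' @param seed Root seed.
#' @param n Cohort size.
#' @param B Rank-null replicates (the stringent rank threshold is `1/B`).
#' @return Configuration list for [run_pipeline()].
#' @export
demo_config <- function(seed = 1L, n = 10000, B = 2000) {
  list(
    seed = seed,
    simulation = list(n = n, m = 200, target_r2 = 0.316, B = B,
                      plant = list(n_low = 25, n_high = 25, shift_sd = 4)),
    methods = list(
      list(method = "mahalanobis", alpha = 0.001),
      list(method = "mahalanobis", bonferroni = TRUE),
      list(method = "residual", k = 2),
      list(method = "residual", k = 3),
      list(method = "grs_rank", alpha = 0.001),
      list(method = "grs_rank", alpha = 1 / B),
      list(method = "centile", k_iqr = 1.5),
      list(method = "centile", k_iqr = 3)
    )
  )
}

#' Run the packaged synthetic demonstration study
#'
#' Generates the packaged synthetic cohort ([demo_config()]) and runs the
#' full pipeline on it.
#'
#' @param out_dir Output directory.
#' @param seed Root seed.
#' @param n Cohort size.
#' @param B Rank-null replicates.
#' @return The [run_pipeline()] result bundle, invisibly.
#' @export
run_demo <- function(out_dir, seed = 1L, n = 10000, B = 2000) {
  run_pipeline(demo_config(seed = seed, n = n, B = B), out_dir)
}

#' Scatter plot of a call set
#'
#' Score versus phenotype with deviators highlighted in red and the aligned
#' group in black, one panel per call set.
#'
#' @param x A [callset()].
#' @param pairs The [standardized_pairs()] the calls were computed on.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_callset <- function(x, pairs, ...) {
  stopifnot(identical(x$calls$individual_id, pairs$individual_id))
  dev <- x$calls$status %in% c("deviator_low", "deviator_high")
  graphics::plot(pairs$ps_z, pairs$pheno_z,
                 col = ifelse(dev, "red", grDevices::adjustcolor("black", 0.3)),
                 pch = 20, cex = ifelse(dev, 0.8, 0.3),
                 xlab = "standardized polygenic score",
                 ylab = "standardized phenotype",
                 main = paste(x$method, x$threshold_label), ...)
  invisible(NULL)
}
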