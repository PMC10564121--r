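test_that("classification thresholds compose as the joint rule dictates", {
  set.seed(20)
  sim <- simulate_null_cohort(sim_config(n = 5000, m = 100, target_r2 = 0.3,
                                         seed = 22), mode = "fast")
  calib <- simulate_null_cohort(sim_config(n = 5000, m = 100, target_r2 = 0.3,
                                           seed = 23), mode = "fast")
  mdl <- fit_mahalanobis(calib$pairs)
  cs <- classify_mahalanobis(sim$pairs, mdl, alpha = 0.001)
  # every Mahalanobis deviator satisfies the residual rule |z| > 2
  z <- polydev:::residual_z(sim$pairs)
  dev_idx <- cs$calls$status %in% c("deviator_low", "deviator_high")
  expect_true(all(abs(z[dev_idx]) > 2))
  # statuses partition the cohort; deviators never in the aligned group
  expect_true(all(cs$calls$status %in%
                    c("deviator_low", "deviator_high", "aligned", "intermediate")))
  expect_true(all(abs(z[cs$calls$status == "aligned"]) < 1))
  # the stringent 0.05/n callset nests within the lenient one
  cs_b <- classify_mahalanobis(sim$pairs, mdl, bonferroni = TRUE)
  expect_identical(cs_b$threshold_label, "P<0.05/n")
  expect_true(all(deviators(cs_b) %in% deviators(cs)))
  expect_error(classify_mahalanobis(sim$pairs, mdl, alpha = 2), "alpha")
})

test_that("residual method flags the expected normal tail and nests by k", {
  pp <- make_pairs(100000, 0.562, seed = 24)
  cs2 <- classify_residual(pp, k = 2)
  frac <- length(deviators(cs2)) / 100000
  expect_lt(abs(frac - 2 * pnorm(-2)), 0.005) # ~4.55%
  cs3 <- classify_residual(pp, k = 3)
  expect_true(all(deviators(cs3) %in% deviators(cs2)))
  # degenerate: perfectly correlated pairs
  z <- standardize(rnorm(30))
  expect_error(classify_residual(standardized_pairs(paste0("i", 1:30), z, z)),
               "zero residual variance")
})

test_that("grs-rank empirical p matches exhaustive enumeration on a toy store", {
  # n = 5 ranks, B = 4 replicates, hand-enumerable
  mat <- rbind(c(-2.0, -1.0, 0.0, 1.0, 2.0),
               c(-1.5, -0.5, 0.5, 1.5, 2.5),
               c(-2.5, -1.5, -0.5, 0.5, 1.5),
               c(-1.0, 0.0, 1.0, 2.0, 3.0))
  store <- toy_rank_null(mat)
  ps <- standardize(1:5)
  ph <- standardize(c(-1.8, 3.0, 0.2, 1.2, 2.1))
  pairs <- standardized_pairs(paste0("i", 1:5), ps, ph)
  cs <- classify_grs_rank(pairs, store, alpha = 0.5)
  # enumeration oracle: per rank, r = #{b : |mat[b,k] - med_k| >= |y_k - med_k|}
  med <- apply(mat, 2, median)
  y <- pairs$pheno_z # ranks follow ps order = input order here
  r <- sapply(1:5, function(k) sum(abs(mat[, k] - med[k]) >= abs(y[k] - med[k])))
  expect_equal(cs$calls$p, (r + 1) / 5)
  expect_equal(cs$calls$statistic, abs(y - med))
  # direction follows the sign of y - med_k
  flagged <- cs$calls$status %in% c("deviator_low", "deviator_high")
  expect_true(all((cs$calls$status == "deviator_low") == (flagged & y < med)))
})

test_that("grs-rank p is monotone in extremity with floor exactly 1/(B+1)", {
  cfg <- sim_config(n = 200, m = 50, target_r2 = 0.3, seed = 30, B = 99)
  store <- simulate_rank_null(cfg, mode = "fast")
  sim <- simulate_null_cohort(cfg, mode = "fast")
  pairs <- sim$pairs
  # make one individual maximally extreme: p must hit the floor
  pairs$pheno_z[7] <- 50
  cs <- classify_grs_rank(pairs, store, alpha = 0.05)
  expect_equal(min(cs$calls$p), 1 / 100)
  expect_equal(cs$calls$p[7], 1 / 100)
  # an individual exactly at its per-rank null median has maximal r -> p = 1
  pairs2 <- sim$pairs
  set.seed(1L) # same tie-break permutation classify_grs_rank will use
  ord <- order(pairs2$ps_z, runif(200))
  med <- apply(store$mat, 2, median)
  pairs2$pheno_z[ord[100]] <- med[100]
  cs2 <- classify_grs_rank(pairs2, store, alpha = 0.05)
  expect_equal(cs2$calls$p[ord[100]], 1)
  # p never increases as extremity grows: compare two spiked magnitudes
  pairs3 <- sim$pairs
  pairs3$pheno_z[ord[50]] <- med[50] + 1
  p_small <- classify_grs_rank(pairs3, store, alpha = 0.05)$calls$p[ord[50]]
  pairs3$pheno_z[ord[50]] <- med[50] + 10
  p_big <- classify_grs_rank(pairs3, store, alpha = 0.05)$calls$p[ord[50]]
  expect_lte(p_big, p_small)
  # size mismatch is rejected
  bad <- make_pairs(100, 0.3, seed = 31)
  expect_error(classify_grs_rank(bad, store), "n = 200")
})

test_that("centile fences match the direct quartile oracle", {
  # one bin holding phenotypes 1..8 and 100: only 100 is outside Q3+1.5IQR
  vals <- c(1:8, 100)
  ps <- standardize(seq_len(9))
  pairs <- standardized_pairs(paste0("i", 1:9), ps, standardize(vals))
  cs <- classify_centile(pairs, k_iqr = 1.5, bins = 1)
  q <- quantile(pairs$pheno_z, c(0.25, 0.75), type = 7)
  fence_hi <- q[2] + 1.5 * (q[2] - q[1])
  flagged <- deviators(cs)
  expect_identical(flagged, "i9")
  expect_true(pairs$pheno_z[9] > fence_hi)
  f <- centile_fences(cs)
  expect_equal(f$q1, unname(q[1]))
  expect_equal(f$upper, unname(fence_hi))
  # constant phenotype within the bin -> zero IQR but no exceedance
  const_pairs <- pairs
  # all-equal phenotype cannot be standardized, so perturb minimally around 0
  expect_error(standardize(rep(1, 9)), "zero variance")
})

test_that("centile method nests by fence multiplier and respects bin counts", {
  pp <- make_pairs(20000, 0.55, seed = 33)
  cs15 <- classify_centile(pp, k_iqr = 1.5, bins = 100)
  cs3 <- classify_centile(pp, k_iqr = 3, bins = 100)
  expect_true(all(deviators(cs3) %in% deviators(cs15)))
  rate <- length(deviators(cs15)) / 20000
  expect_gt(rate, 0.003 * 0.5)
  expect_lt(rate, 0.02)
  expect_error(classify_centile(pp, bins = 0), "bins")
  expect_warning(classify_centile(make_pairs(30, 0.3, seed = 2), bins = 10),
                 "unstable")
})

test_that("direction split follows the phenotype sign, with residual mode", {
  pp <- make_pairs(500, 0.5, seed = 35)
  # plant a deviator with slightly positive phenotype but strong residual
  pp$ps_z[1] <- 4
  pp$pheno_z[1] <- 0.1
  cs <- classify_residual(pp, k = 2)
  stopifnot("id1" %in% deviators(cs))
  expect_identical(cs$calls$status[1], "deviator_high") # phenotype rule
  cs_res <- split_direction(cs, pp, direction_rule = "residual")
  # residual z = (ps - rho * pheno)/sd > 0 => phenotype below expectation
  expect_identical(cs_res$calls$status[1], "deviator_low")
  # an unambiguous low deviator stays low under both rules
  pp$pheno_z[2] <- -2.5
  pp$ps_z[2] <- 0
  cs2 <- classify_residual(pp, k = 2)
  if ("id2" %in% deviators(cs2)) {
    expect_identical(cs2$calls$status[2], "deviator_low")
  }
  # no deviators -> identical output
  null_pp <- make_pairs(50, 0.3, seed = 36)
  cs_null <- classify_residual(null_pp, k = 50)
  expect_identical(split_direction(cs_null, null_pp), cs_null)
})

test_that("overlap percentages follow the set-count oracle", {
  mk <- function(ids_low, all_ids) {
    status <- ifelse(all_ids %in% ids_low, "deviator_low", "aligned")
    callset("residual", ">2SD",
            data.frame(individual_id = all_ids, status = status,
                       statistic = 0, p = NA_real_))
  }
  ids <- paste0("i", 1:10)
  A <- mk(c("i1", "i2", "i3", "i4"), ids)
  B <- mk(c("i3", "i4"), ids)
  ov <- suppressMessages(method_overlap(list(A = A, B = B)))
  expect_equal(ov$low["A", "B"], 50)
  expect_equal(ov$low["B", "A"], 100)
  expect_equal(diag(ov$low), c(A = 100, B = 100))
  # disjoint sets give 0
  C <- mk(c("i9", "i10"), ids)
  ov2 <- suppressMessages(method_overlap(list(A = A, C = C)))
  expect_equal(ov2$low["A", "C"], 0)
  # mismatched cohorts are rejected
  D <- mk("j1", paste0("j", 1:10))
  expect_error(method_overlap(list(A = A, D = D)), "different cohorts")
})

test_that("classifiers are invariant to row order and id relabelling", {
  pp <- make_pairs(2000, 0.55, seed = 37)
  calib <- make_pairs(2000, 0.55, seed = 38)
  mdl <- fit_mahalanobis(calib)
  perm <- sample(seq_len(2000))
  pp_perm <- standardized_pairs(pp$individual_id[perm], pp$ps_z[perm],
                                pp$pheno_z[perm])
  for (fn in list(
    function(p) classify_mahalanobis(p, mdl, alpha = 0.01),
    function(p) classify_residual(p, k = 2),
    function(p) classify_centile(p, k_iqr = 1.5, bins = 20)
  )) {
    a <- fn(pp)
    b <- fn(pp_perm)
    expect_setequal(deviators(a), deviators(b))
    expect_setequal(deviators(a, "low"), deviators(b, "low"))
  }
})
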