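test_that("identical seeds give bit-identical cohorts; different seeds differ", {
  cfg <- sim_config(n = 500, m = 50, target_r2 = 0.3, seed = 42)
  a <- simulate_null_cohort(cfg)
  b <- simulate_null_cohort(cfg)
  expect_identical(a, b)
  c <- simulate_null_cohort(sim_config(n = 500, m = 50, target_r2 = 0.3,
                                       seed = 43))
  expect_false(identical(a$pairs$pheno_z, c$pairs$pheno_z))
})

test_that("realized variance explained matches the squared-correlation oracle", {
  cfg <- sim_config(n = 50000, m = 500, target_r2 = 0.316, seed = 9)
  sim <- simulate_null_cohort(cfg)
  # independent oracle: regression R^2 of phenotype on score
  r2_oracle <- summary(lm(sim$pairs$pheno_z ~ sim$pairs$ps_z))$r.squared
  expect_equal(sim$realized_r2, r2_oracle, tolerance = 1e-10)
  expect_lt(abs(sim$realized_r2 - 0.316), 0.02)
  # slope of phenotype on score ~ sqrt(target_r2)
  slope <- coef(lm(sim$pairs$pheno_z ~ sim$pairs$ps_z))[2]
  expect_lt(abs(slope - sqrt(0.316)), 0.02)
})

test_that("score and phenotype decouple in the target_r2 -> 0 limit", {
  cfg <- sim_config(n = 10000, m = 100, target_r2 = 1e-6, seed = 4)
  sim <- simulate_null_cohort(cfg, mode = "fast")
  expect_lt(abs(cor(sim$pairs$ps_z, sim$pairs$pheno_z)), 0.05)
})

test_that("dosage frequencies match the requested maf within binomial error", {
  m <- 40
  maf <- seq(0.05, 0.45, length.out = m)
  cfg <- sim_config(n = 5000, m = m, target_r2 = 0.3, maf = maf, seed = 8)
  sim <- simulate_null_cohort(cfg)
  freq <- colMeans(sim$dosages) / 2
  se <- sqrt(maf * (1 - maf) / (2 * 5000))
  expect_true(all(abs(freq - maf) < 5 * se))
})

test_that("null phenotype marginal is standard normal (KS)", {
  cfg <- sim_config(n = 10000, m = 200, target_r2 = 0.316, seed = 12)
  sim <- simulate_null_cohort(cfg)
  expect_gt(ks.test(sim$pairs$pheno_z, "pnorm")$p.value, 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n = 100, target_r2 = 0), "target_r2")
  expect_error(sim_config(n = 100, target_r2 = 1), "target_r2")
  expect_error(sim_config(n = 1), "n must")
  expect_error(sim_config(n = 100, m = 3, maf = c(0.2, 0.3, 0.6)), "maf")
  expect_error(sim_config(n = 100, maf = c(0.5, 0.1)), "maf")
})

test_that("single-replicate rank null equals the cohort ordered by score rank", {
  cfg <- sim_config(n = 50, m = 30, target_r2 = 0.4, seed = 6, B = 1)
  store <- simulate_rank_null(cfg, mode = "genotype")
  expect_equal(dim(store$mat), c(1, 50))
  # rebuild the same cohort: same seed, same draw sequence
  set.seed(cfg$seed)
  d <- polydev:::draw_cohort(cfg, "genotype")
  pheno_z <- standardize(d$pheno_raw)
  ord <- order(d$ps_z, runif(50))
  expect_equal(store$mat[1, ], unname(pheno_z[ord]))
  # each row is a permutation of a standardized cohort
  expect_equal(mean(store$mat[1, ]), 0, tolerance = 1e-10)
})

test_that("per-rank null means increase with score rank on average", {
  cfg <- sim_config(n = 100, m = 50, target_r2 = 0.4, seed = 13, B = 200)
  store <- simulate_rank_null(cfg, mode = "fast")
  per_rank_mean <- colMeans(store$mat)
  # rank-correlation oracle: positive coupling implies an increasing trend
  expect_gt(cor(per_rank_mean, seq_len(100), method = "spearman"), 0.9)
})

test_that("rank-null memory cap triggers a helpful error", {
  cfg <- sim_config(n = 1000, m = 10, target_r2 = 0.3, seed = 1, B = 1000)
  expect_error(simulate_rank_null(cfg, max_bytes = 1e6), "reduce B or n")
})

test_that("planting shifts the chosen individuals and only them", {
  cfg <- sim_config(n = 20000, m = 100, target_r2 = 0.32, seed = 10)
  st <- generate_synthetic_study(cfg, plant_spec(50, 50, shift_sd = 4),
                                 mode = "fast")
  expect_equal(sum(st$truth$truth == "planted_low"), 50)
  expect_equal(sum(st$truth$truth == "planted_high"), 50)
  ph <- st$cohort$pairs$pheno_z
  low <- st$truth$truth == "planted_low"
  high <- st$truth$truth == "planted_high"
  expect_lt(mean(ph[low]), -3)   # group-mean oracle
  expect_gt(mean(ph[high]), 3)
  expect_lt(abs(mean(ph[st$truth$truth == "null"])), 0.1)
})

test_that("a no-op plant reproduces the null cohort at the same seed", {
  cfg <- sim_config(n = 300, m = 40, target_r2 = 0.3, seed = 21)
  st <- generate_synthetic_study(cfg, plant_spec(0, 0))
  null <- simulate_null_cohort(cfg)
  expect_equal(st$cohort$pairs, null$pairs)
})

test_that("plant overflow and skew/sex options behave", {
  cfg <- sim_config(n = 100, m = 10, target_r2 = 0.3, seed = 2)
  expect_error(generate_synthetic_study(cfg, plant_spec(60, 60)), "exceeds")

  cfg2 <- sim_config(n = 5000, m = 50, target_r2 = 0.167, seed = 3)
  sk <- generate_synthetic_study(cfg2, plant_spec(0, 0, skew = TRUE),
                                 mode = "fast")
  # exp transform produces right skew
  ph <- sk$cohort$pairs$pheno_z
  skewness <- mean((ph - mean(ph))^3) / sd(ph)^3
  expect_gt(skewness, 0.5)

  sx <- generate_synthetic_study(cfg2, plant_spec(0, 0, sexed = TRUE),
                                 mode = "fast")
  expect_true(all(sx$cohort$covariates$sex %in% c("male", "female")))
})
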