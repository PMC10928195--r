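test_that("config validation enforces the design envelope", {
  expect_error(generator_config(), "seed")
  expect_error(generator_config(1, richness_levels = c(1, 2, 32),
                                species_pool_size = 20), "exceeds")
  expect_error(generator_config(1, ar1_rho = 1), "ar1_rho")
  expect_error(generator_config(1, n_rates = c(-5, 40)), ">= 0")
})

test_that("monoculture simulation is exact without noise and scales with N response", {
  cfg <- generator_config(seed = 2, n_studies = 2, n_years = c(2, 2),
                          noise_sd = 0, ar1_rho = 0, deposition = c(0, 0),
                          n_response = function(rate) 1)
  m <- simulate_monocultures(cfg)
  # noise-free, flat N response: a species' yield is its baseline everywhere
  spread <- tapply(m$biomass_g_m2, paste(m$study_id, m$species_id),
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))

  cfg2 <- generator_config(seed = 2, n_studies = 1, n_years = 1,
                           noise_sd = 0, ar1_rho = 0, deposition = 0,
                           n_rates = c(0, 500),
                           n_response = function(rate) 1 + 0.001 * rate)
  m2 <- simulate_monocultures(cfg2)
  y0 <- m2$biomass_g_m2[m2$n_rate_kg_ha_yr == 0]
  y500 <- m2$biomass_g_m2[m2$n_rate_kg_ha_yr == 500]
  expect_equal(y500 / y0, rep(1.5, length(y0)))
})

test_that("the generator is deterministic in the seed", {
  cfg <- generator_config(seed = 99, n_studies = 2, n_years = c(3, 2))
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$ground_truth, s2$ground_truth)

  s3 <- simulate_experiment(generator_config(seed = 100, n_studies = 2,
                                             n_years = c(3, 2)))
  expect_false(identical(s1$data$biomass_g_m2, s3$data$biomass_g_m2))
  # design (plots, years, targets from the trend surfaces) is seed-invariant
  expect_identical(s1$ground_truth[c("study_id", "plot_id", "year",
                                     "richness", "annual_rate_total")],
                   s3$ground_truth[c("study_id", "plot_id", "year",
                                     "richness", "annual_rate_total")])
})

test_that("mixture inversion hits prescribed effects and flags degeneracies", {
  inv <- simulate_mixture(M = c(100, 200), ry_e = c(0.5, 0.5),
                          target_ce = 37.5, target_se = -17.5)
  expect_equal(inv$Y, c(80, 90), ignore_attr = TRUE)
  expect_false(inv$clipped)

  # null targets give the expected-yield community
  M <- c(150, 250, 400); ry_e <- c(0.3, 0.3, 0.4)
  expect_equal(simulate_mixture(M, ry_e, 0, 0)$Y, ry_e * M,
               ignore_attr = TRUE)

  # zero selection target makes the deviation constant across species
  d <- simulate_mixture(M, ry_e, 30, 0)$delta_ry
  expect_equal(diff(range(d)), 0)

  expect_error(simulate_mixture(c(100, 100), c(0.5, 0.5), 10, 5),
               "target_se")
  expect_true(simulate_mixture(c(100, 200), c(0.5, 0.5), -500, 0)$clipped)
})

test_that("noise-free simulated mixtures round-trip through the partition", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    M <- exp(rnorm(n, log(300), 0.4))
    w <- runif(n, 0.3, 1); ry_e <- w / sum(w)
    ce <- runif(1, -40, 80)
    se <- runif(1, -25, 25)
    inv <- simulate_mixture(M, ry_e, ce, se)
    if (inv$clipped) next
    p <- partition_effects(inv$Y, M, ry_e)
    expect_equal(p$ce, ce, tolerance = 1e-9)
    expect_equal(p$se, se, tolerance = 1e-9)
    expect_equal(p$nbe, ce + se, tolerance = 1e-9)
  }
})

test_that("noise-free experiments reproduce the trend targets through the pipeline", {
  # modest trend magnitudes keep clipping out of play
  cfg <- generator_config(seed = 8, n_studies = 2, n_years = c(3, 2),
                          noise_sd = 0, ar1_rho = 0,
                          ce_fun = function(time, rate) 20 + 2 * time - 2 * log(rate),
                          se_fun = function(time, rate) 5 - 0.2 * time + 0.5 * log(rate))
  sim <- simulate_experiment(cfg)
  ann <- aggregate_annual_yield(sim$data)
  part <- batch_partition(ann, monoculture_reference(ann, adjustment_c = 0))
  m <- merge(part, sim$ground_truth, by = c("study_id", "plot_id", "year"))
  ok <- !m$clipped
  expect_gt(mean(ok), 0.9)
  expect_equal(m$ce[ok], m$target_ce[ok], tolerance = 1e-9)
  expect_equal(m$se[ok], m$target_se[ok], tolerance = 1e-9)

  # all-zero targets give identically zero net effects (no clipping possible)
  cfg0 <- generator_config(seed = 9, n_studies = 1, n_years = 2,
                           noise_sd = 0, ar1_rho = 0,
                           ce_fun = zero_trend, se_fun = zero_trend)
  sim0 <- simulate_experiment(cfg0)
  ann0 <- aggregate_annual_yield(sim0$data)
  p0 <- batch_partition(ann0, monoculture_reference(ann0, adjustment_c = 0))
  expect_equal(p0$nbe, rep(0, nrow(p0)), tolerance = 1e-9)
})

test_that("with noise the partitioned CE is unbiased for the target", {
  cfg <- generator_config(seed = 21, n_studies = 1, n_years = 2,
                          richness_levels = c(1, 4), n_rates = 0,
                          deposition = 10, mixture_reps = 500, mono_reps = 20,
                          ce_fun = function(time, rate) 40,
                          se_fun = zero_trend)
  sim <- simulate_experiment(cfg)
  ann <- aggregate_annual_yield(sim$data)
  part <- batch_partition(ann, monoculture_reference(ann))
  part <- part[part$year == 2, ]
  expect_equal(nrow(part), 500)
  sem <- sd(part$ce) / sqrt(nrow(part))
  expect_lt(abs(mean(part$ce) - 40), 3 * sem)
})

test_that("plot-level noise has the configured AR1 autocorrelation", {
  base <- list(seed = 31, n_studies = 1, n_years = 10, n_rates = c(0, 120),
               mono_reps = 4, ar1_rho = 0.4)
  noisy <- do.call(generator_config, c(base, noise_sd = 0.2))
  clean <- do.call(generator_config, c(base, noise_sd = 0))
  m1 <- simulate_monocultures(noisy)
  m0 <- simulate_monocultures(clean)
  # identical seed and design: the log-ratio isolates the AR1 noise series
  e <- log(m1$biomass_g_m2 / m0$biomass_g_m2)
  em <- matrix(e, ncol = 10)  # plots x years (plot varies fastest per year)
  expect_gt(nrow(em), 100)
  lag_cor <- cor(as.vector(em[, -10]), as.vector(em[, -1]))
  expect_lt(abs(lag_cor - 0.4), 0.1)
})

test_that("explosive selection targets are attenuated, not propagated", {
  # near-tied monoculture means would demand unbounded deviations; the
  # generator caps them and reports the achieved target
  cfg <- generator_config(seed = 51, n_studies = 4, noise_sd = 0,
                          ar1_rho = 0, trend_mode = "multiplicative")
  sim <- simulate_experiment(cfg)
  ann <- aggregate_annual_yield(sim$data)
  part <- batch_partition(ann, monoculture_reference(ann, adjustment_c = 0))
  m <- merge(part, sim$ground_truth, by = c("study_id", "plot_id", "year"))
  ok <- !m$clipped
  expect_equal(m$se[ok], m$target_se[ok], tolerance = 1e-9)
  # no partitioned value is wildly outside the target surface's range
  expect_lt(max(abs(m$ce[ok])), 2 * max(abs(m$target_ce)) + 100)
})
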