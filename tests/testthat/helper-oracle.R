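# Independent brute-force evaluation of the partition equations, written
# term by term from their definitions; deliberately naive so it cannot
# share a code path with the package implementation.
oracle_partition <- function(Y, M, ry_e) {
  n <- length(Y)
  ry <- numeric(n)
  dry <- numeric(n)
  for (i in seq_len(n)) {
    ry[i] <- Y[i] / M[i]
    dry[i] <- ry[i] - ry_e[i]
  }
  nbe <- 0
  for (i in seq_len(n)) nbe <- nbe + Y[i] - ry_e[i] * M[i]
  m_bar <- 0
  for (i in seq_len(n)) m_bar <- m_bar + M[i] / n
  d_bar <- 0
  for (i in seq_len(n)) d_bar <- d_bar + dry[i] / n
  ce <- n * m_bar * d_bar
  cov_pop <- 0
  for (i in seq_len(n)) cov_pop <- cov_pop + (M[i] - m_bar) * (dry[i] - d_bar) / n
  se <- n * cov_pop
  ryt <- 0
  for (i in seq_len(n)) ryt <- ryt + ry[i]
  list(nbe = nbe, ce = ce, se = se, ryt = ryt)
}

# Random valid mixture observation for property tests.
random_community <- function(n = NULL) {
  if (is.null(n)) n <- sample(2:16, 1)
  M <- exp(rnorm(n, log(300), 0.5))
  w <- runif(n, 0.2, 1)
  ry_e <- w / sum(w)
  d <- rnorm(n, 0, 0.3)
  Y <- pmax((ry_e + d) * M, 0)
  list(n = n, M = M, ry_e = ry_e, Y = Y)
}

# Canonical-schema row builder for hand-made fixtures.
rec <- function(study, plot, year, species, biomass, sown = 1,
                prop = ifelse(sown == 1, 1, 0), rate = 0, harvest = 1) {
  data.frame(study_id = study, plot_id = plot, year = year,
             harvest_index = harvest, species_id = species,
             biomass_g_m2 = biomass, sown = sown, sown_proportion = prop,
             n_rate_kg_ha_yr = rate, n_treatment = as.integer(rate > 0),
             stringsAsFactors = FALSE)
}

# Full pipeline up to the model-ready table, used by model and acceptance
# tests.
sim_analysis_table <- function(cfg, policy = "study_year_treatment",
                               adjustment_c = 1) {
  sim <- simulate_experiment(cfg)
  val <- validate_dataset(sim$data)
  ann <- aggregate_annual_yield(val$data)
  part <- batch_partition(ann, monoculture_reference(ann, adjustment_c,
                                                     policy = policy))
  expo <- cumulative_exposure(val$schedule, cfg$deposition)
  add_exposure(part, expo)
}

zero_trend <- function(time, rate) 0
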