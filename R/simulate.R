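#' Configuration for the synthetic community-experiment generator
#'
#' Builds and validates the parameter set for [simulate_experiment()]. The
#' defaults emulate the design envelope of multi-site grassland biodiversity
#' x N-addition experiments: 15 studies, a sown-richness ladder on powers of
#' two up to 16 species, experimental N rates from 0 to 360 kg/ha/year on
#' top of static site deposition, one long-running study (23 years, the
#' BioCON analogue) and 14 short studies (2-4 years), and monoculture plots
#' for every species at every rate.
#'
#' @param seed integer seed; mandatory, all randomness derives from it.
#' @param n_studies number of studies (sites).
#' @param species_pool_size species available per study; must be at least
#'   `max(richness_levels)`.
#' @param richness_levels sown richness ladder (log2 ladder by default).
#' @param n_rates experimental N rates, kg/ha/year; 0 is the ambient control.
#' @param n_years integer vector of study durations (years), recycled to
#'   `n_studies`; default gives study 1 a 23-year run and the rest 2-4 years.
#' @param deposition static atmospheric deposition per study, kg/ha/year;
#'   named vector or single value; default spreads 6-24 across studies.
#' @param mono_reps replicate monoculture plots per species x rate.
#' @param mixture_reps replicate mixture plots per richness x rate cell.
#' @param ce_fun,se_fun target complementarity / selection effect surfaces,
#'   functions of `(time, rate)` or `(time, rate, richness)` where `rate`
#'   is the total annual N input (experimental + deposition, kg/ha/year)
#'   and `time` the experiment year. Defaults come from
#'   [trend_presets()] with the chosen `trend_mode`.
#' @param trend_mode which preset CE/SE surfaces to use when `ce_fun` /
#'   `se_fun` are not supplied: `"additive"` (product of a time trend and a
#'   rate trend) or `"multiplicative"` (trend in log cumulative N).
#' @param baseline_mean mean monoculture productivity, g/m2/year.
#' @param baseline_sd_log lognormal sd of species baselines.
#' @param n_response multiplicative monoculture response to the total
#'   annual N rate; default `function(rate) 1 + 8e-4 * rate`.
#' @param ar1_rho lag-1 autocorrelation of plot-level noise, in \[0, 1).
#' @param noise_sd marginal sd of the lognormal plot noise (log scale);
#'   0 gives noise-free data.
#' @param max_delta_ry cap on the per-species |relative-yield deviation|
#'   contributed by the selection-effect term. When the sown species happen
#'   to have nearly equal monoculture means, the exact inversion would
#'   require explosive deviations (the term divides by the variance of the
#'   means); the cap attenuates the selection target for such plots and the
#'   ground-truth table records the achieved value.
#' @param multi_harvest logical vector (recycled): studies whose annual
#'   yields are reported as two within-year harvests (60/40 split) that the
#'   pipeline must re-aggregate; default every second study.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_studies = 15,
                             species_pool_size = 20,
                             richness_levels = c(1, 2, 4, 8, 16),
                             n_rates = c(0, 40, 120, 360),
                             n_years = NULL,
                             deposition = NULL,
                             mono_reps = 2,
                             mixture_reps = 2,
                             ce_fun = NULL,
                             se_fun = NULL,
                             trend_mode = c("additive", "multiplicative"),
                             baseline_mean = 350,
                             baseline_sd_log = 0.35,
                             n_response = function(rate) 1 + 8e-4 * rate,
                             ar1_rho = 0.4,
                             noise_sd = 0.15,
                             max_delta_ry = 1.5,
                             multi_harvest = NULL) {
  trend_mode <- match.arg(trend_mode)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    .stopf("a single integer seed is mandatory")
  }
  if (any(richness_levels < 1)) .stopf("richness levels must be >= 1")
  if (max(richness_levels) > species_pool_size) {
    .stopf("richness %d exceeds species_pool_size %d",
           max(richness_levels), species_pool_size)
  }
  if (ar1_rho < 0 || ar1_rho >= 1) .stopf("ar1_rho must be in [0, 1)")
  if (any(n_rates < 0)) .stopf("N rates must be >= 0")
  if (is.null(n_years)) {
    n_years <- if (n_studies == 1) 23 else
      c(23, rep_len(c(4, 3, 3, 2, 2), n_studies - 1))
  }
  n_years <- rep_len(as.integer(n_years), n_studies)
  if (any(n_years < 1) || any(n_years > 23)) {
    .stopf("study durations must be 1-23 years")
  }
  study_ids <- sprintf("study%02d", seq_len(n_studies))
  if (is.null(deposition)) {
    deposition <- round(seq(6, 24, length.out = n_studies), 1)
  }
  if (is.null(names(deposition))) {
    deposition <- stats::setNames(rep_len(deposition, n_studies), study_ids)
  }
  if (any(deposition < 0)) .stopf("deposition must be >= 0")
  if (is.null(multi_harvest)) {
    multi_harvest <- seq_len(n_studies) %% 2 == 0
  }
  multi_harvest <- rep_len(multi_harvest, n_studies)
  presets <- trend_presets(trend_mode)
  if (is.null(ce_fun)) ce_fun <- presets$ce_fun
  if (is.null(se_fun)) se_fun <- presets$se_fun
  structure(list(
    seed = as.integer(seed), n_studies = n_studies,
    study_ids = study_ids, species_pool_size = species_pool_size,
    richness_levels = sort(unique(as.integer(richness_levels))),
    n_rates = sort(unique(n_rates)), n_years = n_years,
    deposition = deposition, mono_reps = as.integer(mono_reps),
    mixture_reps = as.integer(mixture_reps),
    ce_fun = ce_fun, se_fun = se_fun, trend_mode = trend_mode,
    baseline_mean = baseline_mean, baseline_sd_log = baseline_sd_log,
    n_response = n_response, ar1_rho = ar1_rho, noise_sd = noise_sd,
    max_delta_ry = max_delta_ry,
    multi_harvest = multi_harvest), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    paste0("Synthetic experiment config: %d studies, richness {%s}, ",
           "rates {%s} kg/ha/yr, %d-%d years, rho = %.2f, sd = %.2f, ",
           "trend mode '%s', seed %d\n"),
    x$n_studies, paste(x$richness_levels, collapse = ","),
    paste(x$n_rates, collapse = ","), min(x$n_years), max(x$n_years),
    x$ar1_rho, x$noise_sd, x$trend_mode, x$seed))
  invisible(x)
}

#' Preset complementarity/selection trend surfaces
#'
#' Two regimes for how the complementarity effect (CE) and selection effect
#' (SE) respond to experiment duration and N input. In the `"additive"`
#' regime duration and rate act without interaction and their contributions
#' add: CE rises linearly with time and falls log-linearly with the annual
#' N rate, SE does the opposite. In the
#' `"multiplicative"` regime time and rate interact through their product,
#' and the targets are quadratic in log cumulative N
#' (\eqn{\log(t \times r)}): convex for CE (and hence for the net effect),
#' concave for SE.
#'
#' @param mode `"additive"` or `"multiplicative"`.
#' @return list with elements `ce_fun` and `se_fun`, functions of
#'   `(time, rate)`.
#' @export
trend_presets <- function(mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  if (mode == "additive") {
    list(
      ce_fun = function(time, rate) {
        40 + 6 * time - 6 * log(pmax(rate, 1))
      },
      se_fun = function(time, rate) {
        25 - 1.2 * time + 4 * log(pmax(rate, 1))
      })
  } else {
    list(
      ce_fun = function(time, rate) {
        lc <- log(pmax(time * rate, 1))
        150 - 60 * lc + 12 * lc^2
      },
      se_fun = function(time, rate) {
        lc <- log(pmax(time * rate, 1))
        -30 + 20 * lc - 3 * lc^2
      })
  }
}

# Evaluate a trend function that may take (time, rate) or
# (time, rate, richness).
.call_trend <- function(f, time, rate, richness) {
  if (length(formals(f)) >= 3) f(time, rate, richness) else f(time, rate)
}

#' Invert the additive partition: mixture yields with given CE and SE
#'
#' Constructs per-species mixture yields whose Loreau-Hector partition
#' returns prescribed complementarity and selection effects exactly. The
#' relative-yield deviations are set to
#' \deqn{\Delta RY_i = \frac{CE}{n \overline{M}} +
#'       \beta (M_i - \overline{M}), \qquad
#'       \beta = \frac{SE}{n \, \mathrm{var}(M)}}
#' (population variance), and \eqn{Y_i = (RY_{e,i} + \Delta RY_i) M_i},
#' clipped at zero. When no clipping occurs, [partition_effects()] on the
#' output with the same `M` recovers `(target_ce + target_se, target_ce,
#' target_se)` exactly.
#'
#' @param M monoculture means of the sown species (g/m2/year), all > 0.
#' @param ry_e sown proportions (sum to 1).
#' @param target_ce,target_se prescribed complementarity and selection
#'   effects (g/m2/year). If all `M` are equal (zero variance),
#'   `target_se` must be 0.
#' @return list with `Y` (species yields), `delta_ry`, and `clipped`
#'   (logical: was any yield truncated at zero).
#' @examples
#' simulate_mixture(M = c(100, 200), ry_e = c(0.5, 0.5),
#'                  target_ce = 37.5, target_se = -17.5)$Y  # 80 90
#' @export
simulate_mixture <- function(M, ry_e, target_ce, target_se) {
  n <- length(M)
  if (n < 2) .stopf("a mixture needs at least 2 species")
  if (length(ry_e) != n) .stopf("M and ry_e must have equal length")
  if (any(M <= 0)) .stopf("monoculture means must be > 0")
  if (abs(sum(ry_e) - 1) > 1e-9) .stopf("sown proportions must sum to 1")
  m_bar <- mean(M)
  v_pop <- mean((M - m_bar)^2)
  if (v_pop == 0 && target_se != 0) {
    .stopf("target_se must be 0 when all monoculture means are equal")
  }
  beta <- if (v_pop == 0) 0 else target_se / (n * v_pop)
  d <- target_ce / (n * m_bar) + beta * (M - m_bar)
  Y <- (ry_e + d) * M
  clipped <- any(Y < 0)
  list(Y = pmax(Y, 0), delta_ry = d, clipped = clipped)
}

# Lognormal species baselines per study (rows) x species (cols).
.draw_baselines <- function(config) {
  n_sp <- max(config$richness_levels)
  matrix(exp(stats::rnorm(config$n_studies * n_sp,
                          log(config$baseline_mean),
                          config$baseline_sd_log)),
         nrow = config$n_studies,
         dimnames = list(config$study_ids, sprintf("sp%02d", seq_len(n_sp))))
}

# Split annual rows of flagged studies into two within-year harvests.
.split_harvests <- function(df, config) {
  flagged <- config$study_ids[config$multi_harvest]
  sel <- df$study_id %in% flagged
  if (!any(sel)) return(df)
  a <- df[sel, , drop = FALSE]
  h1 <- a; h1$biomass_g_m2 <- a$biomass_g_m2 * 0.6; h1$harvest_index <- 1L
  h2 <- a; h2$biomass_g_m2 <- a$biomass_g_m2 * 0.4; h2$harvest_index <- 2L
  out <- rbind(df[!sel, , drop = FALSE], h1, h2)
  out[order(out$study_id, out$plot_id, out$year, out$species_id,
            out$harvest_index), , drop = FALSE]
}

#' Simulate monoculture plots
#'
#' Generates annual monoculture yields for every study, species,
#' experimental N rate and replicate: `baseline_s * n_response(annual rate)`
#' times mean-one lognormal AR(1) plot noise. Deterministic given the
#' config seed.
#'
#' @param config a [generator_config()].
#' @param baselines optional study x species baseline matrix (internal use;
#'   drawn from the config when `NULL`).
#' @return data.frame in the canonical species-yield schema (single
#'   harvest; use [simulate_experiment()] for the full design including
#'   multi-harvest studies).
#' @export
simulate_monocultures <- function(config, baselines = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(baselines)) {
    set.seed(config$seed)
    baselines <- .draw_baselines(config)
  }
  n_sp <- ncol(baselines)
  out <- vector("list", config$n_studies)
  for (s in seq_len(config$n_studies)) {
    sid <- config$study_ids[s]
    yrs <- seq_len(config$n_years[s])
    plots <- expand.grid(species = colnames(baselines),
                         rate = config$n_rates,
                         rep = seq_len(config$mono_reps),
                         stringsAsFactors = FALSE)
    annual_rate <- plots$rate + config$deposition[[sid]]
    mu <- baselines[s, plots$species] * config$n_response(annual_rate)
    noise <- .ar1_lognorm(nrow(plots), length(yrs),
                          config$ar1_rho, config$noise_sd)
    yield <- mu * noise  # recycles mu down columns? no: mu * matrix -> by col
    # mu is length n_plots; noise is n_plots x T; element-wise by column is
    # exactly mu[i] * noise[i, t].
    out[[s]] <- data.frame(
      study_id = sid,
      plot_id = rep(sprintf("%s_mono_%s_r%g_%d", sid, plots$species,
                            plots$rate, plots$rep), times = length(yrs)),
      year = rep(yrs, each = nrow(plots)),
      harvest_index = 1L,
      species_id = rep(plots$species, times = length(yrs)),
      biomass_g_m2 = as.vector(yield),
      sown = 1L, sown_proportion = 1,
      n_rate_kg_ha_yr = rep(plots$rate, times = length(yrs)),
      n_treatment = rep(as.integer(plots$rate > 0), times = length(yrs)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a full multi-study biodiversity x N-addition experiment
#'
#' Generates a complete synthetic dataset in the canonical schema:
#' monoculture plots for every species x rate, and mixture plots at every
#' richness x rate x replicate cell, observed every year. Mixture yields
#' are built by the exact partition inversion ([simulate_mixture()]) around
#' targets `ce_fun(year, annual_rate[, richness])` and `se_fun(...)`, then
#' multiplied by plot-level mean-one lognormal AR(1) noise shared across
#' the species of a plot. Studies flagged `multi_harvest` report each
#' annual yield as two within-year harvests. A ground-truth table of the
#' per-plot-year CE/SE targets is returned for recovery testing; it records
#' the achieved targets, i.e. after the `max_delta_ry` attenuation of the
#' selection term for plots whose species have nearly tied monoculture
#' means.
#'
#' @param config a [generator_config()].
#' @return list of class `synthetic_experiment`: `data` (canonical
#'   schema), `ground_truth` (`study_id`, `plot_id`, `year`, `richness`,
#'   `n_rate_kg_ha_yr`, `annual_rate_total`, `target_ce`, `target_se`,
#'   `clipped`), and `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  baselines <- .draw_baselines(config)
  monos <- simulate_monocultures(config, baselines = baselines)

  # accumulate plain vectors; building data.frames inside the plot loop
  # is the dominant cost otherwise
  mix_rows <- list(); truth <- list(); k <- 0L
  mix_levels <- config$richness_levels[config$richness_levels >= 2]
  for (s in seq_len(config$n_studies)) {
    sid <- config$study_ids[s]
    yrs <- seq_len(config$n_years[s])
    dep <- config$deposition[[sid]]
    for (n in mix_levels) {
      for (rate in config$n_rates) {
        annual <- rate + dep
        for (r in seq_len(config$mixture_reps)) {
          comp <- sample(colnames(baselines), n)
          M <- baselines[s, comp] * config$n_response(annual)
          ry_e <- rep(1 / n, n)
          ce_t <- .call_trend(config$ce_fun, yrs, annual, n)
          se_t <- .call_trend(config$se_fun, yrs, annual, n)
          ce_t <- rep_len(ce_t, length(yrs))
          se_t <- rep_len(se_t, length(yrs))
          m_bar <- mean(M)
          v_pop <- mean((M - m_bar)^2)
          if (v_pop == 0 && any(se_t != 0)) {
            .stopf("se target nonzero but all monoculture means equal")
          }
          beta_t <- if (v_pop == 0) rep(0, length(yrs)) else se_t / (n * v_pop)
          # attenuate the selection term when the species' monoculture means
          # nearly tie: the inversion divides by var(M), so unbounded beta
          # would demand explosive relative-yield deviations
          dev_max <- max(abs(M - m_bar))
          if (dev_max > 0) {
            beta_cap <- config$max_delta_ry / dev_max
            beta_t <- pmin(pmax(beta_t, -beta_cap), beta_cap)
            se_t <- beta_t * n * v_pop
          }
          # species x year matrix of yields before noise
          d_mat <- outer(rep(1, n), ce_t / (n * m_bar)) +
            outer(M - m_bar, beta_t)
          y_mat <- (ry_e + d_mat) * M
          clipped_t <- apply(y_mat < 0, 2, any)
          y_mat <- pmax(y_mat, 0)
          noise <- .ar1_lognorm(1, length(yrs), config$ar1_rho,
                                config$noise_sd)[1, ]
          y_mat <- sweep(y_mat, 2, noise, "*")
          pid <- sprintf("%s_mix_n%02d_r%g_%d", sid, n, rate, r)
          k <- k + 1L
          ny <- length(yrs)
          mix_rows[[k]] <- list(
            study_id = rep(sid, n * ny), plot_id = rep(pid, n * ny),
            year = rep(yrs, each = n),
            species_id = rep(comp, times = ny),
            biomass_g_m2 = as.vector(y_mat),
            sown_proportion = rep(1 / n, n * ny),
            n_rate_kg_ha_yr = rep(rate, n * ny))
          truth[[k]] <- list(
            study_id = rep(sid, ny), plot_id = rep(pid, ny), year = yrs,
            richness = rep(n, ny), n_rate_kg_ha_yr = rep(rate, ny),
            annual_rate_total = rep(annual, ny),
            target_ce = ce_t, target_se = se_t, clipped = clipped_t)
        }
      }
    }
  }
  col <- function(rows, nm) unlist(lapply(rows, `[[`, nm), use.names = FALSE)
  mix <- data.frame(
    study_id = col(mix_rows, "study_id"), plot_id = col(mix_rows, "plot_id"),
    year = col(mix_rows, "year"), harvest_index = 1L,
    species_id = col(mix_rows, "species_id"),
    biomass_g_m2 = col(mix_rows, "biomass_g_m2"),
    sown = 1L, sown_proportion = col(mix_rows, "sown_proportion"),
    n_rate_kg_ha_yr = col(mix_rows, "n_rate_kg_ha_yr"),
    stringsAsFactors = FALSE)
  mix$n_treatment <- as.integer(mix$n_rate_kg_ha_yr > 0)
  data <- rbind(monos, mix)
  data <- .split_harvests(data, config)
  rownames(data) <- NULL
  gt <- data.frame(
    study_id = col(truth, "study_id"), plot_id = col(truth, "plot_id"),
    year = col(truth, "year"), richness = col(truth, "richness"),
    n_rate_kg_ha_yr = col(truth, "n_rate_kg_ha_yr"),
    annual_rate_total = col(truth, "annual_rate_total"),
    target_ce = col(truth, "target_ce"), target_se = col(truth, "target_se"),
    clipped = col(truth, "clipped"), stringsAsFactors = FALSE)
  structure(list(data = data, ground_truth = gt, config = config),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf(
    paste0("Synthetic biodiversity x N experiment: %d records, %d studies, ",
           "%d mixture plot-years (seed %d)\n"),
    nrow(x$data), x$config$n_studies, nrow(x$ground_truth), x$config$seed))
  invisible(x)
}
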