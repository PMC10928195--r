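# Internal helpers shared across modules.

# Canonical input schema for plot-level species biomass records.
CANONICAL_COLUMNS <- c(
  "study_id", "plot_id", "year", "harvest_index", "species_id",
  "biomass_g_m2", "sown", "sown_proportion", "n_rate_kg_ha_yr", "n_treatment"
)

# Composite key built with a separator unlikely to occur in identifiers.
.key <- function(...) {
  do.call(paste, c(list(...), sep = "\r"))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    .stopf("%s is missing required column(s): %s", what,
           paste(missing, collapse = ", "))
  }
  invisible(df)
}

# djb2 string hash, used only to stamp run logs with a config fingerprint.
.text_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

# Stationary AR(1) Gaussian series: marginal sd is `sd` at every time point,
# lag-1 correlation `rho`. Returns an n_series x n_time matrix.
.ar1_matrix <- function(n_series, n_time, rho, sd) {
  stopifnot(rho >= 0, rho < 1, sd >= 0, n_time >= 1)
  e <- matrix(0, n_series, n_time)
  e[, 1] <- stats::rnorm(n_series, 0, sd)
  if (n_time > 1) {
    innov_sd <- sd * sqrt(1 - rho^2)
    for (t in 2:n_time) {
      e[, t] <- rho * e[, t - 1] + stats::rnorm(n_series, 0, innov_sd)
    }
  }
  e
}

# Multiplicative lognormal noise with unit mean: exp(e - sd^2/2) where
# e is AR(1) with marginal sd `sd`.
.ar1_lognorm <- function(n_series, n_time, rho, sd) {
  exp(.ar1_matrix(n_series, n_time, rho, sd) - sd^2 / 2)
}
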