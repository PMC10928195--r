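#' Annual nitrogen input rate per plot-year
#'
#' The annual N input a plot actually receives is the experimental addition
#' plus the site's atmospheric deposition. Deposition is treated as a
#' static per-site rate (kg/ha/year), so ambient control plots still
#' receive a strictly positive input wherever deposition is positive —
#' which is what keeps log-rate models defined for control plots.
#'
#' @param schedule data.frame with columns `study_id`, `plot_id`, `year`,
#'   `experimental_rate` (kg/ha/year; 0 for ambient plots).
#' @param deposition named numeric vector (names = study ids) or data.frame
#'   with columns `study_id`, `deposition_rate`, in kg/ha/year.
#' @return the schedule with columns `deposition_rate` and
#'   `annual_rate_total` appended.
#' @export
annual_n_rate <- function(schedule, deposition) {
  schedule <- as.data.frame(schedule)
  .assert_columns(schedule, c("study_id", "plot_id", "year", "experimental_rate"),
                  "schedule")
  dep <- .deposition_vector(deposition)
  unknown <- setdiff(unique(schedule$study_id), names(dep))
  if (length(unknown)) {
    .stopf("no deposition rate configured for site(s): %s",
           paste(unknown, collapse = ", "))
  }
  if (any(schedule$experimental_rate < 0)) {
    .stopf("experimental N rates must be >= 0")
  }
  schedule$deposition_rate <- unname(dep[schedule$study_id])
  schedule$annual_rate_total <- schedule$experimental_rate +
    schedule$deposition_rate
  if (any(schedule$annual_rate_total == 0)) {
    .warnf("%d plot-year(s) have zero total N input; log-rate models will drop them",
           sum(schedule$annual_rate_total == 0))
  }
  schedule
}

.deposition_vector <- function(deposition) {
  if (is.data.frame(deposition)) {
    .assert_columns(deposition, c("study_id", "deposition_rate"), "deposition")
    deposition <- stats::setNames(deposition$deposition_rate,
                                  deposition$study_id)
  }
  if (is.list(deposition)) deposition <- unlist(deposition)
  if (is.null(names(deposition)) || !is.numeric(deposition)) {
    .stopf("deposition must be a named numeric vector or a data.frame")
  }
  if (any(deposition < 0)) .stopf("deposition rates must be >= 0")
  deposition
}

#' Cumulative nitrogen exposure per plot-year
#'
#' Cumulative exposure multiplies the annual N input by the number of years
#' over which inputs occurred: exposure through year \eqn{t} includes year
#' \eqn{t}'s input, so year 1 exposure equals one year's rate. With
#' time-varying experimental rates the rate in effect is carried forward
#' across unobserved years and summed. Three accounting modes separate the
#' contribution of experimental addition, atmospheric deposition, or both.
#'
#' @inheritParams annual_n_rate
#' @param mode which input stream the `cum_n` convenience column reports:
#'   `"both"` (default), `"experimental"` or `"deposition"`. All three
#'   cumulative columns are always returned.
#' @return data.frame with one row per plot-year: `study_id`, `plot_id`,
#'   `year`, `years_elapsed`, `annual_rate_total`, `cum_experimental`,
#'   `cum_deposition`, `cum_total` (kg/ha) and `cum_n` (the selected mode).
#' @examples
#' sched <- data.frame(study_id = "s", plot_id = "p", year = 1:23,
#'                     experimental_rate = 40)
#' tail(cumulative_exposure(sched, c(s = 0))$cum_experimental, 1)  # 920
#' @export
cumulative_exposure <- function(schedule, deposition,
                                mode = c("both", "experimental", "deposition")) {
  mode <- match.arg(mode)
  sched <- annual_n_rate(schedule, deposition)
  sched <- sched[order(sched$study_id, sched$plot_id, sched$year), ,
                 drop = FALSE]
  plot_key <- .key(sched$study_id, sched$plot_id)
  first_year <- stats::ave(sched$year, plot_key, FUN = min)
  elapsed <- sched$year - first_year + 1L

  # constant-rate plots (the usual case) reduce to rate x years elapsed;
  # time-varying schedules carry the rate forward over unobserved years
  varying <- stats::ave(sched$experimental_rate, plot_key,
                        FUN = function(x) max(x) - min(x)) > 0
  cum_exp <- sched$experimental_rate * elapsed
  if (any(varying)) {
    v <- sched[varying, , drop = FALSE]
    vk <- plot_key[varying]
    cum_exp[varying] <- unlist(lapply(
      split(seq_len(nrow(v)), factor(vk, levels = unique(vk))),
      function(i) {
        yrs <- v$year[i]
        full_years <- min(yrs):max(yrs)
        cum_full <- cumsum(v$experimental_rate[i][findInterval(full_years, yrs)])
        cum_full[match(yrs, full_years)]
      }), use.names = FALSE)
  }
  out <- data.frame(
    study_id = sched$study_id, plot_id = sched$plot_id, year = sched$year,
    years_elapsed = elapsed,
    annual_rate_total = sched$annual_rate_total,
    cum_experimental = cum_exp,
    cum_deposition = sched$deposition_rate * elapsed,
    stringsAsFactors = FALSE)
  out$cum_total <- out$cum_experimental + out$cum_deposition
  out$cum_n <- switch(mode, both = out$cum_total,
                      experimental = out$cum_experimental,
                      deposition = out$cum_deposition)
  out
}

#' Derive the N schedule from a canonical dataset and attach exposure
#'
#' Convenience wrapper: extracts the unique plot-years and experimental
#' rates from a canonical species-yield dataset (or a partition table),
#' computes [cumulative_exposure()], and returns the exposure table.
#'
#' @param dataset data.frame with columns `study_id`, `plot_id`, `year`,
#'   `n_rate_kg_ha_yr`.
#' @inheritParams cumulative_exposure
#' @export
exposure_from_dataset <- function(dataset, deposition, mode = "both") {
  dataset <- as.data.frame(dataset)
  .assert_columns(dataset, c("study_id", "plot_id", "year", "n_rate_kg_ha_yr"),
                  "dataset")
  key <- .key(dataset$study_id, dataset$plot_id, dataset$year)
  sched <- dataset[!duplicated(key),
                   c("study_id", "plot_id", "year", "n_rate_kg_ha_yr")]
  names(sched)[4] <- "experimental_rate"
  cumulative_exposure(sched, deposition, mode = mode)
}

#' Join partition results with exposure records
#'
#' @param partition_table output of [batch_partition()].
#' @param exposure output of [cumulative_exposure()] or
#'   [exposure_from_dataset()].
#' @return the partition table with `annual_rate_total`, `years_elapsed` and
#'   the cumulative N columns appended; rows without an exposure match are
#'   dropped with a warning.
#' @export
add_exposure <- function(partition_table, exposure) {
  key_p <- .key(partition_table$study_id, partition_table$plot_id,
                partition_table$year)
  key_e <- .key(exposure$study_id, exposure$plot_id, exposure$year)
  idx <- match(key_p, key_e)
  if (anyNA(idx)) {
    .warnf("%d partition row(s) have no exposure record and were dropped",
           sum(is.na(idx)))
  }
  keep <- !is.na(idx)
  cbind(partition_table[keep, , drop = FALSE],
        exposure[idx[keep],
                 c("years_elapsed", "annual_rate_total", "cum_experimental",
                   "cum_deposition", "cum_total"), drop = FALSE],
        row.names = NULL)
}
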