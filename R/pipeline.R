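#' Validate a plot-level species biomass dataset
#'
#' Checks a dataset against the canonical schema and the inclusion rules of
#' multi-study overyielding syntheses: species-level biomass must be
#' present and non-negative, sown proportions within a plot-year must sum
#' to one, each study must contain monoculture plots, and observations from
#' a study's first year are excluded (biomass is informative at earliest in
#' the second year after establishment). Rows are dropped with a recorded
#' reason, never silently.
#'
#' @param x data.frame or path to a CSV file with header columns
#'   `study_id, plot_id, year, harvest_index, species_id, biomass_g_m2,
#'   sown, sown_proportion, n_rate_kg_ha_yr, n_treatment`.
#' @param drop_first_year exclude each study's first observed year
#'   (default `TRUE`).
#' @param proportion_tol tolerance on the sown-proportion sum.
#' @return list with `data` (clean rows), `report` (a `validation_report`:
#'   row counts, per-rule counts, drop ledger) and `schedule` (unique
#'   plot-years of all structurally valid rows — including first-year rows
#'   — with experimental N rates, for exposure accounting).
#' @export
validate_dataset <- function(x, drop_first_year = TRUE,
                             proportion_tol = 1e-6) {
  df <- if (is.character(x)) {
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x)
  }
  .assert_columns(df, CANONICAL_COLUMNS, "dataset")
  rows_in <- nrow(df)
  drops <- list()
  note_drop <- function(rows, reason) {
    if (!nrow(rows)) return(NULL)
    data.frame(study_id = as.character(rows$study_id),
               plot_id = as.character(rows$plot_id),
               year = rows$year, reason = reason,
               stringsAsFactors = FALSE)
  }

  num_cols <- c("year", "harvest_index", "biomass_g_m2", "sown",
                "sown_proportion", "n_rate_kg_ha_yr", "n_treatment")
  for (cc in num_cols) {
    if (!is.numeric(df[[cc]])) {
      df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    }
  }
  bad_num <- !stats::complete.cases(df[num_cols])
  drops$malformed <- note_drop(df[bad_num, , drop = FALSE], "malformed_numeric")
  df <- df[!bad_num, , drop = FALSE]

  neg <- df$biomass_g_m2 < 0
  drops$negative <- note_drop(df[neg, , drop = FALSE], "negative_biomass")
  df <- df[!neg, , drop = FALSE]

  if (!nrow(df)) {
    report <- structure(list(
      rows_in = rows_in, rows_kept = 0L, rows_dropped = rows_in,
      rule_counts = c(malformed_numeric = sum(bad_num),
                      negative_biomass = sum(neg),
                      proportions_not_normalized = 0L,
                      no_monoculture_in_study = 0L,
                      first_year_excluded = 0L),
      ledger = do.call(rbind, c(drops[!vapply(drops, is.null, TRUE)],
        list(data.frame(study_id = character(), plot_id = character(),
                        year = numeric(), reason = character()))))),
      class = "validation_report")
    return(list(data = df, report = report,
                schedule = data.frame(study_id = character(),
                                      plot_id = character(),
                                      year = numeric(),
                                      experimental_rate = numeric())))
  }

  # schedule before content-based exclusions: exposure accrues from the
  # first treated year even when that year's biomass is excluded
  key_all <- .key(df$study_id, df$plot_id, df$year)
  schedule <- df[!duplicated(key_all),
                 c("study_id", "plot_id", "year", "n_rate_kg_ha_yr")]
  names(schedule)[4] <- "experimental_rate"
  rownames(schedule) <- NULL

  # sown proportions must sum to 1 within each plot-year
  py <- .key(df$study_id, df$plot_id, df$year)
  sown_first <- df$sown != 0 & !duplicated(.key(py, df$species_id))
  psum <- rowsum(ifelse(sown_first, df$sown_proportion, 0), py,
                 reorder = FALSE)
  bad_py <- rownames(psum)[abs(psum[, 1] - 1) > proportion_tol]
  in_bad <- py %in% bad_py
  drops$props <- note_drop(df[in_bad & !duplicated(py), , drop = FALSE],
                           "proportions_not_normalized")
  df <- df[!in_bad, , drop = FALSE]

  # studies must contain monoculture plots
  py <- .key(df$study_id, df$plot_id, df$year)
  n_sown <- rowsum(as.numeric(df$sown != 0 &
                                !duplicated(.key(py, df$species_id))),
                   py, reorder = FALSE)
  mono_py <- rownames(n_sown)[n_sown[, 1] == 1]
  mono_studies <- unique(df$study_id[py %in% mono_py])
  no_mono <- !(df$study_id %in% mono_studies)
  drops$no_mono <- note_drop(
    df[no_mono & !duplicated(df$study_id), , drop = FALSE],
    "no_monoculture_in_study")
  df_dropped_no_mono <- df[no_mono, , drop = FALSE]
  df <- df[!no_mono, , drop = FALSE]

  # first-year exclusion
  dropped_first <- df[0, , drop = FALSE]
  if (drop_first_year && nrow(df)) {
    first_year <- tapply(df$year, df$study_id, min)
    is_first <- df$year == first_year[df$study_id]
    pyf <- .key(df$study_id, df$plot_id, df$year)
    drops$first <- note_drop(df[is_first & !duplicated(pyf), , drop = FALSE],
                             "first_year_excluded")
    dropped_first <- df[is_first, , drop = FALSE]
    df <- df[!is_first, , drop = FALSE]
  }

  ledger <- do.call(rbind, drops[!vapply(drops, is.null, TRUE)])
  if (is.null(ledger)) {
    ledger <- data.frame(study_id = character(), plot_id = character(),
                         year = numeric(), reason = character())
  }
  rownames(ledger) <- NULL
  rows_kept <- nrow(df)
  report <- structure(list(
    rows_in = rows_in, rows_kept = rows_kept,
    rows_dropped = rows_in - rows_kept,
    rule_counts = c(
      malformed_numeric = sum(bad_num),
      negative_biomass = sum(neg),
      proportions_not_normalized = sum(in_bad),
      no_monoculture_in_study = nrow(df_dropped_no_mono),
      first_year_excluded = nrow(dropped_first)),
    ledger = ledger), class = "validation_report")
  rownames(df) <- NULL
  list(data = df, report = report, schedule = schedule)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation: %d rows in, %d kept, %d dropped\n",
              x$rows_in, x$rows_kept, x$rows_dropped))
  rc <- x$rule_counts[x$rule_counts > 0]
  if (length(rc)) {
    for (i in seq_along(rc)) cat(sprintf("  %s: %d\n", names(rc)[i], rc[i]))
  } else {
    cat("  all rules passed\n")
  }
  invisible(x)
}

.default_models <- function() {
  list(responses = c("nbe", "ce", "se"),
       hypotheses = c("h1a_binary", "h1a_richness", "h1b_rate", "h2_time",
                      "h3_cumulative", "h3_rate_time"),
       method = "REML")
}

#' Run the full overyielding analysis pipeline
#'
#' Orchestrates the end-to-end analysis: load (or simulate) plot-level
#' species biomass records, validate them, aggregate harvests to annual
#' yields, build the monoculture reference, partition every mixture
#' plot-year into net biodiversity / complementarity / selection effects,
#' attach annual and cumulative N exposure, and fit the requested
#' mixed-model hierarchy. All outputs are plain CSV (plus a YAML/JSON
#' metadata sidecar per model) and the run is deterministic given the
#' config and seed.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{seed}{integer; mandatory when simulating.}
#'     \item{input}{list with `csv` path, or `NULL` to simulate.}
#'     \item{simulate}{list of [generator_config()] arguments (used when
#'       `input` is absent).}
#'     \item{adjustment_c}{monoculture adjustment constant, default 1.}
#'     \item{monoculture_policy}{character vector of matching policies in
#'       fallback order, default `"study_year_treatment"`.}
#'     \item{deposition}{named per-study deposition rates (kg/ha/year);
#'       defaults to the generator's when simulating.}
#'     \item{models}{list with `responses`, `hypotheses`, optional
#'       `h2_study` and `method`; `NULL` fits the full default menu.}
#'   }
#' @param out_dir directory for output files; `NULL` (default) writes
#'   nothing to disk.
#' @return (invisibly) list with `data`, `validation`, `partition`,
#'   `exposure`, `table` (partition + exposure), `fits`, `ground_truth`
#'   (when simulated) and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg_text <- yaml::as.yaml(config)
  log_lines <- c(sprintf("run started %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("R %s, overyieldN %s", getRversion(),
                         as.character(utils::packageVersion("overyieldN"))),
                 sprintf("config hash %s", .text_hash(cfg_text)))

  ground_truth <- NULL
  if (!is.null(config$input$csv)) {
    raw <- utils::read.csv(config$input$csv, stringsAsFactors = FALSE)
    log_lines <- c(log_lines, sprintf("input: %s (%d rows)",
                                      config$input$csv, nrow(raw)))
    deposition <- config$deposition
    if (is.null(deposition)) {
      .stopf("deposition rates must be configured when reading a CSV input")
    }
  } else {
    sim_args <- config$simulate
    if (is.null(sim_args)) sim_args <- list()
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    if (is.null(sim_args$seed)) .stopf("a seed is required to simulate data")
    gc <- do.call(generator_config, sim_args)
    sim <- simulate_experiment(gc)
    raw <- sim$data
    ground_truth <- sim$ground_truth
    deposition <- if (!is.null(config$deposition)) {
      unlist(config$deposition)
    } else {
      gc$deposition
    }
    log_lines <- c(log_lines, sprintf("simulated input: %d rows, seed %d",
                                      nrow(raw), gc$seed))
  }
  deposition <- .deposition_vector(deposition)

  val <- validate_dataset(raw,
    drop_first_year = !isFALSE(config$drop_first_year))
  log_lines <- c(log_lines,
                 sprintf("validation: %d in / %d kept / %d dropped",
                         val$report$rows_in, val$report$rows_kept,
                         val$report$rows_dropped))
  if (!nrow(val$data)) {
    .warnf("no rows left after validation; outputs are empty")
  }

  annual <- aggregate_annual_yield(val$data)
  adjustment_c <- if (is.null(config$adjustment_c)) 1 else config$adjustment_c
  policies <- config$monoculture_policy
  if (is.null(policies)) policies <- "study_year_treatment"
  monos <- lapply(policies, function(p) {
    monoculture_reference(annual, adjustment_c = adjustment_c, policy = p)
  })
  part <- if (nrow(annual)) batch_partition(annual, monos) else
    batch_partition(annual[0, ], monos)
  n_drop <- nrow(attr(part, "drops"))
  log_lines <- c(log_lines,
                 sprintf("partition: %d plot-years, %d dropped", nrow(part),
                         if (is.null(n_drop)) 0L else n_drop))

  exposure <- if (nrow(val$schedule)) {
    cumulative_exposure(val$schedule, deposition)
  } else {
    cumulative_exposure(
      data.frame(study_id = character(), plot_id = character(),
                 year = integer(), experimental_rate = numeric()),
      deposition)
  }
  tab <- if (nrow(part)) add_exposure(part, exposure) else part

  # model menu
  fits <- list()
  model_cfg <- config$models
  if (is.null(model_cfg)) model_cfg <- .default_models()
  if (!identical(model_cfg, FALSE) && nrow(part)) {
    responses <- model_cfg$responses
    if (is.null(responses)) responses <- c("nbe", "ce", "se")
    hyps <- model_cfg$hypotheses
    if (is.null(hyps)) hyps <- .default_models()$hypotheses
    method <- if (is.null(model_cfg$method)) "REML" else model_cfg$method
    h2_study <- model_cfg$h2_study
    if (is.null(h2_study)) {
      # default: the study with the most observed years
      yrs <- tapply(tab$year, tab$study_id, function(y) length(unique(y)))
      h2_study <- names(yrs)[which.max(yrs)]
    }
    for (resp in responses) {
      for (h in hyps) {
        nm <- paste(h, resp, sep = "_")
        f <- tryCatch(switch(h,
          h1a_binary    = fit_h1a_binary(tab, resp, method = method),
          h1a_richness  = fit_h1a_richness(tab, resp, method = method),
          h1b_rate      = fit_h1b_rate(tab, resp, method = method),
          h2_time       = fit_h2_time(tab, h2_study, resp, method = method),
          h3_cumulative = fit_h3_cumulative(tab, resp, method = method),
          h3_rate_time  = fit_h3_rate_time(tab, resp, method = method),
          .stopf("unknown hypothesis '%s'", h)),
          error = function(e) e)
        if (inherits(f, "error")) {
          log_lines <- c(log_lines, sprintf("model %s failed: %s", nm,
                                            conditionMessage(f)))
        } else {
          fits[[nm]] <- f
          log_lines <- c(log_lines, sprintf("model %s: AIC %.2f", nm, f$aic))
        }
      }
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(
      part[c("study_id", "plot_id", "year", "richness", "nbe", "ce", "se",
             "ryt", "flags")],
      file.path(out_dir, "partition.csv"), row.names = FALSE)
    utils::write.csv(
      exposure[c("study_id", "plot_id", "year", "annual_rate_total",
                 "cum_experimental", "cum_deposition", "cum_total")],
      file.path(out_dir, "exposure.csv"), row.names = FALSE)
    utils::write.csv(tab, file.path(out_dir, "analysis_table.csv"),
                     row.names = FALSE)
    drops <- attr(part, "drops")
    if (!is.null(drops) && nrow(drops)) {
      utils::write.csv(drops, file.path(out_dir, "partition_drops.csv"),
                       row.names = FALSE)
    }
    if (!is.null(ground_truth)) {
      utils::write.csv(ground_truth, file.path(out_dir, "ground_truth.csv"),
                       row.names = FALSE)
    }
    for (nm in names(fits)) {
      f <- fits[[nm]]
      utils::write.csv(f$coefficients,
                       file.path(out_dir, sprintf("model_%s_coefficients.csv", nm)),
                       row.names = FALSE)
      meta <- list(spec = f$spec, loglik = f$loglik, k = f$k, aic = f$aic,
                   n_obs = f$n_obs, converged = f$converged, notes = f$notes)
      writeLines(yaml::as.yaml(meta),
                 file.path(out_dir, sprintf("model_%s_meta.yml", nm)))
    }
    writeLines(c(log_lines, utils::capture.output(print(val$report))),
               file.path(out_dir, "run_log.txt"))
  }

  invisible(list(data = raw, validation = val$report, partition = part,
                 exposure = exposure, table = tab, fits = fits,
                 ground_truth = ground_truth, out_dir = out_dir))
}
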