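# Mixed-effects model hierarchy for partitioned biodiversity effects.
#
# All models are fitted with nlme::lme so that random intercepts/slopes can
# be combined with a first-order autoregressive residual correlation over
# years within plots. Model construction, transformations and inclusion
# rules live here; the numerics are nlme's.

.lme_ctrl <- function() {
  nlme::lmeControl(maxIter = 150, msMaxIter = 200, niterEM = 50,
                   returnObject = TRUE)
}

# Fit with the default optimiser, retrying with optim on failure.
.fit_lme <- function(fixed, data, random, correlation = NULL,
                     method = "REML") {
  notes <- character()
  fit <- tryCatch(
    nlme::lme(fixed, data = data, random = random,
              correlation = correlation, method = method,
              control = .lme_ctrl(), na.action = stats::na.omit),
    error = function(e) e)
  if (inherits(fit, "error")) {
    notes <- sprintf("default optimiser failed (%s); retried with optim",
                     conditionMessage(fit))
    ctrl <- .lme_ctrl(); ctrl$opt <- "optim"
    fit <- nlme::lme(fixed, data = data, random = random,
                     correlation = correlation, method = method,
                     control = ctrl, na.action = stats::na.omit)
  }
  list(model = fit, notes = notes)
}

# Wrap an lme fit into the package's fit container.
.new_fit <- function(model, spec, data, marginal_means = NULL,
                     notes = character()) {
  ll <- stats::logLik(model)
  tt <- summary(model)$tTable
  coefs <- data.frame(term = rownames(tt),
                      estimate = tt[, "Value"], se = tt[, "Std.Error"],
                      df = tt[, "DF"], t = tt[, "t-value"],
                      p = tt[, "p-value"], row.names = NULL)
  structure(list(
    spec = spec, model = model, coefficients = coefs,
    loglik = as.numeric(ll), k = attr(ll, "df"),
    aic = stats::AIC(model), n_obs = model$dims$N,
    marginal_means = marginal_means, converged = TRUE, notes = notes,
    data = data), class = "oyn_fit")
}

#' @export
print.oyn_fit <- function(x, ...) {
  cat(sprintf("Mixed-model fit [%s] response '%s' (n = %d, method %s)\n",
              x$spec$hypothesis, x$spec$response, x$n_obs, x$spec$method))
  cat(sprintf("  fixed:  %s\n  random: %s\n", x$spec$fixed, x$spec$random))
  if (!is.null(x$spec$correlation) && nzchar(x$spec$correlation))
    cat(sprintf("  residual correlation: %s\n", x$spec$correlation))
  cat(sprintf("  logLik = %.3f, k = %d, AIC = %.3f\n", x$loglik, x$k, x$aic))
  print(x$coefficients, digits = 4)
  if (!is.null(x$marginal_means)) {
    cat("Marginal means:\n")
    print(x$marginal_means, digits = 4)
  }
  if (length(x$notes)) cat("Notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.oyn_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

.check_response <- function(tab, response) {
  if (!response %in% c("nbe", "ce", "se")) {
    .stopf("response must be one of nbe, ce, se")
  }
  .assert_columns(tab, c("study_id", "plot_id", "year", response),
                  "partition table")
  tab$.resp <- tab[[response]]
  tab
}

#' H1a: overall effect of N addition as a binary treatment
#'
#' Fits `response ~ treatment * study` over the studies that contain both
#' ambient and N-addition plots, with plot-level random intercepts and a
#' first-order autoregressive (AR1) residual correlation across years
#' within plots, and returns estimated marginal means for ambient vs N
#' (averaged over studies with equal weights). The alternative literal
#' random structure — plot nested in year as random intercepts, no AR1 —
#' is available via `random_structure = "plot_in_year"`.
#'
#' @param tab partition table (from [batch_partition()], optionally with
#'   exposure columns), with `n_treatment` (0 ambient / 1 N).
#' @param response `"nbe"`, `"ce"` or `"se"`.
#' @param random_structure `"plot_ar1"` (default) or `"plot_in_year"`.
#' @param method `"REML"` (default) or `"ML"` (required for AIC comparison
#'   across different fixed effects).
#' @return object of class `oyn_fit`; `$marginal_means` holds the
#'   ambient/N means, `$contrasts` their difference.
#' @export
fit_h1a_binary <- function(tab, response = "ce",
                           random_structure = c("plot_ar1", "plot_in_year"),
                           method = "REML") {
  random_structure <- match.arg(random_structure)
  tab <- .check_response(as.data.frame(tab), response)
  .assert_columns(tab, "n_treatment", "partition table")

  # inclusion rule: studies with both ambient and N plots
  has_both <- tapply(tab$n_treatment, tab$study_id,
                     function(x) length(unique(x)) >= 2)
  d <- tab[tab$study_id %in% names(has_both)[has_both], , drop = FALSE]
  if (!nrow(d) || length(unique(d$n_treatment)) < 2) {
    .stopf("need studies containing both ambient and N-addition plots")
  }
  d$trt <- factor(ifelse(d$n_treatment > 0, "N", "ambient"),
                  levels = c("ambient", "N"))
  d$study <- factor(d$study_id)
  d$plot_f <- factor(d$plot_id)
  d$year_f <- factor(d$year)
  notes <- character()

  fixed <- if (nlevels(d$study) >= 2) .resp ~ trt * study else .resp ~ trt
  if (nlevels(d$study) < 2) notes <- c(notes, "single study: no study fixed effect")

  repeated <- any(tapply(d$year, d$plot_id, function(y) length(unique(y))) > 1)
  if (random_structure == "plot_ar1") {
    random <- ~ 1 | plot_f
    corr <- if (repeated) nlme::corAR1(form = ~ year | plot_f) else NULL
    if (!repeated) {
      .warnf("no repeated years per plot; AR1 correlation dropped")
      notes <- c(notes, "AR1 dropped: single year per plot")
    }
  } else {
    random <- ~ 1 | year_f / plot_f
    corr <- NULL
  }

  res <- .fit_lme(fixed, d, random, corr, method)
  emm_obj <- tryCatch(emmeans::emmeans(res$model, specs = "trt", data = d),
                      error = function(e) {
                        .warnf("marginal means unavailable: %s",
                               conditionMessage(e))
                        NULL
                      })
  emm <- if (!is.null(emm_obj)) as.data.frame(emm_obj) else NULL
  fit <- .new_fit(res$model,
    spec = list(hypothesis = "H1a_binary", response = response,
                fixed = deparse(fixed),
                random = if (random_structure == "plot_ar1")
                  "~1 | plot" else "~1 | year/plot",
                correlation = if (!is.null(corr)) "AR1(year | plot)" else "",
                method = method, filter = "studies with both treatments"),
    data = d, marginal_means = emm, notes = c(notes, res$notes))
  if (!is.null(emm_obj) && nrow(emm) == 2) {
    ctr <- as.data.frame(emmeans::contrast(emm_obj, method = "revpairwise"))
    fit$contrasts <- data.frame(
      contrast = ctr$contrast, estimate = ctr$estimate, se = ctr$SE,
      df = ctr$df, p = ctr$p.value)
  }
  fit
}

#' H1a: interaction of N addition with sown species richness
#'
#' Fits `response ~ treatment * log2(richness)` with random intercepts for
#' richness level nested in study. Following the inclusion rule for this
#' hypothesis, only studies with at least three mixture richness levels
#' enter the fit.
#'
#' @inheritParams fit_h1a_binary
#' @return `oyn_fit`; the treatment x log2(richness) interaction row of
#'   `$coefficients` is the quantity of interest.
#' @export
fit_h1a_richness <- function(tab, response = "ce", method = "REML") {
  tab <- .check_response(as.data.frame(tab), response)
  .assert_columns(tab, c("richness", "n_treatment"), "partition table")
  if (length(unique(tab$richness)) < 2) {
    .stopf("richness is constant; the richness model is undefined")
  }
  n_lev <- tapply(tab$richness, tab$study_id,
                  function(x) length(unique(x)))
  keep <- names(n_lev)[n_lev >= 3]
  d <- tab[tab$study_id %in% keep, , drop = FALSE]
  if (!nrow(d) || length(unique(d$richness)) < 3) {
    .stopf(paste0("fewer than 3 sown richness levels available; the ",
                  "richness-interaction analysis requires studies with ",
                  "more than two richness levels"))
  }
  d$trt <- factor(ifelse(d$n_treatment > 0, "N", "ambient"),
                  levels = c("ambient", "N"))
  d$log2_richness <- log2(d$richness)
  d$rich_f <- factor(d$richness)
  d$study <- factor(d$study_id)
  res <- .fit_lme(.resp ~ trt * log2_richness, d,
                  random = ~ 1 | study / rich_f, method = method)
  .new_fit(res$model,
    spec = list(hypothesis = "H1a_richness", response = response,
                fixed = ".resp ~ trt * log2(richness)",
                random = "~1 | study/richness", correlation = "",
                method = method,
                filter = "studies with >= 3 richness levels"),
    data = d, notes = res$notes)
}

#' H1b: effect of the annual N addition rate
#'
#' Fits `response ~ log(annual N rate)` with random intercepts and slopes
#' among studies. The annual rate is the total input (experimental +
#' atmospheric deposition), so ambient plots keep a positive rate wherever
#' deposition is positive. Rows with zero total rate are dropped with a
#' message. The ambient/N-addition contrast can be separated from the rate
#' effect by toggling `include_ambient`.
#'
#' @inheritParams fit_h1a_binary
#' @param include_ambient keep ambient (no experimental N) plots (`TRUE`,
#'   default) or restrict to N-addition plots (`FALSE`).
#' @export
fit_h1b_rate <- function(tab, response = "ce", include_ambient = TRUE,
                         method = "REML") {
  tab <- .check_response(as.data.frame(tab), response)
  .assert_columns(tab, "annual_rate_total", "partition table")
  d <- tab
  if (!include_ambient) {
    .assert_columns(d, "n_treatment", "partition table")
    d <- d[d$n_treatment > 0, , drop = FALSE]
  }
  n_zero <- sum(d$annual_rate_total <= 0)
  if (n_zero) {
    message(sprintf("dropping %d row(s) with zero total N rate", n_zero))
    d <- d[d$annual_rate_total > 0, , drop = FALSE]
  }
  if (!nrow(d)) .stopf("no rows with positive N rate")
  if (length(unique(d$study_id)) < 2) {
    .stopf("random slopes among studies require at least 2 studies")
  }
  d$log_rate <- log(d$annual_rate_total)
  d$study <- factor(d$study_id)
  res <- .fit_lme(.resp ~ log_rate, d, random = ~ log_rate | study,
                  method = method)
  .new_fit(res$model,
    spec = list(hypothesis = "H1b_rate", response = response,
                fixed = ".resp ~ log(annual rate)",
                random = "~log_rate | study", correlation = "",
                method = method,
                filter = if (include_ambient) "include ambient"
                         else "exclude ambient"),
    data = d, notes = res$notes)
}

#' H2: interaction of N addition with experiment duration
#'
#' For one long-running study, fits `response ~ treatment * year` with
#' random intercepts for sown richness level. The treatment x year
#' interaction measures how N addition bends the temporal trajectory of
#' the biodiversity effect.
#'
#' @inheritParams fit_h1a_binary
#' @param study id of the study to analyse (the long-running one).
#' @export
fit_h2_time <- function(tab, study, response = "ce", method = "REML") {
  tab <- .check_response(as.data.frame(tab), response)
  .assert_columns(tab, c("richness", "n_treatment"), "partition table")
  if (!study %in% tab$study_id) .stopf("study '%s' not present", study)
  d <- tab[tab$study_id == study, , drop = FALSE]
  if (length(unique(d$year)) < 3) {
    .stopf("the duration analysis needs at least 3 distinct years")
  }
  if (length(unique(d$n_treatment)) < 2) {
    .stopf("study '%s' lacks an ambient/N contrast", study)
  }
  d$trt <- factor(ifelse(d$n_treatment > 0, "N", "ambient"),
                  levels = c("ambient", "N"))
  notes <- character()
  if (length(unique(d$richness)) >= 2) {
    random <- ~ 1 | rich_f
    d$rich_f <- factor(d$richness)
    rand_lab <- "~1 | richness"
  } else {
    random <- ~ 1 | plot_f
    d$plot_f <- factor(d$plot_id)
    rand_lab <- "~1 | plot"
    notes <- "single richness level: plot random intercept used"
  }
  res <- .fit_lme(.resp ~ trt * year, d, random = random, method = method)
  .new_fit(res$model,
    spec = list(hypothesis = "H2_time", response = response,
                fixed = ".resp ~ trt * year", random = rand_lab,
                correlation = "", method = method,
                filter = sprintf("study == %s", study)),
    data = d, notes = c(notes, res$notes))
}

#' H3: quadratic effect of cumulative N addition
#'
#' Fits `response ~ log(cum N) + log(cum N)^2` with random intercepts and
#' slopes among studies, under one of three accounting modes for the
#' cumulative input: experimental addition only, atmospheric deposition
#' only, or both combined. The sign of the quadratic coefficient is the
#' headline quantity: positive = convex, negative = concave on the log
#' cumulative-N axis.
#'
#' @inheritParams fit_h1a_binary
#' @param mode `"both"` (default), `"experimental"` or `"deposition"`.
#' @return `oyn_fit` with `$quadratic`, the coefficient row for the
#'   squared term.
#' @export
fit_h3_cumulative <- function(tab, response = "nbe",
                              mode = c("both", "experimental", "deposition"),
                              method = "REML") {
  mode <- match.arg(mode)
  tab <- .check_response(as.data.frame(tab), response)
  col <- switch(mode, both = "cum_total", experimental = "cum_experimental",
                deposition = "cum_deposition")
  .assert_columns(tab, col, "partition table")
  if (all(tab[[col]] == 0)) {
    .stopf("cumulative column '%s' is identically zero", col)
  }
  d <- tab
  n_zero <- sum(d[[col]] <= 0)
  if (n_zero) {
    message(sprintf("dropping %d row(s) with non-positive cumulative N", n_zero))
    d <- d[d[[col]] > 0, , drop = FALSE]
  }
  if (length(unique(d$study_id)) < 2) {
    .stopf("random slopes among studies require at least 2 studies")
  }
  d$log_cum <- log(d[[col]])
  d$study <- factor(d$study_id)
  res <- .fit_lme(.resp ~ log_cum + I(log_cum^2), d,
                  random = ~ log_cum | study, method = method)
  fit <- .new_fit(res$model,
    spec = list(hypothesis = "H3_cumulative", response = response,
                fixed = ".resp ~ log(cum N) + log(cum N)^2",
                random = "~log_cum | study", correlation = "",
                method = method, filter = sprintf("mode = %s", mode)),
    data = d, notes = res$notes)
  fit$quadratic <- fit$coefficients[fit$coefficients$term == "I(log_cum^2)", ]
  fit
}

#' Competitor model: annual N rate and time
#'
#' The model the cumulative-N formulation is compared against: fixed
#' effects of log(annual rate) and year — additive by default, or with
#' their interaction — and random intercepts and slopes among studies.
#'
#' @inheritParams fit_h1a_binary
#' @param interaction include the rate x year interaction.
#' @export
fit_h3_rate_time <- function(tab, response = "nbe", interaction = FALSE,
                             method = "REML") {
  tab <- .check_response(as.data.frame(tab), response)
  .assert_columns(tab, "annual_rate_total", "partition table")
  d <- tab[tab$annual_rate_total > 0, , drop = FALSE]
  if (length(unique(d$study_id)) < 2) {
    .stopf("random slopes among studies require at least 2 studies")
  }
  d$log_rate <- log(d$annual_rate_total)
  d$study <- factor(d$study_id)
  fixed <- if (interaction) .resp ~ log_rate * year else .resp ~ log_rate + year
  res <- .fit_lme(fixed, d, random = ~ log_rate | study, method = method)
  .new_fit(res$model,
    spec = list(hypothesis = "H3_rate_time", response = response,
                fixed = deparse(fixed), random = "~log_rate | study",
                correlation = "", method = method,
                filter = if (interaction) "rate x time interaction"
                         else "additive rate + time"),
    data = d, notes = res$notes)
}

#' Rank model fits by AIC
#'
#' @param ... `oyn_fit` objects, or a single list of them (optionally
#'   named).
#' @return data.frame sorted by AIC ascending with `delta_aic` relative to
#'   the best model. Fits on different observation sets are not comparable
#'   and raise an error; REML fits trigger a warning because REML AICs are
#'   only comparable across identical fixed effects.
#' @export
compare_aic <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "oyn_fit")) {
    fits <- fits[[1]]
  }
  if (length(fits) < 2 || !all(vapply(fits, inherits, TRUE, "oyn_fit"))) {
    .stopf("compare_aic needs at least two oyn_fit objects")
  }
  n_obs <- vapply(fits, `[[`, 0, "n_obs")
  if (length(unique(n_obs)) > 1) {
    .stopf("fits use different observation counts (%s); AIC not comparable",
           paste(n_obs, collapse = ", "))
  }
  resp <- vapply(fits, function(f) f$spec$response, "")
  if (length(unique(resp)) > 1) {
    .stopf("fits model different responses (%s); AIC not comparable",
           paste(unique(resp), collapse = ", "))
  }
  if (any(vapply(fits, function(f) f$spec$method, "") == "REML")) {
    .warnf("REML AICs are comparable only across identical fixed effects; refit with method = 'ML'")
  }
  nm <- names(fits)
  if (is.null(nm) || any(!nzchar(nm))) {
    nm <- vapply(fits, function(f) f$spec$hypothesis, "")
    nm <- make.unique(nm)
  }
  out <- data.frame(model = nm,
                    aic = vapply(fits, `[[`, 0, "aic"),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    k = vapply(fits, `[[`, 0, "k"),
                    n_obs = n_obs)
  out <- out[order(out$aic), , drop = FALSE]
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  out
}
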