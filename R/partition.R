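#' Sum multiple harvests into annual species yields
#'
#' Grassland experiments often harvest the same plot several times a year.
#' To compare productivity across studies, within-year harvests are summed
#' into a single annual above-ground yield per species and plot
#' (g/m\eqn{^2}/year).
#'
#' @param records data.frame of plot-level species biomass records with at
#'   least columns `study_id`, `plot_id`, `year`, `species_id`,
#'   `biomass_g_m2`, and optionally `harvest_index` (assumed 1 when absent).
#'   Other columns (sowing metadata, treatments) are carried through
#'   unchanged, taking the value of the first harvest row.
#' @return data.frame with one row per (study, plot, year, species); the
#'   `harvest_index` column is removed and `biomass_g_m2` holds the annual
#'   sum.
#' @details Negative biomass values and duplicated
#'   (plot, year, species, harvest) rows are treated as data errors, not
#'   silently repaired.
#' @examples
#' rec <- data.frame(
#'   study_id = "s1", plot_id = "p1", year = 2, harvest_index = c(1, 2),
#'   species_id = "spA", biomass_g_m2 = c(120, 80)
#' )
#' aggregate_annual_yield(rec)$biomass_g_m2  # 200
#' @export
aggregate_annual_yield <- function(records) {
  records <- as.data.frame(records)
  .assert_columns(records,
    c("study_id", "plot_id", "year", "species_id", "biomass_g_m2"),
    "records")
  if (!"harvest_index" %in% names(records)) records$harvest_index <- 1L

  bad <- which(is.na(records$biomass_g_m2) | records$biomass_g_m2 < 0)
  if (length(bad)) {
    .stopf("negative or missing biomass in %d record(s); first offending row: %d",
           length(bad), bad[1])
  }
  full_key <- .key(records$study_id, records$plot_id, records$year,
                   records$species_id, records$harvest_index)
  if (anyDuplicated(full_key)) {
    d <- records[duplicated(full_key), ][1, ]
    .stopf(paste0("duplicate harvest record for study=%s plot=%s year=%s ",
                  "species=%s harvest=%s"),
           d$study_id, d$plot_id, d$year, d$species_id, d$harvest_index)
  }

  grp <- .key(records$study_id, records$plot_id, records$year,
              records$species_id)
  sums <- rowsum(records$biomass_g_m2, grp, reorder = FALSE)
  keep <- !duplicated(grp)
  out <- records[keep, setdiff(names(records), "harvest_index"), drop = FALSE]
  out$biomass_g_m2 <- sums[match(grp[keep], rownames(sums)), 1]
  rownames(out) <- NULL
  out
}

#' Build the monoculture reference table
#'
#' For every sown species the partition needs its expected monoculture
#' productivity \eqn{M_i}. This is estimated as the mean annual yield over
#' replicate monoculture plots within a matching group, plus a small
#' constant `adjustment_c`. The constant guards against relative yields
#' exploding when a monoculture happens to yield close to zero; the
#' conventional value is 1 g/m\eqn{^2}/year.
#'
#' @param records annual species-yield records (see
#'   [aggregate_annual_yield()]); monoculture plots are identified as plots
#'   whose sown community is a single species.
#' @param adjustment_c non-negative constant added to every monoculture mean
#'   (g/m\eqn{^2}/year); default 1.
#' @param policy matching group for the reference:
#'   `"study_year_treatment"` (default) matches a mixture to monocultures of
#'   the same study, year and experimental N rate; `"study_treatment"`
#'   averages over years; `"study_year"` pools N treatments within a year.
#' @return data.frame of class `monoculture_table` with columns `study_id`,
#'   `year` and/or `n_rate_kg_ha_yr` (depending on policy), `species_id`,
#'   `M` (adjusted mean) and `n_reps` (replicate monoculture plot-years).
#' @export
monoculture_reference <- function(records, adjustment_c = 1,
                                  policy = c("study_year_treatment",
                                             "study_treatment",
                                             "study_year")) {
  policy <- match.arg(policy)
  if (!is.numeric(adjustment_c) || length(adjustment_c) != 1 ||
      is.na(adjustment_c) || adjustment_c < 0) {
    .stopf("adjustment_c must be a single non-negative number")
  }
  records <- as.data.frame(records)
  .assert_columns(records,
    c("study_id", "plot_id", "year", "species_id", "biomass_g_m2", "sown"),
    "records")
  if (anyDuplicated(.key(records$study_id, records$plot_id, records$year,
                         records$species_id))) {
    .stopf("records contain multiple rows per plot-year and species; aggregate to annual yields first")
  }
  if (!"n_rate_kg_ha_yr" %in% names(records)) records$n_rate_kg_ha_yr <- 0

  # A monoculture plot-year has exactly one sown species.
  py <- .key(records$study_id, records$plot_id, records$year)
  n_sown <- rowsum(as.numeric(records$sown != 0), py, reorder = FALSE)
  mono_py <- rownames(n_sown)[n_sown[, 1] == 1]
  mono <- records[py %in% mono_py & records$sown != 0, , drop = FALSE]
  if (!nrow(mono) && nrow(records)) {
    .stopf("no monoculture plots found in records")
  }

  grp_cols <- switch(policy,
    study_year_treatment = c("study_id", "year", "n_rate_kg_ha_yr", "species_id"),
    study_treatment      = c("study_id", "n_rate_kg_ha_yr", "species_id"),
    study_year           = c("study_id", "year", "species_id"))
  if (!nrow(mono)) {
    out <- cbind(mono[grp_cols], n_reps = integer(0), M = numeric(0))
    return(structure(out, class = c("monoculture_table", "data.frame"),
                     policy = policy, adjustment_c = adjustment_c))
  }
  grp <- do.call(.key, mono[grp_cols])
  sums <- rowsum(cbind(mono$biomass_g_m2, 1), grp, reorder = FALSE)
  keep <- !duplicated(grp)
  out <- mono[keep, grp_cols, drop = FALSE]
  idx <- match(grp[keep], rownames(sums))
  out$n_reps <- as.integer(sums[idx, 2])
  out$M <- sums[idx, 1] / out$n_reps + adjustment_c
  rownames(out) <- NULL
  structure(out,
            class = c("monoculture_table", "data.frame"),
            policy = policy, adjustment_c = adjustment_c)
}

#' @export
print.monoculture_table <- function(x, ...) {
  cat(sprintf("Monoculture reference table: %d entries, policy '%s', c = %g\n",
              nrow(x), attr(x, "policy"), attr(x, "adjustment_c")))
  NextMethod()
}

# Look up M for given (study, year, rate, species) under the table's policy.
.lookup_M <- function(monos, study_id, year, n_rate, species_id) {
  key <- switch(attr(monos, "policy"),
    study_year_treatment = .key(study_id, year, n_rate, species_id),
    study_treatment      = .key(study_id, n_rate, species_id),
    study_year           = .key(study_id, year, species_id))
  tab_key <- do.call(.key, monos[setdiff(names(monos), c("M", "n_reps"))])
  monos$M[match(key, tab_key)]
}

#' Additive partition of the net biodiversity effect for one community
#'
#' Implements the Loreau–Hector additive partition. With observed mixture
#' yields \eqn{Y_i}, monoculture references \eqn{M_i} and sown proportions
#' \eqn{RY_{e,i}} over the \eqn{n \ge 2} sown species:
#' \deqn{RY_i = Y_i / M_i, \quad \Delta RY_i = RY_i - RY_{e,i}}
#' \deqn{NBE = \sum Y_i - \sum RY_{e,i} M_i}
#' \deqn{CE = n \, \overline{M} \, \overline{\Delta RY}, \quad
#'       SE = n \, \mathrm{cov}(M, \Delta RY)}
#' The covariance uses divisor \eqn{n} (population covariance), which is the
#' variant under which the identity \eqn{NBE = CE + SE} holds exactly; the
#' sample covariance (divisor \eqn{n-1}) breaks it.
#'
#' @param Y numeric vector of observed species yields in the mixture
#'   (g/m\eqn{^2}/year), one element per sown species; species sown but
#'   absent at harvest enter with 0.
#' @param M numeric vector of monoculture references, already adjusted.
#' @param ry_e numeric vector of sown proportions, summing to 1.
#' @param species optional species identifiers for the per-species table.
#' @param check when `TRUE` (default), validates lengths, signs and the
#'   proportion sum.
#' @return list of class `partition_result`: `nbe`, `ce`, `se`, `ryt`,
#'   `n`, and `per_species` (data.frame with `species_id`, `Y`, `M`,
#'   `ry_e`, `ry`, `delta_ry`).
#' @examples
#' p <- partition_effects(Y = c(80, 90), M = c(100, 200), ry_e = c(0.5, 0.5))
#' c(p$nbe, p$ce, p$se)  # 20, 37.5, -17.5
#' @export
partition_effects <- function(Y, M, ry_e, species = NULL, check = TRUE) {
  n <- length(Y)
  if (check) {
    if (n < 2) .stopf("partition undefined for fewer than 2 sown species")
    if (length(M) != n || length(ry_e) != n) {
      .stopf("Y, M and ry_e must have equal length")
    }
    if (any(!is.finite(Y)) || any(Y < 0)) .stopf("yields must be finite and >= 0")
    if (any(!is.finite(M)) || any(M <= 0)) {
      .stopf("monoculture references must be finite and > 0")
    }
    if (abs(sum(ry_e) - 1) > 1e-9) {
      .stopf("sown proportions must sum to 1 (got %.12g)", sum(ry_e))
    }
  }
  ry <- Y / M
  d  <- ry - ry_e
  m_bar <- mean(M)
  d_bar <- mean(d)
  nbe <- sum(Y) - sum(ry_e * M)
  ce  <- n * m_bar * d_bar
  se  <- sum((M - m_bar) * (d - d_bar))   # n * population covariance
  if (is.null(species)) species <- paste0("sp", seq_len(n))
  structure(
    list(nbe = nbe, ce = ce, se = se, ryt = sum(ry), n = n,
         per_species = data.frame(species_id = species, Y = Y, M = M,
                                  ry_e = ry_e, ry = ry, delta_ry = d)),
    class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf(
    "Biodiversity-effect partition (n = %d species)\n  NBE = %.4f  CE = %.4f  SE = %.4f  RYT = %.4f\n",
    x$n, x$nbe, x$ce, x$se, x$ryt))
  invisible(x)
}

#' Partition every mixture plot-year in a dataset
#'
#' Applies [partition_effects()] to each mixture plot-year (two or more sown
#' species) of an annual species-yield dataset, looking up monoculture
#' references in one or more [monoculture_reference()] tables. Tables are
#' tried in order; a match from a table after the first is recorded in the
#' `flags` column as `mono_fallback_<policy>`. Plot-years with any sown
#' species lacking a reference in every table are dropped and reported.
#' Unsown species present in a mixture (invaders) are excluded from the
#' partition and flagged `unsown_invader`.
#'
#' @param dataset annual species-yield data.frame in the canonical schema
#'   (see [validate_dataset()]).
#' @param monos a `monoculture_table` or a list of them (fallback order).
#' @return data.frame with one row per partitioned plot-year: `study_id`,
#'   `plot_id`, `year`, `richness`, `n_rate_kg_ha_yr`, `n_treatment`,
#'   `nbe`, `ce`, `se`, `ryt`, `flags` (semicolon-joined). Dropped
#'   plot-years are attached as `attr(, "drops")`, a data.frame with a
#'   `reason` column.
#' @export
batch_partition <- function(dataset, monos) {
  dataset <- as.data.frame(dataset)
  .assert_columns(dataset,
    c("study_id", "plot_id", "year", "species_id", "biomass_g_m2", "sown",
      "sown_proportion"),
    "dataset")
  if (inherits(monos, "monoculture_table")) monos <- list(monos)
  if (!length(monos) || !all(vapply(monos, inherits, TRUE, "monoculture_table"))) {
    .stopf("monos must be a monoculture_table or a list of them")
  }
  if (!"n_rate_kg_ha_yr" %in% names(dataset)) dataset$n_rate_kg_ha_yr <- 0
  if (!"n_treatment" %in% names(dataset)) {
    dataset$n_treatment <- as.integer(dataset$n_rate_kg_ha_yr > 0)
  }

  empty <- data.frame(study_id = character(), plot_id = character(),
                      year = integer(), richness = integer(),
                      n_rate_kg_ha_yr = numeric(), n_treatment = integer(),
                      nbe = numeric(), ce = numeric(), se = numeric(),
                      ryt = numeric(), flags = character())
  if (!nrow(dataset)) {
    attr(empty, "drops") <- data.frame(study_id = character(),
                                       plot_id = character(),
                                       year = integer(), reason = character())
    return(empty)
  }

  py <- .key(dataset$study_id, dataset$plot_id, dataset$year)
  n_sown_tab <- rowsum(as.numeric(dataset$sown != 0), py, reorder = FALSE)
  richness_of <- stats::setNames(as.integer(n_sown_tab[, 1]), rownames(n_sown_tab))
  is_mix_py <- richness_of[py] >= 2

  invader_py <- unique(py[is_mix_py & dataset$sown == 0 &
                            dataset$biomass_g_m2 > 0])

  mix <- dataset[is_mix_py & dataset$sown != 0, , drop = FALSE]
  if (!nrow(mix)) {
    attr(empty, "drops") <- data.frame(study_id = character(),
                                       plot_id = character(),
                                       year = integer(), reason = character())
    return(empty)
  }

  # Resolve M across the fallback chain.
  M <- rep(NA_real_, nrow(mix))
  src <- rep(NA_integer_, nrow(mix))
  for (i in seq_along(monos)) {
    need <- is.na(M)
    if (!any(need)) break
    got <- .lookup_M(monos[[i]], mix$study_id[need], mix$year[need],
                     mix$n_rate_kg_ha_yr[need], mix$species_id[need])
    M[need] <- got
    src[need][!is.na(got)] <- i
  }

  key <- .key(mix$study_id, mix$plot_id, mix$year)
  missing_py <- unique(key[is.na(M)])
  ok <- !(key %in% missing_py)
  mix <- mix[ok, , drop = FALSE]
  M <- M[ok]; src <- src[ok]; key <- key[ok]

  drops <- if (length(missing_py)) {
    parts <- do.call(rbind, strsplit(missing_py, "\r", fixed = TRUE))
    data.frame(study_id = parts[, 1], plot_id = parts[, 2],
               year = utils::type.convert(parts[, 3], as.is = TRUE),
               reason = "missing_monoculture")
  } else {
    data.frame(study_id = character(), plot_id = character(),
               year = integer(), reason = character())
  }

  if (!nrow(mix)) {
    attr(empty, "drops") <- drops
    return(empty)
  }

  # Vectorised partition per plot-year via grouped sums.
  ry  <- mix$biomass_g_m2 / M
  d   <- ry - mix$sown_proportion
  mat <- cbind(one = 1, Y = mix$biomass_g_m2, ReM = mix$sown_proportion * M,
               M = M, d = d, Md = M * d, ry = ry)
  g <- rowsum(mat, key, reorder = FALSE)
  n    <- g[, "one"]
  mbar <- g[, "M"] / n
  dbar <- g[, "d"] / n
  nbe  <- g[, "Y"] - g[, "ReM"]
  ce   <- n * mbar * dbar
  se   <- g[, "Md"] - n * mbar * dbar

  keep <- !duplicated(key)
  out <- data.frame(
    study_id = mix$study_id[keep], plot_id = mix$plot_id[keep],
    year = mix$year[keep], richness = as.integer(n),
    n_rate_kg_ha_yr = mix$n_rate_kg_ha_yr[keep],
    n_treatment = mix$n_treatment[keep],
    nbe = as.numeric(nbe), ce = as.numeric(ce), se = as.numeric(se),
    ryt = as.numeric(g[, "ry"]), stringsAsFactors = FALSE)

  # Flags: invaders excluded, fallback monoculture matches.
  uk <- key[keep]
  flags <- character(nrow(out))
  flags[uk %in% invader_py] <- "unsown_invader"
  fb <- rowsum(as.numeric(src > 1), key, reorder = FALSE)[, 1] > 0
  for (i in which(fb)) {
    pol <- attr(monos[[max(src[key == uk[i]], na.rm = TRUE)]], "policy")
    flags[i] <- paste(c(flags[i][nzchar(flags[i])],
                        paste0("mono_fallback_", pol)), collapse = ";")
  }
  out$flags <- flags
  rownames(out) <- NULL
  attr(out, "drops") <- drops
  out
}
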