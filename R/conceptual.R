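#' Conceptual cumulative-N curves from time and rate trends
#'
#' Combines a duration trend \eqn{f(t)} and an N-rate trend \eqn{g(r)} of a
#' biodiversity-effect component into a single curve against cumulative N
#' input (\eqn{t \times r}, kg/ha). Two constructions:
#' \describe{
#'   \item{additive}{time and rate act independently; the curve is the
#'     pointwise product \eqn{f(t) g(r)} plotted against \eqn{t r}.}
#'   \item{multiplicative}{time and rate interact; the pointwise products
#'     are treated as data and a quadratic trend in \eqn{\log(t r)} is
#'     fitted and evaluated on the grid.}
#' }
#' An increasing time trend combined with a decreasing rate trend (the
#' typical complementarity-effect shapes) yields a convex curve in log
#' cumulative N — a positive fitted quadratic coefficient.
#'
#' @param time_trend function of time (years).
#' @param rate_trend function of N rate (kg/ha/year).
#' @param mode `"additive"` or `"multiplicative"`.
#' @param time_grid,rate_grid evaluation grids; points with non-positive
#'   cumulative N are omitted with a warning (the curve lives on a log
#'   x-axis).
#' @param component label carried in the result (`"nbe"`, `"ce"`, `"se"`).
#' @return data.frame of class `conceptual_curve` with columns `time`,
#'   `rate`, `cum_n`, `value`; attributes `mode`, `component` and (always)
#'   `quad_coef`, the quadratic-in-log coefficient of the curve.
#' @export
conceptual_trends <- function(time_trend, rate_trend,
                              mode = c("additive", "multiplicative"),
                              time_grid = 1:23,
                              rate_grid = seq(10, 500, by = 10),
                              component = "nbe") {
  mode <- match.arg(mode)
  grid <- expand.grid(time = time_grid, rate = rate_grid)
  grid$cum_n <- grid$time * grid$rate
  bad <- grid$cum_n <= 0
  if (any(bad)) {
    .warnf("%d grid point(s) with non-positive cumulative N omitted",
           sum(bad))
    grid <- grid[!bad, , drop = FALSE]
  }
  raw <- time_trend(grid$time) * rate_trend(grid$rate)
  lc <- log(grid$cum_n)
  qfit <- stats::lm(raw ~ lc + I(lc^2))
  grid$value <- if (mode == "additive") raw else unname(stats::fitted(qfit))
  rownames(grid) <- NULL
  structure(grid, class = c("conceptual_curve", "data.frame"),
            mode = mode, component = component,
            quad_coef = unname(stats::coef(qfit)[3]))
}

#' Quadratic-in-log-cumulative-N coefficient of a curve
#'
#' Fits `value ~ log(cum_n) + log(cum_n)^2` by least squares and returns
#' the quadratic coefficient: positive means the curve is convex on a log
#' cumulative-N axis, negative concave.
#'
#' @param curve a [conceptual_trends()] result, or any data.frame with
#'   `cum_n` and `value` columns.
#' @export
quad_log_coef <- function(curve) {
  lc <- log(curve$cum_n)
  unname(stats::coef(stats::lm(curve$value ~ lc + I(lc^2)))[3])
}
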