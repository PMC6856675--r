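#' Scalar waveform statistics
#'
#' Systolic (maximum), diastolic (minimum) and mean (time-average) value of
#' a uniformly sampled series over the analysis window.
#'
#' @param x numeric series covering at least one full cycle.
#' @return A single number.
#' @export
systolic <- function(x) {
  .check_series(x)
  max(x)
}

#' @rdname systolic
#' @export
diastolic <- function(x) {
  .check_series(x)
  min(x)
}

#' @rdname systolic
#' @export
mean_value <- function(x) {
  .check_series(x)
  mean(x)
}

.check_series <- function(x) {
  if (length(x) == 0L) stop("empty series")
  if (any(!is.finite(x))) stop("series contains non-finite values")
  invisible(x)
}

#' Pressure-volume loop area (stroke work)
#'
#' Signed shoelace area of the closed (V, P) curve over one cycle, returned
#' as an absolute value in mmHg.ml.  The loop is closed between the last and
#' first sample; the result is invariant under cyclic rotation of the
#' starting sample.
#'
#' @param p pressure series (mmHg) over exactly one cycle.
#' @param v volume series (ml) on the same grid.
#' @return Stroke work (mmHg.ml), >= 0.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 2001)[-1]
#' pv_loop_area(60 + 40 * sin(th), 100 + 50 * cos(th))  # ~ pi * 40 * 50
pv_loop_area <- function(p, v) {
  .check_series(p)
  .check_series(v)
  if (length(p) != length(v))
    stop("pressure and volume series must share the sampling grid")
  i2 <- c(seq_along(v)[-1], 1L)
  abs(sum(v * p[i2] - v[i2] * p)) / 2
}

#' Percent change relative to a baseline value
#'
#' `100 * (new - base) / base`.
#'
#' @param new,base numeric; `base` must be nonzero.
#' @return Percent change (positive = increase).
#' @export
percent_change <- function(new, base) {
  if (any(base == 0)) stop("base must be nonzero")
  100 * (new - base) / base
}

#' Laplace wall stress of a thin-walled vessel
#'
#' Circumferential wall stress `H = P * r / (2 * T_wall)` under transmural
#' pressure `P` at radius `r` and wall thickness `T_wall`.
#'
#' @param p transmural pressure.
#' @param r vessel radius.
#' @param t_wall wall thickness, > 0 (same length unit as `r`).
#' @return Wall stress, in the pressure unit of `p`.
#' @export
laplace_wall_stress <- function(p, r, t_wall) {
  if (any(t_wall <= 0)) stop("wall thickness must be > 0")
  p * r / (2 * t_wall)
}

#' Reduce a simulation to its scalar metric table
#'
#' Computes the systolic, diastolic and mean value of every waveform over
#' the analysis window, plus the left-ventricular stroke work (PV-loop area
#' over the last full cycle).
#'
#' @param sim a `"cv_sim"` object.
#' @param scenario label recorded in the output (e.g. a scenario name).
#' @return A data frame with columns `scenario`, `observable`, `statistic`
#'   (`"systolic"`, `"diastolic"`, `"mean"`, or `"stroke_work"`), `value`
#'   and `units`.
#' @export
metric_table <- function(sim, scenario = "baseline") {
  wf <- sim$waveforms
  cols <- setdiff(names(wf), "time")
  rows <- do.call(rbind, lapply(cols, function(cl) {
    x <- wf[[cl]]
    data.frame(scenario = scenario, observable = cl,
               statistic = c("systolic", "diastolic", "mean"),
               value = c(systolic(x), diastolic(x), mean_value(x)),
               units = .obs_unit(cl))
  }))
  n_cycle <- round(sim$period / sim$dt)
  idx <- (nrow(wf) - n_cycle + 1):nrow(wf)
  sw <- pv_loop_area(wf$P_lv[idx], wf$V_lv[idx])
  rbind(rows, data.frame(scenario = scenario, observable = "lv_loop",
                         statistic = "stroke_work", value = sw,
                         units = "mmHg.ml"))
}

.obs_unit <- function(name) {
  if (startsWith(name, "P_")) "mmHg"
  else if (startsWith(name, "Q_")) "ml/s"
  else if (startsWith(name, "V_")) "ml"
  else ""
}

#' Look up one value in a metric table
#'
#' @param metrics a metric table from [metric_table()].
#' @param observable,statistic row selector.
#' @return The value, a single number.
#' @export
metric_value <- function(metrics, observable, statistic) {
  i <- metrics$observable == observable & metrics$statistic == statistic
  if (sum(i) != 1L)
    stop("no unique metric for (", observable, ", ", statistic, ")")
  metrics$value[i]
}
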