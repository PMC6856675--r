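#' Define a named parameter-perturbation scenario
#'
#' A scenario is a named multiplicative perturbation of the baseline
#' parameter set, optionally with a pacing-period override.  The two
#' built-in hypertension scenarios follow the literature-motivated and the
#' exaggerated definitions used for the hypertensive states:
#' * hypertension 1 (`scenario_h1()`): arteriolar resistance x 1.5, aortic
#'   compliance x 0.47, maximal left-ventricular elastance x 2;
#' * hypertension 2 (`scenario_h2()`): arteriolar resistance x 25, aortic
#'   compliance x 0.25, maximal left-ventricular elastance x 10.
#'
#' By default the resistance factor targets the systemic arteriole `R_sar`
#' and the stiffness factor targets the aortic compliance `C_sat` only.
#' Because the model does not functionally distinguish the arteriole from
#' the capillary bed, `resistance_target = "R_scp"` applies the factor there
#' instead; `stiffness_targets` may extend the compliance factor to the
#' venous compliances (`C_svn`, `C_pvn`) for stiffness sweeps that stiffen
#' all large vessels together.
#'
#' @param name scenario label.
#' @param multipliers named numeric vector of strictly positive factors;
#'   names must be parameter names of [cv_params()].  An empty vector is the
#'   baseline (identity) scenario.
#' @param period optional pacing-period override (s); applied with
#'   [set_period()], which rescales the activation timings proportionally.
#' @return An object of class `"cv_scenario"`.
#' @export
#' @examples
#' cv_scenario("stiff_aorta", c(C_sat = 0.5))
#' scenario_h2(period = 0.5)
cv_scenario <- function(name, multipliers = numeric(), period = NULL) {
  multipliers <- unlist(multipliers)
  if (length(multipliers)) {
    if (is.null(names(multipliers)) || any(!nzchar(names(multipliers))))
      stop("multipliers must be named")
    valid <- names(param_units())
    bad <- setdiff(names(multipliers), valid)
    if (length(bad))
      stop("unknown parameter(s) in scenario: ",
           paste(bad, collapse = ", "),
           "; valid names are: ", paste(valid, collapse = ", "))
    if (any(multipliers <= 0)) stop("multipliers must be strictly positive")
  }
  if (!is.null(period) && (!is.numeric(period) || period <= 0))
    stop("period must be a positive number")
  structure(list(name = name, multipliers = multipliers, period = period),
            class = "cv_scenario")
}

#' @rdname cv_scenario
#' @param resistance_target which small-vessel resistance the factor scales.
#' @param stiffness_targets which compliances the stiffness factor scales.
#' @export
scenario_h1 <- function(period = NULL,
                        resistance_target = c("R_sar", "R_scp"),
                        stiffness_targets = "C_sat") {
  resistance_target <- match.arg(resistance_target)
  m <- c(stats::setNames(1.5, resistance_target),
         stats::setNames(rep(0.47, length(stiffness_targets)),
                         stiffness_targets),
         Elv_max = 2)
  cv_scenario("h1", m, period)
}

#' @rdname cv_scenario
#' @export
scenario_h2 <- function(period = NULL,
                        resistance_target = c("R_sar", "R_scp"),
                        stiffness_targets = "C_sat") {
  resistance_target <- match.arg(resistance_target)
  m <- c(stats::setNames(25, resistance_target),
         stats::setNames(rep(0.25, length(stiffness_targets)),
                         stiffness_targets),
         Elv_max = 10)
  cv_scenario("h2", m, period)
}

#' @export
print.cv_scenario <- function(x, ...) {
  cat("<cv_scenario>", x$name, "\n")
  if (length(x$multipliers))
    cat(paste(sprintf("  %s x %g", names(x$multipliers), x$multipliers),
              collapse = "\n"), "\n")
  else cat("  (identity)\n")
  if (!is.null(x$period)) cat("  pacing period:", x$period, "s\n")
  invisible(x)
}

#' Apply a scenario to a parameter set
#'
#' Returns a new parameter set with each named parameter multiplied by its
#' factor and the pacing period overridden if the scenario carries one; the
#' baseline object is not modified.  Scenario application commutes and
#' composes: applying two scenarios in either order equals applying the
#' merged multiplier map.
#'
#' @param params baseline `"cv_params"` parameter set.
#' @param scenario a `"cv_scenario"`.
#' @return The perturbed, validated parameter set.
#' @export
apply_scenario <- function(params, scenario) {
  params <- validate_params(params)
  if (!inherits(scenario, "cv_scenario")) stop("not a cv_scenario")
  m <- scenario$multipliers
  if (length(m)) params[names(m)] <- params[names(m)] * m
  if (!is.null(scenario$period)) params <- set_period(params, scenario$period)
  validate_params(params)
  params
}

#' Simulate a scenario and compare it with baseline
#'
#' Runs the full steady-oscillation protocol for the perturbed parameters
#' and attaches the percent change of every (observable, statistic) pair
#' relative to a baseline run at the same pacing period.
#'
#' @param params baseline `"cv_params"` parameter set.
#' @param scenario a `"cv_scenario"`.
#' @param baseline_metrics optional cached baseline metric table (from
#'   [metric_table()]) at the scenario's pacing period; recomputed when
#'   missing.
#' @param ... passed to [cv_simulate()] (e.g. `duration`, `dt`).
#' @return A list: `metrics` (scenario metric table with a `pct_change`
#'   column), `baseline` (baseline metric table), `sim` (the scenario
#'   `"cv_sim"`), `steady`.
#' @export
run_scenario <- function(params, scenario, baseline_metrics = NULL, ...) {
  params <- validate_params(params)
  if (is.null(baseline_metrics)) {
    base_p <- if (is.null(scenario$period)) params
              else set_period(params, scenario$period)
    base_sim <- cv_simulate(base_p, ...)
    baseline_metrics <- metric_table(base_sim, scenario = "baseline")
  }
  sim <- tryCatch(
    cv_simulate(apply_scenario(params, scenario), ...),
    error = function(e)
      stop("scenario '", scenario$name, "': ", conditionMessage(e)))
  met <- metric_table(sim, scenario = scenario$name)
  key <- paste(met$observable, met$statistic)
  bkey <- paste(baseline_metrics$observable, baseline_metrics$statistic)
  base_vals <- baseline_metrics$value[match(key, bkey)]
  met$baseline <- base_vals
  met$pct_change <- ifelse(base_vals != 0,
                           100 * (met$value - base_vals) / base_vals, NA_real_)
  list(metrics = met, baseline = baseline_metrics, sim = sim,
       steady = sim$steady)
}

#' One- and two-parameter sweeps
#'
#' Simulates the full protocol for every multiplier (or multiplier pair) of
#' one or two parameters, at an optional pacing-period override, and
#' collects the metric tables.  Per-cell integration failures are recorded
#' (`ok = FALSE`) and the sweep continues.
#'
#' @param params baseline `"cv_params"` parameter set.
#' @param parameter,parameter_a,parameter_b parameter name(s) to scale.
#' @param factors,factors_a,factors_b strictly positive multiplier grids;
#'   sorted ascending.
#' @param period optional pacing-period override (s).
#' @param ... passed to [cv_simulate()].
#' @return A data frame of metrics with one block per grid cell, carrying
#'   the factor column(s), the steadiness residual and the `ok` flag.
#' @export
sweep_1d <- function(params, parameter, factors, period = NULL, ...) {
  if (!length(factors) || any(factors <= 0))
    stop("factors must be a non-empty positive vector")
  factors <- sort(factors)
  out <- lapply(factors, function(f) {
    sc <- cv_scenario(sprintf("%s_x%g", parameter, f),
                      stats::setNames(f, parameter), period)
    cell <- tryCatch({
      sim <- cv_simulate(apply_scenario(params, sc), ...)
      met <- metric_table(sim, scenario = sc$name)
      met$steady_residual <- sim$steady$residual
      met$ok <- TRUE
      met
    }, error = function(e) {
      data.frame(scenario = sc$name, observable = NA, statistic = NA,
                 value = NA_real_, units = NA,
                 steady_residual = NA_real_, ok = FALSE)
    })
    cell$factor <- f
    cell
  })
  res <- do.call(rbind, out)
  attr(res, "parameter") <- parameter
  attr(res, "period") <- period
  res
}

#' @rdname sweep_1d
#' @export
grid_2d <- function(params, parameter_a, factors_a, parameter_b, factors_b,
                    period = NULL, ...) {
  if (!length(factors_a) || !length(factors_b) ||
      any(c(factors_a, factors_b) <= 0))
    stop("factor grids must be non-empty and positive")
  factors_a <- sort(factors_a)
  factors_b <- sort(factors_b)
  cells <- expand.grid(factor_a = factors_a, factor_b = factors_b)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    fa <- cells$factor_a[i]; fb <- cells$factor_b[i]
    sc <- cv_scenario(sprintf("%s_x%g.%s_x%g", parameter_a, fa,
                              parameter_b, fb),
                      stats::setNames(c(fa, fb),
                                      c(parameter_a, parameter_b)), period)
    cell <- tryCatch({
      sim <- cv_simulate(apply_scenario(params, sc), ...)
      met <- metric_table(sim, scenario = sc$name)
      met$steady_residual <- sim$steady$residual
      met$ok <- TRUE
      met
    }, error = function(e) {
      data.frame(scenario = sc$name, observable = NA, statistic = NA,
                 value = NA_real_, units = NA,
                 steady_residual = NA_real_, ok = FALSE)
    })
    cell$factor_a <- fa
    cell$factor_b <- fb
    cell
  })
  res <- do.call(rbind, out)
  attr(res, "parameters") <- c(parameter_a, parameter_b)
  attr(res, "period") <- period
  res
}
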