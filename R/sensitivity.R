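#' First-order dynamic local sensitivity of a waveform to a parameter
#'
#' Computes the parameter-scaled local sensitivity
#' `S(t) = p_j * dV_i/dp_j` of an observable `V_i` to a parameter `p_j`,
#' evaluated along the steady waveform, by central finite differences: the
#' full steady protocol is run at `p_j * (1 - h)` and `p_j * (1 + h)` and
#'
#' `S(t) = p_j * (V+ - V-) / (2 h p_j) = (V+(t) - V-(t)) / (2 h)`.
#'
#' Both perturbed runs use identical pacing, so their analysis windows are
#' aligned by simulation time; the trace is returned over the last full
#' cycle of the window.  Sensitivity with respect to the pacing period
#' itself is not supported (phase slip between the two runs would make the
#' pointwise difference meaningless).
#'
#' An evaluation context (e.g. a hypertension scenario) is applied to the
#' parameters before differencing, so sensitivities can be compared between
#' baseline and diseased operating points.
#'
#' @param params baseline `"cv_params"` parameter set.
#' @param parameter name of the parameter `p_j`.
#' @param variable name of the waveform column `V_i` (e.g. `"P_sat"`).
#' @param rel_step relative step `h`, in (0, 0.1]; default 1%.
#' @param context optional `"cv_scenario"` applied before differencing,
#'   or `NULL` for the baseline context.
#' @param ... passed to [cv_simulate()] (e.g. `duration`).
#' @return An object of class `"cv_sens"`: a list with `time` (s, one
#'   cycle, starting at 0), `S` (units of `V_i`), `variable`, `parameter`,
#'   `value` (the parameter value differenced about), `rel_step`, `context`
#'   (label) and `steady` (steadiness of the two perturbed runs).
#' @export
dynamic_sensitivity <- function(params, parameter, variable,
                                rel_step = 0.01, context = NULL, ...) {
  params <- validate_params(params)
  if (!parameter %in% names(param_units()))
    stop("unknown parameter: ", parameter)
  if (parameter %in% c("T", "Ts1", "Ts2", "Tpwb", "Tpww"))
    stop("sensitivity w.r.t. pacing/timing parameters is not supported")
  if (!is.numeric(rel_step) || rel_step <= 0 || rel_step > 0.1)
    stop("rel_step must be in (0, 0.1]")
  ctx_label <- "baseline"
  if (!is.null(context)) {
    params <- apply_scenario(params, context)
    ctx_label <- context$name
  }
  p0 <- params[[parameter]]
  if (p0 == 0) stop("parameter value is zero; relative step undefined")

  up <- params; up[[parameter]] <- p0 * (1 + rel_step)
  dn <- params; dn[[parameter]] <- p0 * (1 - rel_step)
  sim_up <- cv_simulate(validate_params(up), ...)
  sim_dn <- cv_simulate(validate_params(dn), ...)
  if (!variable %in% names(sim_up$waveforms))
    stop("unknown waveform variable: ", variable)

  n_cycle <- round(sim_up$period / sim_up$dt)
  n <- nrow(sim_up$waveforms)
  idx <- (n - n_cycle + 1):n
  S <- sensitivity_kernel(sim_up$waveforms[[variable]][idx],
                          sim_dn$waveforms[[variable]][idx], rel_step)
  structure(list(time = sim_up$waveforms$time[idx] -
                   sim_up$waveforms$time[idx[1]],
                 S = S, variable = variable, parameter = parameter,
                 value = p0, rel_step = rel_step, context = ctx_label,
                 steady = list(up = sim_up$steady, down = sim_dn$steady)),
            class = "cv_sens")
}

#' @export
print.cv_sens <- function(x, ...) {
  cat(sprintf("<cv_sens> S(%s; %s) at %s (p = %g, h = %g%%)\n",
              x$variable, x$parameter, x$context, x$value, 100 * x$rel_step))
  cat(sprintf("  peak |S| = %.4g, cycle-mean |S| = %.4g (%d samples)\n",
              max(abs(x$S)), mean(abs(x$S)), length(x$S)))
  if (!(x$steady$up$achieved && x$steady$down$achieved))
    cat("  warning: a perturbed run did not reach steady oscillation\n")
  invisible(x)
}

#' Central-difference sensitivity kernel
#'
#' The parameter-scaled sensitivity estimator used by
#' [dynamic_sensitivity()]:
#' `S = p * (V(p(1+h)) - V(p(1-h))) / (2 h p) = (v_plus - v_minus) / (2 h)`.
#' For a response linear in the parameter this equals `p * dV/dp` exactly
#' (and, being a central difference, it is exact for quadratic responses
#' too); in general the error is O(h^2).
#'
#' @param v_plus,v_minus response evaluated at `p * (1 + h)` and
#'   `p * (1 - h)`; vectors of equal length.
#' @param rel_step relative step `h`, > 0.
#' @return The sensitivity estimate, in the units of the response.
#' @export
#' @examples
#' p <- 3; h <- 0.02
#' f <- function(p) 5 * p          # linear: S = p f'(p) = f(p)
#' sensitivity_kernel(f(p * (1 + h)), f(p * (1 - h)), h)  # 15
sensitivity_kernel <- function(v_plus, v_minus, rel_step) {
  if (rel_step <= 0) stop("rel_step must be > 0")
  (v_plus - v_minus) / (2 * rel_step)
}

#' Summarize and rank sensitivity traces across contexts
#'
#' Given traces of the same variable (possibly for several parameters and
#' several evaluation contexts), reports the peak `|S|` and cycle-mean `|S|`
#' per trace and ranks parameters within each context by cycle-mean `|S|`
#' (rank 1 = most influential).  Ties share the minimum rank.
#'
#' @param traces a list of `"cv_sens"` objects sharing `variable` and time
#'   grid length.
#' @return A data frame: `context`, `parameter`, `variable`, `peak_abs`,
#'   `mean_abs`, `rank`.
#' @export
compare_contexts <- function(traces) {
  if (!length(traces) || !all(vapply(traces, inherits, TRUE, "cv_sens")))
    stop("traces must be a list of cv_sens objects")
  vars <- unique(vapply(traces, `[[`, "", "variable"))
  if (length(vars) != 1L)
    stop("traces must share the same variable")
  ns <- vapply(traces, function(x) length(x$S), integer(1))
  if (length(unique(ns)) != 1L)
    stop("traces must share the time grid")
  df <- do.call(rbind, lapply(traces, function(x)
    data.frame(context = x$context, parameter = x$parameter,
               variable = x$variable,
               peak_abs = max(abs(x$S)), mean_abs = mean(abs(x$S)))))
  df$rank <- stats::ave(-df$mean_abs, df$context,
                        FUN = function(v) rank(v, ties.method = "min"))
  df[order(df$context, df$rank), ]
}
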