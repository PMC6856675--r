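#' Time-varying chamber elastance
#'
#' Ventricular activation rises as a half-cosine on `[0, Ts1)`, falls on
#' `[Ts1, Ts2)` and is zero for the rest of the cycle; the elastance is
#' `E_min + (E_max - E_min) * e(t)`, so it oscillates between `E_min`
#' (diastole) and exactly `E_max` at the activation peak `t = Ts1`.
#' `atrial_elastance()` uses the analogous full-cosine bump of width `Tpww`
#' beginning at `Tpwb` (wrapping around the cycle end), peaking at
#' `Tpwb + Tpww/2`.
#'
#' @param t time (s); interpreted modulo the pacing period, vectorized.
#' @param period pacing period T (s).
#' @param Ts1,Ts2 ventricular activation peak and end times (s),
#'   `0 < Ts1 < Ts2 < period`.
#' @param Tpwb,Tpww atrial activation onset and width (s).
#' @param Emin,Emax minimum and maximum elastance (mmHg/ml), `Emax >= Emin`.
#' @return Elastance (mmHg/ml), same length as `t`.
#' @export
#' @examples
#' chamber_elastance(0.3, 1, 0.3, 0.45, 0.1, 2.5)  # peak: returns Emax
chamber_elastance <- function(t, period, Ts1, Ts2, Emin, Emax) {
  if (!(Ts1 > 0 && Ts1 < Ts2 && Ts2 < period))
    stop("ventricular timing must satisfy 0 < Ts1 < Ts2 < T")
  if (Emax < Emin) stop("Emax must be >= Emin")
  tc <- t %% period
  e <- ifelse(tc < Ts1, 0.5 * (1 - cos(pi * tc / Ts1)),
       ifelse(tc < Ts2, 0.5 * (1 + cos(pi * (tc - Ts1) / (Ts2 - Ts1))), 0))
  Emin + (Emax - Emin) * e
}

#' @rdname chamber_elastance
#' @export
atrial_elastance <- function(t, period, Tpwb, Tpww, Emin, Emax) {
  if (Tpwb < 0 || Tpwb >= period || Tpww <= 0 || Tpww > period)
    stop("atrial timing must satisfy 0 <= Tpwb < T and 0 < Tpww <= T")
  if (Emax < Emin) stop("Emax must be >= Emin")
  tc <- (t - Tpwb) %% period
  e <- ifelse(tc < Tpww, 0.5 * (1 - cos(2 * pi * tc / Tpww)), 0)
  Emin + (Emax - Emin) * e
}

#' Unidirectional valve flow (square-root orifice law)
#'
#' `Q = CQ * sqrt(P_up - P_down)` for a positive gradient and 0 otherwise:
#' non-negative everywhere and continuous at `P_up = P_down`.
#'
#' @param p_up,p_down pressures upstream and downstream of the valve (mmHg),
#'   vectorized.
#' @param cq valve flow coefficient (ml/(s.mmHg^0.5)), > 0.
#' @return Flow (ml/s).
#' @export
#' @examples
#' valve_flow(104, 100, 350)  # 350 * sqrt(4) = 700
valve_flow <- function(p_up, p_down, cq) {
  if (any(cq <= 0)) stop("cq must be > 0")
  dp <- p_up - p_down
  ifelse(dp > 0, cq * sqrt(pmax(dp, 0)), 0)
}

# canonical state ordering; must match src/cvloop.c
.state_names <- c("V_lv", "V_la", "V_rv", "V_ra",
                  "P_sas", "P_sat", "P_svn", "P_pas", "P_pat", "P_pvn",
                  "Q_sas", "Q_sat", "Q_pas", "Q_pat")

.obs_names <- c("P_lv", "P_la", "P_rv", "P_ra",
                "Q_ao", "Q_mi", "Q_ti", "Q_po", "Q_svn", "Q_pvn")

# parameter packing order for the compiled right-hand side;
# identical to the cv_params() name order, asserted here for safety
.pack_params <- function(params) {
  params <- validate_params(params)
  as.numeric(params[names(param_units())])
}

#' Initial state for the simulation protocol
#'
#' The closed loop conserves total blood volume (the sum of chamber volumes
#' and compliance-stored compartment volumes), so the initial state fixes the
#' circulating volume and, through it, the operating pressures.  The default
#' `"nominal"` state is the distributed reference state of the model: filled
#' ventricles (500 ml each), small atrial volumes (20 ml), systemic arterial
#' compartments primed at 100 mmHg, and every other pressure and flow nil.
#' `"nil"` sets every dynamical variable to zero (an empty circulation,
#' useful for degeneracy checks only).
#'
#' @param params a `"cv_params"` parameter set (unused for the built-in
#'   kinds, accepted for interface symmetry).
#' @param kind `"nominal"` or `"nil"`.
#' @return Named numeric vector of the 14 dynamical variables.
#' @export
cv_init_state <- function(params = cv_params(), kind = c("nominal", "nil")) {
  kind <- match.arg(kind)
  y <- stats::setNames(numeric(14), .state_names)
  if (kind == "nominal") {
    y[c("V_lv", "V_rv")] <- 500
    y[c("V_la", "V_ra")] <- 20
    y[c("P_sas", "P_sat")] <- 100
  }
  y
}

#' Model right-hand side (reference R implementation)
#'
#' Computes the derivative of the 14 dynamical variables: chamber volume
#' rates are valve/venous inflow minus outflow; compartment pressure rates
#' are net inflow divided by compliance; inertance-branch flow rates are the
#' pressure gradient minus the resistive drop, divided by inertance.  The
#' induced total-volume rate (sum of chamber dV/dt plus sum of C dP/dt) is
#' identically zero: the loop is closed.
#'
#' This R implementation is the readable reference; [cv_simulate()] uses the
#' identical compiled version by default.  The signature follows the
#' `deSolve` convention so it can be passed to [deSolve::ode()] directly.
#'
#' @param t time (s).
#' @param state named numeric vector of the 14 dynamical variables
#'   (see [cv_init_state()] for the ordering).
#' @param params a `"cv_params"` parameter set.
#' @return A list: the derivative vector, then the named instantaneous
#'   observables (chamber pressures, valve flows, venous flows).
#' @export
cv_rhs <- function(t, state, params) {
  if (any(!is.finite(state)))
    stop("non-finite state at t = ", t)
  p <- as.list(unclass(params))
  y <- stats::setNames(as.numeric(state), .state_names)

  ev <- chamber_elastance(t, p$T, p$Ts1, p$Ts2, 0, 1)
  ea <- atrial_elastance(t, p$T, p$Tpwb, p$Tpww, 0, 1)

  P_lv <- (p$Elv_min + (p$Elv_max - p$Elv_min) * ev) * (y[["V_lv"]] - p$Vlv0)
  P_rv <- (p$Erv_min + (p$Erv_max - p$Erv_min) * ev) * (y[["V_rv"]] - p$Vrv0)
  P_la <- (p$Ela_min + (p$Ela_max - p$Ela_min) * ea) * (y[["V_la"]] - p$Vla0)
  P_ra <- (p$Era_min + (p$Era_max - p$Era_min) * ea) * (y[["V_ra"]] - p$Vra0)

  Q_ao <- valve_flow(P_lv, y[["P_sas"]], p$CQ_ao)
  Q_mi <- valve_flow(P_la, P_lv, p$CQ_mi)
  Q_ti <- valve_flow(P_ra, P_rv, p$CQ_ti)
  Q_po <- valve_flow(P_rv, y[["P_pas"]], p$CQ_po)
  Q_svn <- (y[["P_svn"]] - P_ra) / p$R_svn
  Q_pvn <- (y[["P_pvn"]] - P_la) / p$R_pvn

  dy <- c(
    V_lv = Q_mi - Q_ao,
    V_la = Q_pvn - Q_mi,
    V_rv = Q_ti - Q_po,
    V_ra = Q_svn - Q_ti,
    P_sas = (Q_ao - y[["Q_sas"]]) / p$C_sas,
    P_sat = (y[["Q_sas"]] - y[["Q_sat"]]) / p$C_sat,
    P_svn = (y[["Q_sat"]] - Q_svn) / p$C_svn,
    P_pas = (Q_po - y[["Q_pas"]]) / p$C_pas,
    P_pat = (y[["Q_pas"]] - y[["Q_pat"]]) / p$C_pat,
    P_pvn = (y[["Q_pat"]] - Q_pvn) / p$C_pvn,
    Q_sas = (y[["P_sas"]] - y[["P_sat"]] - p$R_sas * y[["Q_sas"]]) / p$L_sas,
    Q_sat = (y[["P_sat"]] - y[["P_svn"]] -
               (p$R_sat + p$R_sar + p$R_scp) * y[["Q_sat"]]) / p$L_sat,
    Q_pas = (y[["P_pas"]] - y[["P_pat"]] - p$R_pas * y[["Q_pas"]]) / p$L_pas,
    Q_pat = (y[["P_pat"]] - y[["P_pvn"]] -
               (p$R_pat + p$R_par + p$R_pcp) * y[["Q_pat"]]) / p$L_pat
  )
  list(dy, c(P_lv = P_lv, P_la = P_la, P_rv = P_rv, P_ra = P_ra,
             Q_ao = Q_ao, Q_mi = Q_mi, Q_ti = Q_ti, Q_po = Q_po,
             Q_svn = Q_svn, Q_pvn = Q_pvn))
}

#' Instantaneous derived observables
#'
#' Chamber pressures from the elastance law and valve/venous flows from the
#' pressure gradients, exactly as used inside [cv_rhs()] at the same
#' `(t, state)`.
#'
#' @inheritParams cv_rhs
#' @return Named numeric vector: `P_lv, P_la, P_rv, P_ra, Q_ao, Q_mi, Q_ti,
#'   Q_po, Q_svn, Q_pvn`.
#' @export
cv_observables <- function(t, state, params) {
  cv_rhs(t, state, params)[[2]]
}

#' Total blood volume of a state
#'
#' Sum of the four chamber volumes and the compliance-stored volumes
#' `C_i * P_i` of the six Windkessel compartments.  Conserved exactly by the
#' model equations; used for drift diagnostics.
#'
#' @inheritParams cv_rhs
#' @return Total stressed volume (ml).
#' @export
total_volume <- function(state, params) {
  p <- unclass(params)
  y <- stats::setNames(as.numeric(state), .state_names)
  sum(y[c("V_lv", "V_la", "V_rv", "V_ra")]) +
    p[["C_sas"]] * y[["P_sas"]] + p[["C_sat"]] * y[["P_sat"]] +
    p[["C_svn"]] * y[["P_svn"]] + p[["C_pas"]] * y[["P_pas"]] +
    p[["C_pat"]] * y[["P_pat"]] + p[["C_pvn"]] * y[["P_pvn"]]
}
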