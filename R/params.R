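#' Default parameter set for the closed-loop circulation model
#'
#' Returns the baseline parameter set of the closed-loop lumped-parameter
#' circulation model: a paced four-chamber heart with time-varying elastances,
#' four unidirectional valves, and systemic plus pulmonary Windkessel chains
#' (aortic sinus, artery, arteriole, capillary, vein compartments and their
#' pulmonary analogues).  Values are the published defaults of the Shi
#' four-chamber model as distributed through the CellML repository; units are
#' mmHg, ml and s throughout (resistances mmHg.s/ml, compliances ml/mmHg,
#' inertances mmHg.s^2/ml, valve coefficients ml/(s.mmHg^0.5)).
#'
#' Named values passed via `...` override individual defaults, e.g.
#' `cv_params(R_sar = 0.75)`.  The result is validated before it is returned.
#'
#' @param ... named numeric overrides of individual parameters.
#' @return A named numeric vector of class `"cv_params"` with 41 entries.
#' @seealso [validate_params()], [read_params()], [write_params()]
#' @export
#' @examples
#' p <- cv_params()
#' p[["R_sar"]]
#' p2 <- cv_params(C_sat = 0.8)
cv_params <- function(...) {
  p <- c(
    # pacing and activation timing (s); timings are phases of a 1 s cycle
    # and are rescaled proportionally when the pacing period is changed
    T = 1.0, Ts1 = 0.3, Ts2 = 0.45, Tpwb = 0.92, Tpww = 0.09,
    # chamber elastances (mmHg/ml) and unstressed volumes (ml)
    Elv_max = 2.5,  Elv_min = 0.1,  Vlv0 = 5,
    Ela_max = 0.25, Ela_min = 0.15, Vla0 = 4,
    Erv_max = 1.15, Erv_min = 0.1,  Vrv0 = 10,
    Era_max = 0.25, Era_min = 0.15, Vra0 = 4,
    # valve flow coefficients (ml/(s.mmHg^0.5))
    CQ_ao = 350, CQ_mi = 400, CQ_ti = 400, CQ_po = 350,
    # systemic loop: aortic sinus, artery, arteriole, capillary, vein
    R_sas = 0.003, C_sas = 0.08, L_sas = 6.2e-5,
    R_sat = 0.05,  C_sat = 1.6,  L_sat = 1.7e-3,
    R_sar = 0.5, R_scp = 0.52,
    R_svn = 0.075, C_svn = 20.5,
    # pulmonary loop: artery sinus, artery, arteriole, capillary, vein
    R_pas = 0.002, C_pas = 0.18, L_pas = 5.2e-5,
    R_pat = 0.01,  C_pat = 3.8,  L_pat = 1.7e-3,
    R_par = 0.05, R_pcp = 0.25,
    R_pvn = 0.006, C_pvn = 20.5
  )
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           "; valid names are: ", paste(names(p), collapse = ", "))
    p[names(ov)] <- ov
  }
  class(p) <- "cv_params"
  validate_params(p)
}

#' @export
print.cv_params <- function(x, ...) {
  cat("<cv_params> closed-loop circulation model parameters\n")
  cat(sprintf("  pacing period %.4g s; %d parameters\n", x[["T"]], length(x)))
  u <- param_units()
  df <- data.frame(value = as.numeric(x), unit = u[names(x)],
                   row.names = names(x))
  print(df, ...)
  invisible(x)
}

#' Physical units of each model parameter
#'
#' @return Named character vector mapping parameter names to unit strings.
#' @export
param_units <- function() {
  c(T = "s", Ts1 = "s", Ts2 = "s", Tpwb = "s", Tpww = "s",
    Elv_max = "mmHg/ml", Elv_min = "mmHg/ml", Vlv0 = "ml",
    Ela_max = "mmHg/ml", Ela_min = "mmHg/ml", Vla0 = "ml",
    Erv_max = "mmHg/ml", Erv_min = "mmHg/ml", Vrv0 = "ml",
    Era_max = "mmHg/ml", Era_min = "mmHg/ml", Vra0 = "ml",
    CQ_ao = "ml/(s.mmHg^0.5)", CQ_mi = "ml/(s.mmHg^0.5)",
    CQ_ti = "ml/(s.mmHg^0.5)", CQ_po = "ml/(s.mmHg^0.5)",
    R_sas = "mmHg.s/ml", C_sas = "ml/mmHg", L_sas = "mmHg.s^2/ml",
    R_sat = "mmHg.s/ml", C_sat = "ml/mmHg", L_sat = "mmHg.s^2/ml",
    R_sar = "mmHg.s/ml", R_scp = "mmHg.s/ml",
    R_svn = "mmHg.s/ml", C_svn = "ml/mmHg",
    R_pas = "mmHg.s/ml", C_pas = "ml/mmHg", L_pas = "mmHg.s^2/ml",
    R_pat = "mmHg.s/ml", C_pat = "ml/mmHg", L_pat = "mmHg.s^2/ml",
    R_par = "mmHg.s/ml", R_pcp = "mmHg.s/ml",
    R_pvn = "mmHg.s/ml", C_pvn = "ml/mmHg")
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the model parameters: strictly
#' positive resistances, compliances, inertances and valve coefficients;
#' `E_max >= E_min > 0` per chamber; ventricular activation timings
#' `0 < Ts1 < Ts2 < T`; atrial timings `0 <= Tpwb < T`, `Tpww > 0`.
#' The error message names the offending parameter.
#'
#' @param params object to validate (named numeric vector, see [cv_params()]).
#' @return `params`, invisibly classed as `"cv_params"`, if valid.
#' @export
validate_params <- function(params) {
  p <- unclass(params)
  need <- names(param_units())
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(p)))
    stop("non-finite parameter(s): ",
         paste(names(p)[!is.finite(p)], collapse = ", "))

  pos <- grep("^(R_|C_|L_|CQ_)", need, value = TRUE)
  bad <- pos[p[pos] <= 0]
  if (length(bad))
    stop("parameter must be strictly positive: ", paste(bad, collapse = ", "))

  for (ch in c("lv", "la", "rv", "ra")) {
    emax <- p[[paste0("E", ch, "_max")]]
    emin <- p[[paste0("E", ch, "_min")]]
    if (emin <= 0) stop("parameter must be strictly positive: E", ch, "_min")
    if (emax < emin) stop("E", ch, "_max must be >= E", ch, "_min")
    if (p[[paste0("V", ch, "0")]] < 0) stop("V", ch, "0 must be >= 0")
  }
  if (p[["T"]] <= 0) stop("parameter must be strictly positive: T")
  if (!(p[["Ts1"]] > 0 && p[["Ts1"]] < p[["Ts2"]] && p[["Ts2"]] < p[["T"]]))
    stop("ventricular timing must satisfy 0 < Ts1 < Ts2 < T ",
         sprintf("(Ts1 = %g, Ts2 = %g, T = %g)",
                 p[["Ts1"]], p[["Ts2"]], p[["T"]]))
  if (p[["Tpwb"]] < 0 || p[["Tpwb"]] >= p[["T"]])
    stop("atrial timing must satisfy 0 <= Tpwb < T (Tpwb = ", p[["Tpwb"]], ")")
  if (p[["Tpww"]] <= 0 || p[["Tpww"]] > p[["T"]])
    stop("atrial timing must satisfy 0 < Tpww <= T (Tpww = ", p[["Tpww"]], ")")

  out <- p[need]
  class(out) <- "cv_params"
  invisible(out)
}

#' Read or write a parameter file
#'
#' Flat key-value text format, one `name = value # unit` entry per line;
#' `#` starts a comment.  Values are written with `format(..., digits = 17)`
#' so that a write/read cycle reproduces each double exactly.
#'
#' @param path file path.
#' @return `read_params()` returns a validated `"cv_params"` vector;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2))
    stop("malformed parameter line: ", lines[lengths(kv) != 2][1])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  if (anyNA(vals))
    stop("non-numeric value for parameter: ", keys[is.na(vals)][1])
  if (anyDuplicated(keys))
    stop("duplicated parameter: ", keys[duplicated(keys)][1])
  p <- stats::setNames(vals, keys)
  validate_params(p)
}

#' @rdname read_params
#' @param params a `"cv_params"` parameter set.
#' @export
write_params <- function(params, path) {
  params <- validate_params(params)
  u <- param_units()
  lines <- sprintf("%s = %s # %s", names(params),
                   vapply(as.numeric(params), format, "", digits = 17),
                   u[names(params)])
  writeLines(c("# closed-loop circulation model parameters", lines), path)
  invisible(path)
}

#' Change the pacing period of a parameter set
#'
#' Sets the heart period `T` and rescales the four activation timings
#' (`Ts1`, `Ts2`, `Tpwb`, `Tpww`) proportionally, so that systole and the
#' atrial contraction keep their phase as fractions of the cycle.  This is
#' required for the timing invariants (`Ts2 < T`, `Tpwb < T`) to hold at
#' fast pacing.
#'
#' @param params a `"cv_params"` parameter set.
#' @param period new pacing period (s), > 0.
#' @return The rescaled parameter set.
#' @export
set_period <- function(params, period) {
  params <- validate_params(params)
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stop("period must be a single positive number")
  f <- period / params[["T"]]
  params[c("T", "Ts1", "Ts2", "Tpwb", "Tpww")] <-
    params[c("T", "Ts1", "Ts2", "Tpwb", "Tpww")] * f
  validate_params(params)
  params
}
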