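#' Generate a synthetic neonatal blood-pressure series
#'
#' Emulates the shape of the observed clinical course: a linear rise of the
#' systolic pressure from a baseline level up to the day treatment takes
#' effect, followed by an exponential relaxation back toward the baseline,
#' with independent Gaussian observation noise.  Deterministic for a fixed
#' seed.  Defaults mirror the reported course: 90 mmHg on day 1 rising to
#' about 115 mmHg by day 15, then declining to roughly 105 mmHg by day 23.
#'
#' @param seed integer RNG seed.
#' @param days number of daily observations (>= 2).
#' @param baseline pre-illness systolic level (mmHg), also the decay floor.
#' @param rise pre-treatment linear rise (mmHg/day).
#' @param treatment_day day the rise peaks and the decay starts.
#' @param decay post-treatment exponential decay rate (1/day).
#' @param noise_sd observation noise standard deviation (mmHg), >= 0.
#' @return A `"bp_series"` with an additional `trend_mmHg` column (the
#'   noise-free trend).
#' @export
#' @examples
#' s <- gen_bp_series(seed = 1)
#' head(s)
gen_bp_series <- function(seed, days = 23, baseline = 90, rise = 25 / 14,
                          treatment_day = 15, decay = 0.064,
                          noise_sd = 3) {
  if (days < 2) stop("days must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  day <- seq_len(days)
  peak <- baseline + rise * (treatment_day - 1)
  trend <- ifelse(day <= treatment_day,
                  baseline + rise * (day - 1),
                  baseline + (peak - baseline) * exp(-decay * (day - treatment_day)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  noise <- stats::rnorm(days, 0, noise_sd)
  s <- bp_series(day, trend + noise)
  s$trend_mmHg <- trend
  s
}

# save/restore the global RNG state so generators are pure in (config, seed)
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate an ensemble of perturbed parameter sets
#'
#' Draws `n` parameter sets from the baseline by multiplying each named
#' parameter with an independent log-uniform factor within the given
#' bounds.  Log-uniform sampling mirrors the multiplicative language of the
#' perturbation scenarios (e.g. "25-fold", "0.25 of baseline").  Every
#' draw is validated against the parameter-set invariants.
#'
#' @param baseline a `"cv_params"` parameter set.
#' @param bounds named list; each element is `c(low, high)` multiplier
#'   bounds (positive, `low <= high`) for one parameter.
#' @param n ensemble size.
#' @param seed integer RNG seed.
#' @return A list of `n` validated `"cv_params"` objects; the drawn factors
#'   are attached as attribute `"factors"` (an `n` x `length(bounds)`
#'   matrix).
#' @export
gen_parameter_ensemble <- function(baseline, bounds, n, seed) {
  baseline <- validate_params(baseline)
  if (!length(bounds) || is.null(names(bounds)))
    stop("bounds must be a named list of c(low, high)")
  bad <- setdiff(names(bounds), names(param_units()))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  bm <- do.call(rbind, bounds)
  if (ncol(bm) != 2 || any(bm <= 0) || any(bm[, 1] > bm[, 2]))
    stop("each bound must be c(low, high) with 0 < low <= high")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fac <- matrix(exp(stats::runif(n * nrow(bm),
                                 rep(log(bm[, 1]), each = n),
                                 rep(log(bm[, 2]), each = n))),
                nrow = n, dimnames = list(NULL, names(bounds)))
  ens <- lapply(seq_len(n), function(i) {
    p <- baseline
    p[colnames(fac)] <- p[colnames(fac)] * fac[i, ]
    validate_params(p)
    p
  })
  attr(ens, "factors") <- fac
  ens
}

#' Analytic two-element Windkessel solution (solver oracle)
#'
#' Closed-form pressure of the RC Windkessel `dP/dt = -P/(RC) + Q_in/C`
#' driven by a square-pulse inflow train: within each constant-inflow
#' segment the solution is `P(t) = Q R + (P_k - Q R) exp(-(t - t_k)/(RC))`,
#' advanced exactly across segment boundaries.  Used as an independent
#' analytic oracle for the numerical integrator.
#'
#' @param R resistance (mmHg.s/ml), > 0.
#' @param C compliance (ml/mmHg), > 0.
#' @param times evaluation times (s), non-negative, increasing.
#' @param amplitude inflow during the "on" phase (ml/s).
#' @param duty fraction of each pulse period with inflow on, in \[0, 1\].
#' @param pulse_period pulse repetition period (s), > 0.
#' @param P0 initial pressure (mmHg).
#' @return Numeric vector `P(times)` (mmHg).
#' @export
#' @examples
#' # pure decay: P(RC) = P0 / e
#' windkessel_oracle(1, 2, times = 2, amplitude = 0, P0 = 10)
windkessel_oracle <- function(R, C, times, amplitude = 0, duty = 0.5,
                              pulse_period = 1, P0 = 0) {
  if (R <= 0 || C <= 0) stop("R and C must be > 0")
  if (duty < 0 || duty > 1) stop("duty must be in [0, 1]")
  if (pulse_period <= 0) stop("pulse_period must be > 0")
  if (any(diff(times) < 0) || any(times < 0))
    stop("times must be non-negative and non-decreasing")
  tau <- R * C
  # segment boundaries: pulse edges up to max(times)
  t_max <- max(times)
  edges <- sort(unique(c(0,
                         seq(0, t_max + pulse_period, by = pulse_period),
                         seq(0, t_max + pulse_period,
                             by = pulse_period) + duty * pulse_period)))
  edges <- edges[edges <= t_max + pulse_period]
  inflow_at <- function(t) {
    ph <- t %% pulse_period
    ifelse(ph < duty * pulse_period, amplitude, 0)
  }
  P <- numeric(length(times))
  p_k <- P0
  k <- 1L
  for (i in seq_along(times)) {
    # advance the exact solution across whole segments up to times[i]
    while (k < length(edges) && edges[k + 1] <= times[i]) {
      q <- inflow_at((edges[k] + edges[k + 1]) / 2)
      p_k <- q * R + (p_k - q * R) * exp(-(edges[k + 1] - edges[k]) / tau)
      k <- k + 1L
    }
    q <- inflow_at((edges[k] + times[i]) / 2)
    P[i] <- q * R + (p_k - q * R) * exp(-(times[i] - edges[k]) / tau)
  }
  P
}
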