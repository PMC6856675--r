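test_that("no-pumping degenerate run stays identically zero and is steady", {
  p <- no_pump_params()
  sim <- cv_simulate(p, duration = 30, window = 4,
                     init = cv_init_state(p, kind = "nil"))
  wf <- sim$waveforms[setdiff(names(sim$waveforms), "time")]
  expect_true(all(abs(as.matrix(wf)) < 1e-10))
  expect_true(sim$steady$achieved)
  expect_equal(sim$steady$residual, 0)
})

test_that("protocol preconditions are enforced", {
  p <- cv_params()
  expect_error(cv_simulate(p, duration = 5), "10 pacing periods")
  expect_error(cv_simulate(p, duration = 30, window = 40), "<= duration")
  expect_error(cv_simulate(p, duration = 30, window = 1.5), "2 pacing periods")
  expect_error(cv_simulate(p, duration = 30, init = rep(NA_real_, 14)),
               "finite")
})

test_that("check_steady measures cycle-to-cycle drift correctly", {
  dt <- 1e-3
  tm <- seq(0, 6 - dt, by = dt)
  # exactly periodic
  wf <- data.frame(time = tm, x = sin(2 * pi * tm))
  r <- check_steady(wf, period = 1, tolerance = 1e-3)
  expect_true(r$achieved)
  expect_equal(r$residual, 0, tolerance = 1e-12)
  # constant series: steady state, residual 0 despite zero range
  wf$x <- 5
  expect_equal(check_steady(wf, period = 1)$residual, 0)
  # 10% amplitude growth per cycle: sup cycle difference 0.1, last-cycle
  # range 3.0 (amplitude 1.5), so the normalized residual is 1/30
  amp <- 1 + 0.1 * floor(tm)
  wf$x <- amp * sin(2 * pi * tm)
  r <- check_steady(wf, period = 1, tolerance = 1e-3)
  expect_false(r$achieved)
  expect_equal(r$residual, 0.1 / 3.0, tolerance = 0.01)
  expect_error(check_steady(wf[tm < 1.5, ], period = 1), "2 full")
})

test_that("integrator reproduces the analytic RC Windkessel", {
  R <- 1.2; C <- 1.5
  rhs <- function(t, y, parms) {
    q <- if (t %% 1 < 0.5) 80 else 0
    list(-y / (R * C) + q / C)
  }
  times <- seq(0, 10, by = 0.001)
  num <- deSolve::ode(c(P = 20), times, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10, hmax = 0.01)[, "P"]
  exact <- windkessel_oracle(R, C, times, amplitude = 80, duty = 0.5,
                             pulse_period = 1, P0 = 20)
  expect_lt(max(abs(num - exact)) / max(abs(exact)), 1e-6)
})

test_that("windkessel oracle closed-form identities", {
  # pure decay reaches P0/e after one time constant
  expect_equal(windkessel_oracle(2, 3, times = 6, amplitude = 0, P0 = 10),
               10 / exp(1))
  # constant inflow (duty 1) settles at Q*R
  expect_equal(windkessel_oracle(1.5, 2, times = 200, amplitude = 40,
                                 duty = 1, P0 = 0),
               40 * 1.5, tolerance = 1e-8)
})

test_that("solver-order convergence: halving the max step barely moves metrics", {
  p <- cv_params()
  s1 <- cv_simulate(p, duration = 60, window = 4, hmax = p[["T"]] / 100)
  s2 <- cv_simulate(p, duration = 60, window = 4, hmax = p[["T"]] / 200)
  for (cl in c("P_sat", "P_pat")) {
    expect_lt(abs(systolic(s2$waveforms[[cl]]) / systolic(s1$waveforms[[cl]]) - 1),
              1e-3)
    expect_lt(abs(diastolic(s2$waveforms[[cl]]) / diastolic(s1$waveforms[[cl]]) - 1),
              1e-3)
  }
})

test_that("tolerance robustness: rtol 1e-6 vs 1e-9 agree on systolic P_sat", {
  p <- cv_params()
  a <- cv_simulate(p, duration = 60, window = 4, rtol = 1e-6, atol = 1e-6)
  b <- cv_simulate(p, duration = 60, window = 4, rtol = 1e-9, atol = 1e-9)
  expect_lt(abs(systolic(a$waveforms$P_sat) /
                  systolic(b$waveforms$P_sat) - 1), 0.005)
})

test_that("waveform CSV and manifest round-trip", {
  sim <- cv_simulate(cv_params(), duration = 30, window = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_waveforms(sim, f)
  wf <- read_waveforms(f)
  expect_equal(wf$P_sat, sim$waveforms$P_sat, tolerance = 1e-12)
  expect_named(wf, names(sim$waveforms))
  j <- withr::local_tempfile(fileext = ".json")
  write_manifest(sim, j)
  man <- jsonlite::read_json(j)
  expect_equal(man$protocol$duration_s, 30)
  expect_equal(man$parameters$R_sar, 0.5)
  expect_true(man$steady$achieved)
})
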