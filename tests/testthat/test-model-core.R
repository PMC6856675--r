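test_that("ventricular elastance hits its bounds at the right phases", {
  Emin <- 0.1; Emax <- 2.5
  E <- function(t) chamber_elastance(t, 1, 0.3, 0.45, Emin, Emax)
  expect_equal(E(0), Emin)                   # activation zero at cycle onset
  expect_equal(E(0.45), Emin)                # relaxation complete
  expect_equal(E(0.7), Emin)
  # analytic maximizer of the piecewise-cosine activation is t = Ts1
  expect_equal(E(0.3), Emax)
  tt <- seq(0, 0.999, by = 1e-3)
  expect_true(all(E(tt) >= Emin - 1e-12 & E(tt) <= Emax + 1e-12))
  expect_lt(max(E(tt)) - Emax, 1e-12)
  expect_equal(which.max(E(tt)), which(tt == 0.3))
})

test_that("elastances are periodic and continuous", {
  tt <- seq(0, 3, by = 1e-3)
  Ev <- chamber_elastance(tt, 1, 0.3, 0.45, 0.1, 2.5)
  expect_equal(Ev, chamber_elastance(tt + 1, 1, 0.3, 0.45, 0.1, 2.5),
               tolerance = 1e-12)
  # no jump anywhere on a fine grid: the steepest analytic slope is
  # (Emax - Emin) * pi / (2 * (Ts2 - Ts1)) = 25.1 /s, i.e. ~0.025 per ms
  expect_lt(max(abs(diff(Ev))), 0.026)
  Ea <- atrial_elastance(tt, 1, 0.92, 0.09, 0.15, 0.25)
  expect_equal(Ea, atrial_elastance(tt + 2, 1, 0.92, 0.09, 0.15, 0.25),
               tolerance = 1e-12)
  expect_equal(max(Ea), 0.25)   # peak maps to Emax despite the wrap
  expect_equal(Ea[1], 0.15 + 0.1 * 0.5 * (1 - cos(2 * pi * 0.08 / 0.09)))
})

test_that("invalid activation timings are rejected", {
  expect_error(chamber_elastance(0, 1, 0.5, 0.45, 0.1, 2.5), "Ts1 < Ts2")
  expect_error(chamber_elastance(0, 1, 0.3, 1.1, 0.1, 2.5), "Ts1 < Ts2")
  expect_error(chamber_elastance(0, 1, 0.3, 0.45, 2.5, 0.1), "Emax")
  expect_error(atrial_elastance(0, 1, 1.2, 0.09, 0.1, 0.2), "Tpwb")
})

test_that("valve law: closed on reverse gradient, orifice open", {
  expect_equal(valve_flow(95, 100, 350), 0)
  expect_equal(valve_flow(101, 100, 123), 123)     # sqrt(1) = 1
  expect_equal(valve_flow(104, 100, 350), 700)     # 350 * sqrt(4)
  expect_equal(valve_flow(100, 100, 350), 0)       # continuous at zero
  dp <- seq(-1, 1, by = 1e-4)
  q <- valve_flow(100 + dp, 100, 350)
  expect_true(all(q >= 0))
  expect_lt(max(abs(diff(q))), 350 * sqrt(1e-4) + 1e-9)  # no jump at 0
  expect_error(valve_flow(1, 0, -2), "cq")
})

test_that("quiescent state with no pumping has a zero derivative", {
  p <- no_pump_params()
  y <- cv_init_state(p, kind = "nil")
  d <- cv_rhs(0, y, p)[[1]]
  expect_equal(unname(d), rep(0, 14))
})

test_that("closed loop: induced total-volume rate is identically zero", {
  p <- cv_params()
  caps <- c(p[["C_sas"]], p[["C_sat"]], p[["C_svn"]],
            p[["C_pas"]], p[["C_pat"]], p[["C_pvn"]])
  for (seed in 1:20) {
    y <- random_state(seed)
    t <- stats::runif(1, 0, 2)
    d <- cv_rhs(t, y, p)[[1]]
    vol_rate <- sum(d[1:4]) + sum(caps * d[5:10])
    expect_lt(abs(vol_rate), 1e-9 * max(abs(d)))
  }
})

test_that("ventricular volume balance matches hand-computed valve flows", {
  p <- cv_params()
  y <- random_state(3)
  t <- 0.15  # mid-systole
  obs <- cv_observables(t, y, p)
  d <- cv_rhs(t, y, p)[[1]]
  q_ao <- valve_flow(obs[["P_lv"]], y[["P_sas"]], p[["CQ_ao"]])
  q_mi <- valve_flow(obs[["P_la"]], obs[["P_lv"]], p[["CQ_mi"]])
  expect_equal(unname(d["V_lv"]), q_mi - q_ao)
  # chamber pressure law through the unstressed point
  y0 <- y; y0["V_lv"] <- p[["Vlv0"]]
  expect_equal(unname(cv_observables(t, y0, p)[["P_lv"]]), 0)
})

test_that("observables agree with the flows used inside the RHS", {
  p <- cv_params()
  for (seed in c(7, 11)) {
    y <- random_state(seed)
    t <- stats::runif(1, 0, 1)
    rhs_out <- cv_rhs(t, y, p)
    expect_identical(cv_observables(t, y, p), rhs_out[[2]])
    # closed aortic valve whenever P_lv <= P_sas
    obs <- rhs_out[[2]]
    if (obs[["P_lv"]] <= y[["P_sas"]]) expect_equal(obs[["Q_ao"]], 0)
  }
})

test_that("non-finite states are rejected", {
  p <- cv_params()
  y <- cv_init_state(p)
  y["P_sat"] <- NaN
  expect_error(cv_rhs(0, y, p), "non-finite")
})

test_that("compiled and R right-hand sides integrate identically", {
  p <- cv_params()
  a <- cv_simulate(p, duration = 30, window = 3, use_compiled = TRUE)
  b <- cv_simulate(p, duration = 30, window = 3, use_compiled = FALSE)
  for (cl in c("P_sat", "V_lv", "Q_sat", "P_pat"))
    expect_equal(a$waveforms[[cl]], b$waveforms[[cl]], tolerance = 1e-6)
})
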