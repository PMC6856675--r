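test_that("bp series construction enforces its invariants", {
  expect_s3_class(bp_series(1:3, c(90, 95, 100)), "bp_series")
  expect_error(bp_series(c(1, 1, 2), c(90, 95, 100)), "increasing")
  expect_error(bp_series(1:2, c(90, 400)), "\\(20, 300\\)")
  expect_error(bp_series(1:2, 90), "equal length")
})

test_that("running mean: identity, constants and hand-computed edges", {
  expect_equal(running_mean(c(1, 2, 3, 4, 5), window = 3),
               c(1.5, 2, 3, 4, 4.5))
  x <- c(88, 92, 95, 99, 103)
  expect_equal(running_mean(x, window = 1), x)
  expect_equal(running_mean(rep(7, 10), window = 5), rep(7, 10))
  expect_error(running_mean(x, window = 4), "odd")
  expect_error(running_mean(x, window = 7), "length")
  s <- running_mean(bp_series(1:5, x), window = 3)
  expect_equal(s$smoothed_mmHg, running_mean(x, 3))
  expect_equal(nrow(s), 5)
})

test_that("running mean is linear, shift-equivariant and range-bounded", {
  set.seed(7)
  x <- 90 + cumsum(stats::rnorm(23))
  y <- 100 + 5 * sin(seq_len(23))
  w <- 5
  expect_equal(running_mean(2 * x + 3 * y, w),
               2 * running_mean(x, w) + 3 * running_mean(y, w))
  expect_equal(running_mean(x + 10, w), running_mean(x, w) + 10)
  expect_true(all(running_mean(x, w) <= max(x) & running_mean(x, w) >= min(x)))
  # lag-shift equivariance away from the edges
  sm <- running_mean(x, w)
  sm_shift <- running_mean(c(x[-1], x[23]), w)
  expect_equal(sm_shift[3:20], sm[4:21])
})

test_that("hypertension flags use strict inequality and summarize the rise", {
  s <- bp_series(1:5, c(90, 92, 91, 90, 89))
  fl <- hypertension_flags(s, reference = 100, window = 1)
  expect_equal(fl$n_flagged, 0)
  # constant series exactly at the reference is not flagged
  fl2 <- hypertension_flags(bp_series(1:4, rep(100, 4)), reference = 100,
                            window = 1)
  expect_equal(fl2$n_flagged, 0)
  # rise from 90 to 115: 27.8% and the days above reference are flagged
  ramp <- bp_series(1:15, seq(90, 115, length.out = 15))
  fl3 <- hypertension_flags(ramp, reference = 100, window = 1)
  expect_equal(fl3$pct_rise, 27.7778, tolerance = 1e-4)
  expect_equal(fl3$peak_mmHg, 115)
  expect_equal(fl3$peak_day, 15)
  expect_equal(fl3$n_flagged, sum(ramp$systolic_mmHg > 100))
  expect_error(hypertension_flags(ramp, reference = -1), "reference")
})

test_that("bp CSV reader round-trips through the schema", {
  f <- withr::local_tempfile(fileext = ".csv")
  s <- bp_series(1:6, c(88, 90, 97, 104, 109, 102))
  utils::write.csv(s, f, row.names = FALSE)
  expect_equal(read_bp_series(f)$systolic_mmHg, s$systolic_mmHg)
  writeLines("a,b\n1,2", f)
  expect_error(read_bp_series(f), "expected columns")
})

test_that("diameter changes: identity, doubling, missing sites", {
  sites <- c("outflow tract", "sinuses of valsalva",
             "sinotubular junction", "tubular ascending aorta")
  tab <- diameter_table(rep(c(1, 150), each = 4), rep(sites, 2),
                        c(0.7, 0.9, 0.75, 0.65, 0.7, 0.9, 0.75, 0.65))
  ch <- diameter_changes(tab, 1, 150)
  expect_equal(ch$pct_change, rep(0, 4))
  tab2 <- tab
  tab2$diameter_cm[5:8] <- tab2$diameter_cm[1:4] * 2
  expect_equal(diameter_changes(tab2, 1, 150)$pct_change, rep(100, 4))
  # site labels normalize case and whitespace
  expect_silent(diameter_table(1, "  Outflow   Tract ", 0.7))
  expect_error(diameter_table(1, "aortic arch", 1), "unknown aortic site")
  expect_error(diameter_changes(tab[-2, ], 1, 150), "sinuses of valsalva")
})

test_that("swapping exams maps x% to the reciprocal change", {
  sites <- c("outflow tract", "sinuses of valsalva",
             "sinotubular junction", "tubular ascending aorta")
  tab <- diameter_table(rep(c(1, 150), each = 4), rep(sites, 2),
                        c(0.7, 0.9, 0.75, 0.65, 0.66, 1.12, 0.86, 0.76))
  fwd <- diameter_changes(tab, 1, 150)$pct_change
  rev <- diameter_changes(tab, 150, 1)$pct_change
  expect_equal(rev, 100 * (1 / (1 + fwd / 100) - 1), tolerance = 1e-12)
})

test_that("shipped synthetic diameter table reproduces its design changes", {
  f <- system.file("extdata", "synthetic_aortic_diameters.csv",
                   package = "cvloop")
  tab <- read_diameters(f)
  ch <- diameter_changes(tab, 1, 150)
  expect_equal(ch$pct_change, c(-5, 25.1, 14.8, 17.1), tolerance = 0.01)
})
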