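test_that("trace correction applies backgrounds and leakage exactly", {
  tr <- fret_trace(rep(100, 10), rep(50, 10))
  # identity when no corrections
  id <- correct_trace(tr)
  expect_identical(id$I_D, tr$I_D)
  expect_identical(id$I_A, tr$I_A)
  ct <- correct_trace(tr, background_donor = 10, background_acceptor = 10,
                      leakage_alpha = 0.1)
  expect_equal(ct$I_D, rep(90, 10))
  expect_equal(ct$I_A, rep(31, 10))
  # donor-only closure: generator leakage removed by matching alpha
  cfg <- trace_gen_config(n_traces = 20, true_efficiency = 0.01,
                          efficiency_sd = 0, noise_sd = 0,
                          leakage_alpha = 0.08, background_donor = 40,
                          background_acceptor = 70, bleach_rate = 0,
                          seed = 2)
  traces <- gen_fret_traces(cfg)
  resid <- vapply(traces, function(tr) {
    mean(correct_trace(tr, 40, 70, 0.08)$I_A)
  }, numeric(1))
  # corrected acceptor carries only the tiny true transfer (E*total)
  expect_equal(mean(resid), 0.01 * 1000, tolerance = 1e-9)
})

test_that("per-frame efficiency covers the symmetric, skewed and limit
           cases and is scale-invariant", {
  tr <- fret_trace(c(50, 32, 0), c(50, 68, 10))
  E <- efficiency_trace(tr)
  expect_equal(E, c(0.5, 0.68, 1))
  scaled <- fret_trace(tr$I_D * 3.7, tr$I_A * 3.7)
  expect_equal(efficiency_trace(scaled), E, tolerance = 1e-12)
  dead <- fret_trace(c(0, 0), c(0, 0))
  expect_error(efficiency_trace(dead), class = "fret_empty_trace")
})

test_that("acceptor bleach detection finds a constructed change point and
           short traces are rejected", {
  I_A <- c(rep(500, 39), rep(20, 30))
  I_D <- c(rep(500, 39), rep(1000, 30))
  tr <- fret_trace(I_D, I_A)
  s <- trace_efficiency(tr)
  expect_equal(s$bleach_frame, 40)
  expect_equal(s$E_mean, 0.5)
  expect_equal(s$n_frames, 39)
  # constant trace, no bleach
  const <- trace_efficiency(fret_trace(rep(400, 50), rep(600, 50)))
  expect_true(is.na(const$bleach_frame))
  expect_equal(const$E_mean, 0.6)
  # 3-frame trace cannot yield 5 valid frames
  short <- trace_efficiency(fret_trace(rep(1, 3), rep(1, 3)))
  expect_true(short$rejected)
})

test_that("efficiency peak fitting handles delta, unimodal and bimodal
           distributions", {
  expect_error(fit_efficiency_peak(rep(0.4, 10)), "at least 30")
  delta <- fit_efficiency_peak(rep(0.4, 100))
  expect_equal(delta$E_mp, 0.4)
  set.seed(5)
  uni <- fit_efficiency_peak(rnorm(400, 0.68, 0.04))
  expect_equal(uni$E_mp, 0.68, tolerance = 0.02)
  bim <- c(rnorm(150, 0.3, 0.03), rnorm(250, 0.7, 0.03))
  ws <- testthat::capture_warnings(res <- fit_efficiency_peak(bim))
  expect_true(any(grepl("multimodal", ws)))
  expect_equal(res$E_mp, 0.7, tolerance = 0.05)
})

test_that("peak recovery tightens as the trace count grows", {
  errs <- sapply(1:10, function(s) {
    sapply(c(100, 500), function(n) {
      cfg <- trace_gen_config(n_traces = n, true_efficiency = 0.68,
                              seed = 1000 + s)
      abs(analyze_fret_traces(gen_fret_traces(cfg))$peak$E_mp - 0.68)
    })
  })
  expect_lt(stats::median(errs[2, ]), stats::median(errs[1, ]) + 1e-9)
  expect_lt(stats::median(errs[2, ]), 0.02)
})

test_that("Forster calibration and inversion are exact inverses", {
  cal <- calibrate_R0(0.5, 4.0)
  expect_equal(cal$R0, 4.0)
  cal2 <- calibrate_R0(0.68, 4.62)
  expect_equal(cal2$R0, 5.24, tolerance = 1e-3)
  # monotone in d_ref
  expect_gt(calibrate_R0(0.68, 5.0)$R0, cal2$R0)
  expect_equal(efficiency_to_distance(0.5, cal), 4.0)
  # round trip d -> E -> d to 1e-12 relative
  d <- seq(3, 8, by = 0.25)
  E <- 1 / (1 + (d / cal2$R0)^6)
  expect_equal(efficiency_to_distance(E, cal2), d, tolerance = 1e-12)
  expect_error(calibrate_R0(1, 4.62), "inside")
  expect_error(efficiency_to_distance(0, cal2), "inside")
})
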