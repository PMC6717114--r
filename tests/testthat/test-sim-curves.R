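test_that("curve generator honours counts, labels and reproducibility", {
  cfg <- curve_gen_config(n_curves = 60, specific_fraction = 0,
                          velocities = 1000, seed = 4)
  cs <- gen_force_curves(cfg)
  expect_length(cs, 60)
  labs <- vapply(cs, function(ci) ci$truth$label, character(1))
  expect_false(any(labs == "specific"))
  # bit-reproducible under the same config + seed
  cs2 <- gen_force_curves(cfg)
  expect_identical(cs[[7]]$force, cs2[[7]]$force)
  expect_identical(cs[[7]]$piezo, cs2[[7]]$piezo)
  # config validation
  expect_error(curve_gen_config(specific_fraction = 1.2), "specific_fraction")
  expect_error(curve_gen_config(specific_fraction = 0.05,
                                velocities = numeric(0)), "velocity")
})

test_that("noiseless rupture forces peak at the closed-form most probable
           force", {
  b <- bell_evans_params(4.5e-3, 0.18)
  p <- fjc_params(55, 0.7)
  cfg <- curve_gen_config(n_curves = 5000, specific_fraction = 1,
                          velocities = 1000, force_noise_sd = 0,
                          bell = b, tether = p, n_samples = 64, seed = 8)
  cs <- gen_force_curves(cfg)
  F_rup <- vapply(cs, function(ci) ci$truth$rupture_force, numeric(1))
  kde <- stats::density(F_rup, bw = "SJ")
  mode_hat <- kde$x[which.max(kde$y)]
  th <- most_probable_force_theory(b, p, 25, 1000, 298)$F_mp
  expect_equal(mode_hat, th, tolerance = 0.10)
})

test_that("simulated rupture-force survival matches the hazard integral
           (Kolmogorov-Smirnov)", {
  b <- bell_evans_params(4.5e-3, 0.18)
  p <- fjc_params(55, 0.7)
  v <- 1000; kc <- 25
  cfg <- curve_gen_config(n_curves = 2000, specific_fraction = 1,
                          velocities = v, kc = kc, force_noise_sd = 0,
                          bell = b, tether = p, n_samples = 64, seed = 9)
  cs <- gen_force_curves(cfg)
  F_rup <- vapply(cs, function(ci) ci$truth$rupture_force, numeric(1))
  # independent trapezoid integration of H(F) = int koff/vF dF
  Fg <- seq(1e-3, max(F_rup) * 1.5, length.out = 20000)
  integrand <- bell_off_rate(Fg, b, 298) / loading_rate(Fg, p, kc, v, 298)
  H <- cumsum(c(0, diff(Fg) * (integrand[-1] + integrand[-length(Fg)]) / 2))
  cdf <- function(q) {
    stats::approx(Fg, 1 - exp(-H), xout = q, rule = 2)$y
  }
  ks <- suppressWarnings(stats::ks.test(F_rup, cdf))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("an experiment-scale request of 5625 curves is met exactly", {
  cfg <- curve_gen_config(n_curves = 5625, specific_fraction = 0.05,
                          n_samples = 32, seed = 10)
  cs <- gen_force_curves(cfg)
  expect_length(cs, 5625)
})
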