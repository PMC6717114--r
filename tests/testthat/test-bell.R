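test_that("Bell off-rate and tilt energy evaluate the escape-landscape
           expressions", {
  p <- bell_evans_params(4.5e-3, 0.18)
  expect_equal(bell_off_rate(0, p), 4.5e-3)
  # orthogonal pull leaves the intrinsic rate untouched
  p90 <- bell_evans_params(4.5e-3, 0.18, theta = pi / 2)
  expect_equal(bell_off_rate(c(0, 50, 500), p90), rep(4.5e-3, 3))
  # direct evaluation at 50 pN
  expect_equal(bell_off_rate(50, p, 298),
               4.5e-3 * exp(50 * 0.18 / kBT(298)), tolerance = 1e-12)
  expect_equal(bell_off_rate(50, p, 298), 4.0e-2, tolerance = 0.02)
  expect_identical(tilt_energy(0, 0.4), 0)
  expect_equal(tilt_energy(100, 0.4, pi / 2), 0, tolerance = 1e-12)
  # a doubled transition distance doubles the tilt at equal force
  expect_equal(tilt_energy(100, 0.40), 40)
  expect_gt(tilt_energy(100, 0.40), tilt_energy(100, 0.18))
})

test_that("Bell-Evans regression is an exact round trip on noiseless
           points and is scale-equivariant", {
  kT <- kBT(298)
  p <- bell_evans_params(4.5e-3, 0.18)
  vF <- 10^seq(3, 6, length.out = 6)
  points <- data.frame(F_mp = bell_evans_force(vF, p, 298),
                       F_sigma = 1, LR_mp = vF)
  fit <- fit_bell_evans(points, T = 298)
  expect_equal(fit$x_beta, 0.18, tolerance = 1e-6)
  expect_equal(fit$koff0, 4.5e-3, tolerance = 1e-6)
  # slope of F vs ln(vF) equals kBT/x_beta
  expect_equal(unname(coef(fit$fit)[2]), kT / 0.18, tolerance = 1e-8)
  # multiplying all loading rates by c shifts F_mp by (kBT/xb)*ln(c)
  shifted <- points
  shifted$LR_mp <- shifted$LR_mp * 7
  shifted$F_mp <- shifted$F_mp + (kT / 0.18) * log(7)
  fit2 <- fit_bell_evans(shifted, T = 298)
  expect_equal(fit2$x_beta, fit$x_beta, tolerance = 1e-9)
  expect_equal(fit2$koff0, fit$koff0, tolerance = 1e-9)
})

test_that("Bell-Evans regression guards its preconditions", {
  p <- bell_evans_params(4.5e-3, 0.18)
  vF <- c(1e4, 2e4, 3e4)   # less than one decade
  pts <- data.frame(F_mp = bell_evans_force(vF, p), F_sigma = 1, LR_mp = vF)
  expect_error(fit_bell_evans(pts), "decade")
  # non-positive slope is a model violation
  bad <- data.frame(F_mp = c(300, 200, 100), F_sigma = 1,
                    LR_mp = c(1e3, 1e4, 1e5))
  expect_error(fit_bell_evans(bad), "slope")
})

test_that("self-consistent most probable force solves the tether fixed
           point", {
  b <- bell_evans_params(4.5e-3, 0.18)
  p <- fjc_params(55, 0.7)
  th <- most_probable_force_theory(b, p, 25, 1000, 298)
  expect_equal(th$F_mp, bell_evans_force(th$vF, b, 298), tolerance = 1e-6)
  expect_equal(th$vF, loading_rate(th$F_mp, p, 25, 1000, 298),
               tolerance = 1e-6)
})
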