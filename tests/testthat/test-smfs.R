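# helper: build a clean synthetic stretch + rupture curve from the force
# balance, with rupture at a prescribed force
make_specific_curve <- function(F_rup, Lc = 55, Lk = 0.7, kc = 25,
                                v = 1000, T = 298, noise = 0,
                                n_samples = 4096, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- fjc_params(Lc, Lk)
  z_rup <- fjc_extension(F_rup, p, T) + F_rup / kc
  z_total <- z_rup * 1.2 + 10
  tgrid <- seq(0, z_total / v, length.out = n_samples)
  zgrid <- v * tgrid
  force <- numeric(n_samples)
  pre <- zgrid < z_rup & zgrid > 0
  force[pre] <- solve_tether_force(zgrid[pre], kc, p, T, tol = 1e-10)
  if (noise > 0) force <- force + rnorm(n_samples, 0, noise)
  structure(list(time = tgrid, piezo = zgrid, force = force, kc = kc,
                 velocity = v, temperature = T, id = "synthetic",
                 truth = list(label = "specific", rupture_force = F_rup)),
            class = "force_curve")
}

test_that("FJC fitting recovers the generating tether", {
  cu <- make_specific_curve(150)
  seg <- which(cu$force > 10 & cu$piezo < cu$piezo[which.max(cu$force)] + 1e-9)
  fit <- fit_fjc(cu, seg)
  expect_equal(fit$fjc$Lc, 55, tolerance = 1e-3)
  expect_equal(fit$fjc$Lk, 0.7, tolerance = 1e-3)
  # noisy recovery within 5% (10 seeds)
  errs <- vapply(1:10, function(s) {
    cn <- make_specific_curve(200, noise = 5, n_samples = 400, seed = 100 + s)
    a <- analyze_curve(cn)
    if (is.null(a$fjc)) return(NA_real_)
    abs(a$fjc$Lc - 55) / 55
  }, numeric(1))
  expect_lt(stats::median(errs, na.rm = TRUE), 0.05)
})

test_that("flat noise is rejected and short-tether adhesion is labelled
           nonspecific", {
  set.seed(42)
  flat <- structure(list(time = seq(0, 0.1, length.out = 500),
                         piezo = seq(0, 100, length.out = 500),
                         force = rnorm(500, 0, 5), kc = 25, velocity = 1000,
                         temperature = 298, id = "flat", truth = NULL),
                    class = "force_curve")
  expect_identical(classify_curve(flat), "none")
  adhesion <- make_specific_curve(100, Lc = 15, seed = 43, noise = 3,
                                  n_samples = 1024)
  expect_identical(classify_curve(adhesion), "nonspecific")
})

test_that("classifier is sensitive to specific events and does not invent
           them", {
  cfg <- curve_gen_config(n_curves = 200, specific_fraction = 1, seed = 20)
  ev <- analyze_curves(gen_force_curves(cfg))
  expect_gte(mean(ev$label == "specific"), 0.95)
  cfg0 <- curve_gen_config(n_curves = 400, specific_fraction = 0, seed = 21)
  ev0 <- analyze_curves(gen_force_curves(cfg0))
  expect_lt(mean(ev0$label == "specific"), 0.01)
})

test_that("rupture extraction reads off the prescribed unbinding force", {
  cu <- make_specific_curve(120)
  a <- analyze_curve(cu)
  expect_identical(a$label, "specific")
  expect_equal(a$event$F_ub, 120, tolerance = 0.5 / 120)
  # noisy curve: smoothed peak stays within the noise scale of the truth
  cn <- make_specific_curve(120, noise = 5, n_samples = 2048, seed = 7)
  an <- analyze_curve(cn)
  expect_equal(an$event$F_ub, 120, tolerance = 5 / 120)
  # monotone curve with no drop
  mono <- cu
  keep <- cu$piezo < fjc_extension(119, fjc_params(55, 0.7)) + 119 / 25
  mono$time <- mono$time[keep]; mono$piezo <- mono$piezo[keep]
  mono$force <- mono$force[keep]
  expect_identical(classify_curve(mono), "none")
})

test_that("per-velocity aggregation needs enough events and handles the
           degenerate case", {
  expect_error(most_probable_force(rep(100, 10), rep(1e4, 10)),
               "events")
  pt <- most_probable_force(rep(100, 30), rep(1e4, 30), velocity = 1000)
  expect_equal(pt$F_mp, 100)
  # unimodal Gaussian forces: peak estimate within 3 pN (5-seed median)
  errs <- vapply(1:5, function(s) {
    set.seed(s)
    F <- rnorm(300, 100, 15)
    abs(most_probable_force(F, exp(rnorm(300, log(2e4), 0.2)))$F_mp - 100)
  }, numeric(1))
  expect_lt(stats::median(errs), 3)
})

test_that("full simulate-classify-fit-regress closure recovers the
           generating landscape", {
  # single-seed smoke version of the multi-seed acceptance closure, at
  # the full 300-events-per-velocity protocol
  cfg <- curve_gen_config(n_curves = 1800, specific_fraction = 1, seed = 30)
  ana <- dfs_analysis(gen_force_curves(cfg))
  expect_equal(ana$bell$x_beta, 0.18, tolerance = 0.15)
  expect_lt(abs(log(ana$bell$koff0 / 4.5e-3)), log(2))
  expect_true(all(ana$points$n_events >= 20))
})
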