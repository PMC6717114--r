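test_that("PSD repair clips negative eigenvalues and keeps unit diagonal", {
  C <- matrix(c(1, 0.9, -0.9,
                0.9, 1, 0.9,
                -0.9, 0.9, 1), 3, 3)   # strongly non-PSD
  R <- nearest_psd(C)
  expect_true(all(eigen(R, symmetric = TRUE, only.values = TRUE)$values >=
                    -1e-10))
  expect_equal(diag(R), rep(1, 3))
  # an infeasible planted structure is a config error
  cfg <- traj_gen_config(
    n_residues_per_chain = 2, n_frames = 50,
    community_blocks = list(list(nodes = c(1, 2), rho = 0.9),
                            list(nodes = c(2, 3), rho = -0.9),
                            list(nodes = c(1, 3), rho = 0.9)),
    background_correlation = 0, seed = 1)
  expect_error(gen_trajectory(cfg), "infeasible")
})

test_that("trajectory generator is seeded-reproducible and flags the
           degenerate zero-fluctuation case", {
  cfg <- traj_gen_config(n_residues_per_chain = 6, n_frames = 40, seed = 3)
  e1 <- gen_trajectory(cfg)
  e2 <- gen_trajectory(cfg)
  expect_identical(e1$coords, e2$coords)
  frozen <- gen_trajectory(traj_gen_config(n_residues_per_chain = 6,
                                           n_frames = 40,
                                           fluctuation_sd = 0, seed = 3))
  expect_true(frozen$truth$degenerate)
  expect_identical(frozen$coords[1, , ], frozen$coords[40, , ])
  expect_error(correlation_matrix(frozen), NA)  # flagged, not an error
  expect_true(all(is.na(suppressWarnings(correlation_matrix(frozen)))))
})

test_that("planted block correlations are realised within sampling error", {
  cfg <- traj_gen_config(
    n_residues_per_chain = 10, n_frames = 2000,
    community_blocks = list(list(nodes = 1:10, rho = 0.9),
                            list(nodes = 11:20, rho = 0.9)),
    background_correlation = 0, seed = 11)
  ens <- gen_trajectory(cfg)
  C <- correlation_matrix(ens)
  blockA <- C[1:10, 1:10][upper.tri(diag(10))]
  inter <- C[1:10, 11:20]
  expect_equal(mean(blockA), 0.9, tolerance = 0.05 / 0.9)
  expect_lt(max(abs(mean(inter)), 0), 0.05)
})

test_that("empirical covariance error shrinks with frame count", {
  err_at <- function(nf) {
    cfg <- traj_gen_config(n_residues_per_chain = 8, n_frames = nf,
                           seed = 17)
    ens <- gen_trajectory(cfg)
    C <- correlation_matrix(ens)
    mean(abs(C - ens$truth$C_target))
  }
  expect_lt(err_at(3200), err_at(200))
})

test_that("fixed-contact geometry yields saturated occupancy downstream", {
  geo <- make_two_chain_reference(4)
  geo$coords[5, ] <- geo$coords[1, ] + c(0, 4.0, 0)   # B:1 pinned near A:1
  cfg <- traj_gen_config(n_residues_per_chain = 4, n_frames = 20,
                         fluctuation_sd = 0, contact_geometry = geo,
                         seed = 2)
  ens <- gen_trajectory(cfg)
  occ <- contact_occupancy(ens)
  expect_equal(occ[1, 5], 1)
})
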