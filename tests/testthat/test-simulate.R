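test_that("frozen dynamics with zero noise give zero displacements", {
  geom <- cell_geometry(3, 0.5)
  sch <- kinetic_scheme(2e-12, 1e-12, 0)  # D ordering requires tiny gaps
  img <- imaging_model(sigma_loc = 0, frames_per_cycle = 5)
  tr <- simulate_tracks(geom, sch, img, 5, seed = 1, start_state = "FD")
  expect_lt(max(displacements(tr)$r_um), 1e-4)
})

test_that("single-state tracks reproduce the closed-form displacement CDF", {
  # weak confinement (large cell, slow D) so the free-space form applies
  geom <- cell_geometry(40, 5)
  D <- 0.02
  sig <- 0.02
  sch <- kinetic_scheme(D, D / 2, 0)
  img <- imaging_model(sigma_loc = sig, frames_per_cycle = 30)
  tr <- simulate_tracks(geom, sch, img, 400, seed = 2, start_state = "FD")
  r <- displacements(tr)$r_um
  expect_gte(length(r), 1e4)
  mu <- 4 * D * img$t_lapse + 4 * sig^2
  ks <- suppressWarnings(ks.test(r^2, function(q) 1 - exp(-q / mu)))
  expect_gt(ks$p.value, 0.01)
  # D_eff estimator: E[r^2]/(4 t) = D + sigma^2/t
  expect_equal(mean(r^2) / (4 * img$t_lapse), D + sig^2 / img$t_lapse,
               tolerance = 0.05)
})

test_that("track lengths follow the photobleaching rate", {
  geom <- cell_geometry(40, 5)
  sch <- kinetic_scheme(0.02, 0.01, 0)
  kb <- 2.5
  img <- imaging_model(k_bleach = kb, frames_per_cycle = 1000)
  tr <- simulate_tracks(geom, sch, img, 3000, seed = 3, start_state = "FD")
  len <- table(tr$track_id)
  mean_expected <- img$t_lapse / (1 - exp(-kb * img$t_lapse))
  se <- sd(as.numeric(len) * img$t_lapse) / sqrt(length(len))
  expect_lt(abs(mean(as.numeric(len)) * img$t_lapse - mean_expected), 3 * se)
})

test_that("state occupancy converges to the generator's stationary distribution", {
  sch <- kinetic_scheme(6.7, 0.82, 0.033, k1_on = 3, k_minus1 = 8,
                        k2_on = 6, k_minus2 = 5, k3 = 1, k_minus3 = 2)
  # independent oracle: null left eigenvector of the rate matrix
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- 6; Q[1, 3] <- 3; Q[2, 1] <- 5; Q[2, 3] <- 1
  Q[3, 1] <- 8; Q[3, 2] <- 2
  diag(Q) <- -rowSums(Q)
  ev <- eigen(t(Q))
  v <- Re(ev$vectors[, which.min(abs(ev$values))])
  pi_oracle <- v / sum(v)
  expect_equal(unname(stationary_distribution(sch)), pi_oracle,
               tolerance = 1e-8)
  geom <- cell_geometry(3, 0.5)
  tr <- simulate_tracks(geom, sch, imaging_model(frames_per_cycle = 30),
                        400, seed = 4)
  occ <- prop.table(table(factor(tr$state, c("FD", "NB", "TB"))))
  expect_equal(as.numeric(occ), pi_oracle, tolerance = 0.05)
})

test_that("localizations stay within the membrane plus localization noise", {
  geom <- cell_geometry(3, 0.5)
  sch <- kinetic_scheme(6.7, 0.82, 0.033, k1_on = 3, k_minus1 = 8,
                        k2_on = 6, k_minus2 = 5)
  img <- imaging_model()
  tr <- simulate_tracks(geom, sch, img, 200, seed = 5)
  expect_true(all(in_cell(geom, tr$x_um, tr$y_um, 0,
                          tol = 4 * img$sigma_loc)))
})

test_that("identical seeds give bit-identical tracks", {
  geom <- cell_geometry(3, 0.5)
  sch <- kinetic_scheme(6.7, 0.82, 0.033, k1_on = 2, k_minus1 = 10,
                        k2_on = 5, k_minus2 = 4)
  img <- imaging_model(k_bleach = 1)
  expect_identical(simulate_tracks(geom, sch, img, 25, seed = 9),
                   simulate_tracks(geom, sch, img, 25, seed = 9))
})
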