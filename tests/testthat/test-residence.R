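test_that("residence runs follow the threshold rule with censoring at track ends", {
  out <- extract_tau(c(0.5, 0.1, 0.1, 0.1, 0.6), r0 = 0.2, t_lapse = 0.04)
  expect_identical(nrow(out), 1L)
  expect_equal(out$tau, 0.12)
  expect_false(out$censored)
  # trailing run at the track end is censored
  out2 <- extract_tau(c(0.5, 0.1, 0.1), r0 = 0.2, t_lapse = 0.04)
  expect_equal(out2$tau, 0.08)
  expect_true(out2$censored)
  # everything above threshold: no events
  expect_identical(nrow(extract_tau(c(0.5, 0.4, 0.3), 0.2, 0.04)), 0L)
  # two separated runs in one track give two events
  out3 <- extract_tau(c(0.1, 0.5, 0.1, 0.1), 0.2, 0.04)
  expect_identical(nrow(out3), 2L)
  expect_equal(out3$tau, c(0.04, 0.08))
  expect_equal(out3$censored, c(FALSE, TRUE))
})

test_that("on-time fit recovers the bleaching rate and rejects degenerate input", {
  t <- 0.04
  set.seed(21)
  lens <- rgeom(2000, 1 / 10) + 1  # mean 10 frames
  fit <- fit_on_times(lens, t, n_boot = 100, seed = 1)
  expect_lt(abs(fit$k_bleach - 1 / (mean(lens) * t)), 1e-12)
  expect_lt(abs(fit$k_bleach - 2.5), 3 * fit$sd + 0.25)
  expect_error(fit_on_times(5, t), "at least 2")
  expect_error(suppressWarnings(fit_on_times(rep(7, 50), t)), "degenerate")
  # scale equivariance: doubling on-times halves the rate
  fit2 <- suppressWarnings(fit_on_times(2 * lens, t, n_boot = 50))
  expect_equal(fit2$k_bleach, fit$k_bleach / 2, tolerance = 1e-12)
})

test_that("dwell fit recovers the unbinding rate without bleaching", {
  t <- 0.04
  d <- gen_dwell(3000, k_minus1 = 5, k_bleach = 0, t_lapse = t, seed = 22)
  expect_equal(mean(d$tau), 0.2, tolerance = 0.1)
  D <- c(FD = 6.7, NB = 0.82, TB = 0.033)
  fit <- fit_dwell_distribution(d, D, c(FD = 0, NB = 0, TB = 1),
                                k_bleach = 0, r0 = 0.2, t_lapse = t,
                                n_boot = 100, seed = 2)
  expect_lt(abs(fit$k_minus1 - 5), 3 * fit$sd)
})

test_that("bleach correction removes the photobleaching contribution", {
  t <- 0.04
  d <- gen_dwell(3000, k_minus1 = 5, k_bleach = 2, t_lapse = t, seed = 23)
  D <- c(FD = 6.7, NB = 0.82, TB = 0.033)
  fit <- fit_dwell_distribution(d, D, c(FD = 0, NB = 0, TB = 1),
                                k_bleach = 2, r0 = 0.2, t_lapse = t,
                                n_boot = 100, seed = 3)
  # the uncorrected inverse-mean rate sees k_minus1 + k_bleach ~ 7
  expect_gt(fit$naive_rate, 5.8)
  expect_lt(abs(fit$k_minus1 - 5), 3 * fit$sd)
  # corrected rate can never exceed the raw rate when bleaching is present
  expect_lte(fit$k_minus1, fit$naive_rate)
})

test_that("the discrete dwell model approaches the continuous exponential limit", {
  # at a lapse much shorter than 1/k the geometric and exponential forms
  # coincide: recovery at t = 4 ms matches the continuous rate
  t <- 0.004
  d <- gen_dwell(4000, k_minus1 = 5, k_bleach = 0, t_lapse = t, seed = 24)
  D <- c(FD = 6.7, NB = 0.82, TB = 0.033)
  fit <- fit_dwell_distribution(d, D, c(FD = 0, NB = 0, TB = 1),
                                k_bleach = 0, r0 = 0.2, t_lapse = t)
  # closed-form continuous MLE on the same events
  k_cont <- sum(!d$censored) / sum(d$tau)
  expect_equal(fit$k_minus1, k_cont, tolerance = 0.05)
})

test_that("full three-state simulation recovers k_minus1 and is robust to r0", {
  geom <- cell_geometry(3, 0.5)
  km1_true <- 5
  kb <- 2
  sch <- kinetic_scheme(6.7, 0.82, 0.033, k1_on = 2, k_minus1 = km1_true,
                        k2_on = 5, k_minus2 = 8)
  img <- imaging_model(k_bleach = kb)
  tr <- simulate_tracks(geom, sch, img, 900, seed = 25)
  disp <- displacements(tr)
  pi0 <- stationary_distribution(sch)
  D <- c(FD = 6.7, NB = 0.82, TB = 0.033)
  fits <- lapply(c(0.15, 0.2, 0.25), function(r0) {
    taus <- extract_tau(disp, r0, img$t_lapse)
    fit_dwell_distribution(taus, D, pi0, k_bleach = kb, r0 = r0,
                           t_lapse = img$t_lapse,
                           sigma_loc = img$sigma_loc,
                           n_boot = if (r0 == 0.2) 100 else 0, seed = 4)
  })
  k_mid <- fits[[2]]$k_minus1
  expect_lt(abs(k_mid - km1_true), 3 * fits[[2]]$sd + 0.5)
  # threshold robustness across 0.15-0.25 um
  ks <- vapply(fits, `[[`, 0, "k_minus1")
  expect_lt(max(abs(ks - k_mid)) / k_mid, 0.2)
})
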