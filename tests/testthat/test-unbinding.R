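test_that("the microscopic rate law evaluates and checks occupancy bounds", {
  p <- biphasic_params(k_o = 10, k_r = 12, k_f = 0.018, alpha = 0.5)
  expect_equal(unbinding_rate_micro(p, 2, 100), 10 + 12 * 0.25 + 1.8)
  # n = 0 at zero concentration reduces to k_o_off = k_o + k_r
  expect_equal(unbinding_rate_micro(p, 0, 0), p$k_o_off)
  expect_error(unbinding_rate_micro(p, 6, 0), "n_o")
  # alpha -> 1: no oligomer attenuation left
  p1 <- biphasic_params(k_o = 10, k_r = 12, k_f = 0.018, alpha = 1 - 1e-12)
  expect_equal(unbinding_rate_micro(p1, 5, 100),
               unbinding_rate_micro(p1, 0, 100), tolerance = 1e-9)
})

test_that("the apparent rate law has the documented limits and values", {
  p <- biphasic_params(k_o_off = 22, k_r = 12, k_f = 0.018, K_m = 12)
  expect_equal(unbinding_rate(p, 0), 22)
  expect_equal(unbinding_rate(p, 100), 11.80, tolerance = 1e-3)
  # facilitated-only reduction
  p0 <- biphasic_params(k_o_off = 22, k_r = 0, k_f = 0.018, K_m = 12)
  expect_equal(unbinding_rate(p0, c(0, 50, 500)),
               22 + 0.018 * c(0, 50, 500))
  # large-P slope approaches k_f
  slope <- (unbinding_rate(p, 1e5) - unbinding_rate(p, 1e5 - 1)) / 1
  expect_equal(slope, p$k_f, tolerance = 1e-9)
})

test_that("the K_m relation and its inversion behave as algebra dictates", {
  expect_equal(oligomer_km(22, 0.77, 1e-12), 22 / 0.77, tolerance = 1e-9)
  expect_equal(oligomer_km(22, 1.54, 0.5), oligomer_km(22, 0.77, 0.5) / 2)
  expect_error(oligomer_km(22, 0.77, 1), "alpha")
  expect_error(oligomer_km(22, 0, 0.5), "k_1")
  # rounded literature values can imply an infeasible alpha; flagged, not
  # silently clipped
  ia <- implied_alpha(22, 0.77, 12)
  expect_false(ia$feasible)
  expect_lt(ia$alpha, 0)
})

test_that("the rate minimum matches the stationary point of the curve", {
  p <- biphasic_params(k_o_off = 25, k_r = 16, k_f = 0.012, K_m = 14)
  pm <- rate_minimum(p)
  expect_equal(pm, 14 * log(16 / (0.012 * 14)), tolerance = 1e-12)
  expect_equal(pm, 63.8, tolerance = 1e-3)
  # numerical minimizer oracle on the curve itself
  opt <- optimize(function(x) unbinding_rate(p, x), c(0, 2000))
  expect_equal(pm, opt$minimum, tolerance = 1e-4)
  # monotone case: no interior minimum
  expect_true(is.na(rate_minimum(
    biphasic_params(k_o_off = 22, k_r = 0, k_f = 0.018, K_m = 12))))
  # boundary case k_r = k_f * K_m
  expect_equal(rate_minimum(
    biphasic_params(k_o_off = 22, k_r = 0.216, k_f = 0.018, K_m = 12)), 0)
})

test_that("biphasic minimum exists iff k_r exceeds k_f * K_m, with the biphasic shape", {
  set.seed(31)
  for (i in 1:20) {
    koff <- runif(1, 5, 40)
    p <- biphasic_params(k_o_off = koff, k_r = runif(1, 0, 0.95 * koff),
                         k_f = runif(1, 0.005, 0.05),
                         K_m = runif(1, 5, 100))
    pm <- rate_minimum(p)
    grid <- seq(0.1, 2000, length.out = 4000)
    k <- unbinding_rate(p, grid)
    if (p$k_r > p$k_f * p$K_m) {
      expect_false(is.na(pm))
      # decreasing before the minimum, increasing after
      expect_true(all(diff(k[grid < pm]) < 0))
      expect_true(all(diff(k[grid > pm]) > 0))
    } else {
      expect_true(is.na(pm) || pm == 0)
      expect_true(all(diff(k) > 0))
    }
  }
})

test_that("noiseless rate-law data are recovered to machine precision", {
  truth <- biphasic_params(k_o_off = 25, k_r = 16, k_f = 0.012, K_m = 14)
  P <- 10^seq(1, 3, length.out = 8)
  fit <- suppressWarnings(fit_unbinding(
    data.frame(P_FD = P, k_minus1 = unbinding_rate(truth, P)), n_boot = 50))
  expect_equal(fit$params$k_o_off, 25, tolerance = 1e-6)
  expect_equal(fit$params$k_r, 16, tolerance = 1e-6)
  expect_equal(fit$params$k_f, 0.012, tolerance = 1e-6)
  expect_equal(fit$params$K_m, 14, tolerance = 1e-6)
  expect_true(fit$prefers_biphasic)
  # idempotence: refitting data generated from the fitted parameters
  # reproduces them
  fit2 <- suppressWarnings(fit_unbinding(
    data.frame(P_FD = P, k_minus1 = unbinding_rate(fit$params, P)),
    n_boot = 50))
  expect_equal(fit2$params$K_m, fit$params$K_m, tolerance = 1e-6)
})

test_that("model comparison recognizes purely facilitated (linear) kinetics", {
  set.seed(32)
  P <- 10^seq(1, 3, length.out = 8)
  k <- (5 + 0.02 * P) * (1 + 0.05 * rnorm(8))
  fit <- suppressWarnings(fit_unbinding(
    data.frame(P_FD = P, k_minus1 = k, sd = 0.05 * k), n_boot = 50))
  expect_false(fit$prefers_biphasic)
})

test_that("K_m is recovered from noisy biphasic data within bootstrap error", {
  set.seed(33)
  truth <- biphasic_params(k_o_off = 22, k_r = 21, k_f = 0.021, K_m = 39)
  P <- 10^seq(1, 3, length.out = 8)
  k <- unbinding_rate(truth, P) * (1 + 0.1 * rnorm(8))
  fit <- fit_unbinding(data.frame(P_FD = P, k_minus1 = k, sd = 0.1 * k),
                       n_boot = 200, seed = 7)
  expect_lt(abs(fit$params$K_m - 39), 3 * fit$sd[["K_m"]])
  expect_error(fit_unbinding(data.frame(P_FD = P[1:3], k_minus1 = k[1:3])),
               "at least 4")
})
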