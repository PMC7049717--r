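test_that("displacements are extracted per adjacent localization pair", {
  tr <- data.frame(cell_id = 1, track_id = 1, frame = 1:2,
                   x_um = c(0, 0.3), y_um = c(0, 0.4))
  expect_equal(displacements(tr)$r_um, 0.5)
  # single localization: nothing to pair
  one <- data.frame(cell_id = 1, track_id = 1, frame = 1, x_um = 0, y_um = 0)
  expect_identical(nrow(displacements(one)), 0L)
  # 5-frame track: exactly 4 displacements
  five <- data.frame(cell_id = 1, track_id = 1, frame = 1:5,
                     x_um = seq(0, 0.4, 0.1), y_um = 0)
  expect_identical(nrow(displacements(five)), 4L)
  # pairs spanning a frame gap are excluded
  gap <- data.frame(cell_id = 1, track_id = 1, frame = c(1, 2, 4, 5),
                    x_um = c(0, 0.1, 5, 5.1), y_um = 0)
  expect_equal(displacements(gap)$r_um, c(0.1, 0.1))
  expect_identical(nrow(displacements(five[0, ])), 0L)
})

test_that("the Brownian displacement CDF matches closed-form values", {
  # threshold inclusion of the tight-bound state at r0 = 0.2 um
  expect_gte(brownian_cdf(0.2, 0.033, 0.04, 0), 0.995)
  expect_equal(brownian_cdf(0.2, 0.033, 0.04, 0),
               1 - exp(-0.04 / (4 * 0.033 * 0.04)), tolerance = 1e-12)
  expect_equal(brownian_cdf(0, 1, 0.04, 0.02), 0)
  expect_equal(brownian_cdf(0.2, 0.82, 0.04, 0), 0.263, tolerance = 1e-3)
  # degenerate motionless, noiseless case
  expect_equal(brownian_cdf(0.2, 0, 0.04, 0), 1)
})

test_that("over-specified single-state data collapse onto one dominant component", {
  r <- gen_mixture_r(2e4, 0.8, 1, t_lapse_default, seed = 11)
  fit <- suppressWarnings(fit_mixture(r, t_lapse_default, n_states = 3))
  expect_true(fit$duplicate_states)
  # after pooling duplicate components one state dominates
  expect_gt(max(fit$f_merged), 0.95)
  expect_equal(max(fit$D_merged), 0.8, tolerance = 0.05)
})

test_that("the three-state global fit recovers mixture parameters", {
  r <- gen_mixture_r(5e4, three_state_D, three_state_f, t_lapse_default,
                     seed = 12)
  fit <- fit_mixture(r, t_lapse_default)
  expect_equal(unname(fit$D), three_state_D, tolerance = 0.07)
  expect_equal(unname(fit$f[1, ]), three_state_f, tolerance = 0.05)
  expect_equal(sum(fit$f[1, ]), 1, tolerance = 1e-6)
  expect_true(all(diff(fit$D) < 0))
  # nesting: 3-state likelihood cannot fall below the 2-state one
  fit2 <- fit_mixture(r, t_lapse_default, n_states = 2)
  expect_gte(fit$loglik, fit2$loglik - 1e-6)
})

test_that("diffusion constants are shared across groups, fractions are free", {
  D <- c(2.0, 0.05)
  r1 <- gen_mixture_r(2e4, D, c(0.7, 0.3), t_lapse_default, seed = 13)
  r2 <- gen_mixture_r(2e4, D, c(0.3, 0.7), t_lapse_default, seed = 14)
  fit <- fit_mixture(c(r1, r2), t_lapse_default, n_states = 2,
                     group = rep(c("a", "b"), each = 2e4))
  expect_identical(nrow(fit$f), 2L)
  expect_equal(unname(fit$f["a", 1]), 0.7, tolerance = 0.05)
  expect_equal(unname(fit$f["b", 1]), 0.3, tolerance = 0.05)
  expect_equal(rowSums(fit$f), c(a = 1, b = 1), tolerance = 1e-6)
})

test_that("with no localization error the single-state D estimate is unbiased", {
  D <- 0.5
  r <- gen_mixture_r(4e4, D, 1, t_lapse_default, sigma_loc = 0, seed = 15)
  fit <- fit_mixture(r, t_lapse_default, n_states = 1)
  # oracle: moment estimator mean(r^2)/(4t), exact MLE for one state
  se <- D / sqrt(length(r))
  expect_lt(abs(fit$D[1] - D), 4 * se)
  expect_equal(unname(fit$D[1]), mean(r^2) / (4 * t_lapse_default),
               tolerance = 1e-6)
})

test_that("the localization-error floor keeps D nonnegative", {
  sig <- 0.02
  r <- gen_mixture_r(2e4, 1e-4, 1, t_lapse_default, sigma_loc = sig,
                     seed = 16)
  fit <- fit_mixture(r, t_lapse_default, sigma_loc = sig, n_states = 1)
  expect_gte(fit$D[1], 0)
  expect_lt(fit$D[1], 0.01)
})

test_that("bootstrap rejects degenerate requests and collapses for duplicated cells", {
  d <- gen_mixture_r(2000, c(1, 0.05), c(0.5, 0.5), t_lapse_default,
                     seed = 17, cell_ids = rep(1:10, each = 200))
  fit_fun <- function(dd) {
    ft <- fit_mixture(dd$r_um, t_lapse_default, n_states = 2,
                      min_per_group = 1)
    c(D1 = unname(ft$D[1]), f1 = unname(ft$f[1, 1]))
  }
  expect_error(bootstrap_sd(d, fit_fun, n_boot = 0), "n_boot")
  expect_error(bootstrap_sd(d[d$cell_id == 1, ], fit_fun, n_boot = 60),
               "at least 2")
  expect_warning(bootstrap_sd(d, fit_fun, n_boot = 10), "unreliable")
  # identical cells: every resample is the same dataset, so sd is exactly 0
  dup <- d
  dup$r_um <- rep(d$r_um[d$cell_id == 1], 10)
  bs <- bootstrap_sd(dup, fit_fun, n_boot = 60, seed = 5)
  expect_equal(unname(bs$sd), c(0, 0), tolerance = 1e-10)
})

test_that("bootstrap spread matches the repeat-experiment spread of f_TB", {
  # scaled-down calibration: 30 synthetic experiments, each bootstrapped
  n_rep <- 30L
  n <- 1500L
  cells <- rep(1:10, each = n / 10)
  cover <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    d <- gen_mixture_r(n, three_state_D, three_state_f, t_lapse_default,
                       seed = 100 + i, cell_ids = cells)
    fit_fun <- function(dd) {
      ft <- fit_mixture(dd$r_um, t_lapse_default, min_per_group = 1)
      c(f_TB = unname(ft$f[1, 3]))
    }
    est <- fit_fun(d)
    bs <- bootstrap_sd(d, fit_fun, n_boot = 50, seed = i)
    cover[i] <- abs(est - three_state_f[3]) <= bs$sd
  }
  # 68% nominal one-sigma coverage, wide band for the small replicate count
  expect_gte(mean(cover), 0.4)
  expect_lte(mean(cover), 0.95)
})
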