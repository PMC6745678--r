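test_that("noise-free invariant data pin the fixed-slope posterior to the truth", {
  top <- c(2, 5, 10, 20, 40)
  d <- regression_data(data.frame(r_max = 1 / top, t_op_bar = top))
  # the posterior collapses toward a spike, so the split-R-hat diagnostic is
  # expected to flag the near-degenerate chains (a warning, never an error)
  expect_warning(
    fit <- fit_allometry(d, "fixed", chains = 2, iter = 5000, burn = 2000,
                         seed = 3),
    "R-hat")
  expect_equal(mean(fit$draws$araT), 1, tolerance = 0.02)
  ci <- hdi(fit$draws$araT, 0.95)
  expect_lt(ci["high"] - ci["low"], 0.1)
})

test_that("the fixed-slope fit recovers a known constant from noisy pairs", {
  d <- gen_allometric_pairs(14, true_a_raT = 1, log_scatter_sd = 0.2, seed = 5)
  fit <- fit_allometry(d, "fixed", chains = 2, iter = 6000, burn = 2000,
                       seed = 1)
  post_sd <- sd(fit$draws$araT)
  expect_lt(abs(mean(fit$draws$araT) - 1), 3 * post_sd)
  d2 <- gen_allometric_pairs(14, true_a_raT = 0.89, log_scatter_sd = 0.15,
                             seed = 6)
  fit2 <- fit_allometry(d2, "fixed", chains = 2, iter = 6000, burn = 2000,
                        seed = 2)
  expect_lt(abs(mean(fit2$draws$araT) - 0.89), 3 * sd(fit2$draws$araT))
})

test_that("the fixed-slope fit equals an intercept-only fit on y = log rmax + log Top", {
  d <- gen_allometric_pairs(14, seed = 9)
  fit <- fit_allometry(d, "fixed", chains = 2, iter = 4000, burn = 1000,
                       seed = 4)
  # identical seed and data => identical draws
  fit_rep <- fit_allometry(d, "fixed", chains = 2, iter = 4000, burn = 1000,
                           seed = 4)
  expect_identical(fit$draws, fit_rep$draws)
  # moving all generation-time structure into r_max (so y is unchanged up to
  # rounding) leaves the posterior law unchanged within MCMC error
  d2 <- regression_data(data.frame(r_max = d$r_max * d$t_op_bar,
                                   t_op_bar = rep(1, nrow(d))))
  fit2 <- fit_allometry(d2, "fixed", chains = 2, iter = 4000, burn = 1000,
                        seed = 4)
  expect_equal(mean(fit2$draws$araT), mean(fit$draws$araT), tolerance = 0.01)
  expect_equal(sd(fit2$draws$araT), sd(fit$draws$araT), tolerance = 0.05)
})

test_that("posterior mean of log araT tracks the sample mean of y (frequentist cross-check)", {
  d <- gen_allometric_pairs(30, true_a_raT = 0.9, log_scatter_sd = 0.15,
                            seed = 12)
  y <- log(d$r_max) + log(d$t_op_bar)
  fit <- fit_allometry(d, "fixed", chains = 2, iter = 6000, burn = 2000,
                       seed = 5)
  la <- log(fit$draws$araT)
  mcse <- sd(la) / sqrt(200)   # conservative effective-size guess
  expect_lt(abs(mean(la) - mean(y)), 2 * mcse + 0.01)
})

test_that("with no data the sampler returns the prior", {
  d <- regression_data(data.frame(r_max = numeric(0), t_op_bar = numeric(0)))
  fit <- fit_allometry(d, "fixed", chains = 2, iter = 8000, burn = 2000,
                       seed = 6)
  prior <- draw_samples(trunc_normal_spec(1, 2, 0, Inf), 2e4, seed = 1)
  expect_equal(mean(fit$draws$araT), mean(prior), tolerance = 0.1)
  expect_equal(sd(fit$draws$araT), sd(prior), tolerance = 0.15)
  expect_equal(mean(fit$draws$sigma), 0.5, tolerance = 0.05)  # U(0,1) prior
})

test_that("the free-slope fit concentrates on a baked-in slope with noise-free data", {
  top <- c(2, 4, 8, 16, 32, 50)
  d <- regression_data(data.frame(r_max = exp(-0.5 * log(top) + log(0.8)),
                                  t_op_bar = top))
  fit <- suppressWarnings(
    fit_allometry(d, "free", chains = 2, iter = 8000, burn = 3000, seed = 7))
  expect_equal(mean(fit$draws$beta1), -0.5, tolerance = 0.05)
  expect_equal(mean(fit$draws$araT), 0.8, tolerance = 0.05)
})

test_that("the free-slope fit needs at least 3 pairs", {
  d <- regression_data(data.frame(r_max = c(0.1, 0.2), t_op_bar = c(10, 5)))
  expect_error(fit_allometry(d, "free"), "at least 3")
})

test_that("regression data with non-positive rates are rejected", {
  expect_error(regression_data(data.frame(r_max = c(0.1, 0), t_op_bar = c(1, 2))),
               "positive")
  expect_error(regression_data(data.frame(r_max = 0.1, t_op = 1)), "columns")
})
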