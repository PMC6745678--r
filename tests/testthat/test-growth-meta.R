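test_that("log transform is row-for-row with published values", {
  tab <- loggerhead_growth_table()
  theta <- log_transform_studies(tab)
  expect_equal(nrow(theta), 9)
  i <- which(tab$L_inf_cm == 99.70)
  expect_equal(unname(theta[i, ]), c(99.70, log(0.0530)), tolerance = 1e-10)
  expect_equal(unname(theta[i, "ln_k"]), -2.9375, tolerance = 1e-4)
  j <- which(tab$L_inf_cm == 94.70)
  expect_equal(unname(theta[j, "ln_k"]), -2.1628, tolerance = 1e-4)
  # k = 1 maps to 0
  expect_equal(unname(log_transform_studies(
    data.frame(L_inf_cm = 50, k_per_year = 1))[1, "ln_k"]), 0)
  expect_error(log_transform_studies(data.frame(L_inf_cm = 1,
                                                k_per_year = -1)), "positive")
})

test_that("the Wishart conditional has the documented convention", {
  # with mu fixed, E[Omega | mu, theta] = (df + n) * (R + S)^-1
  set.seed(31)
  theta <- cbind(rnorm(50, 10, 2), rnorm(50, -2, 0.3))
  mu <- c(10, -2)
  R <- diag(2)
  S <- crossprod(sweep(theta, 2, mu))
  target <- (2 + nrow(theta)) * solve(R + S)
  draws <- replicate(4000, draw_omega(theta, mu, R, 2))
  expect_equal(apply(draws, 1:2, mean), target, tolerance = 0.05)
})

test_that("parameter recovery from many synthetic studies", {
  tab <- gen_growth_studies(200, true_mu = c(100, -2.85),
                            true_sigma = diag(c(40, 0.13)), seed = 8)
  fit <- fit_growth_meta(tab, chains = 2, iter = 3000, burn = 1000, seed = 9)
  expect_lt(abs(mean(fit$draws$L_inf_bar) - 100),
            3 * sd(fit$draws$L_inf_bar) + 0.05)
  expect_lt(abs(mean(fit$draws$ln_k_bar) + 2.85),
            3 * sd(fit$draws$ln_k_bar) + 0.01)
})

test_that("a dominant prior pins the posterior mean to the prior mean", {
  tab <- loggerhead_growth_table()
  fit <- fit_growth_meta(tab, prior_mu_mean = c(100, -3),
                         prior_mu_precision = 1e9,
                         chains = 2, iter = 2000, burn = 500, seed = 10)
  expect_equal(mean(fit$draws$L_inf_bar), 100, tolerance = 0.01)
  expect_equal(mean(fit$draws$ln_k_bar), -3, tolerance = 0.01)
})

test_that("vague-prior shrinkage is small and directed toward zero", {
  tab <- loggerhead_growth_table()
  fit <- small_meta_fit()
  sample_mean <- mean(tab$L_inf_cm)   # 101.73
  post_mean <- mean(fit$draws$L_inf_bar)
  # the 1e-3-precision zero-mean prior pulls the posterior just below the
  # sample mean (about half a percent)
  expect_lt(post_mean, sample_mean)
  expect_gt(post_mean, sample_mean * 0.985)
  # essentially-flat prior recovers the sample mean
  fit0 <- fit_growth_meta(tab, prior_mu_precision = 1e-10,
                          chains = 2, iter = 3000, burn = 1000, seed = 11)
  expect_equal(mean(fit0$draws$L_inf_bar), sample_mean, tolerance = 0.3)
})

test_that("every precision-matrix draw is symmetric positive definite", {
  fit <- small_meta_fit()
  d <- fit$draws
  ok <- vapply(seq_len(nrow(d)), function(i) {
    om <- matrix(c(d$omega_11[i], d$omega_12[i], d$omega_12[i], d$omega_22[i]),
                 2, 2)
    inherits(try(chol(om), silent = TRUE), "matrix")
  }, logical(1))
  expect_true(all(ok))
})

test_that("identical seed and settings give identical chains", {
  tab <- loggerhead_growth_table()
  f1 <- fit_growth_meta(tab, chains = 2, iter = 1200, burn = 200, seed = 99)
  f2 <- fit_growth_meta(tab, chains = 2, iter = 1200, burn = 200, seed = 99)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_growth_meta(tab, chains = 2, iter = 1200, burn = 200, seed = 100)
  expect_false(identical(f1$draws$L_inf_bar, f3$draws$L_inf_bar))
})

test_that("fit preconditions are enforced", {
  tab <- loggerhead_growth_table()
  expect_error(fit_growth_meta(tab[1, ]), "at least 2")
  expect_error(fit_growth_meta(tab, wishart_df = 1), "degrees of freedom")
  expect_error(fit_growth_meta(tab, prior_mu_precision = 0), "positive")
})
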