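test_that("the fixed-point solver matches the bisection oracle on the reference triple", {
  lam <- solve_lambda_max(1, 41, 0.841)
  expect_equal(lam, bisect_lambda(1, 41, 0.841), tolerance = 1e-11)
  expect_equal(lam, 1.022151, tolerance = 1e-6)
  top <- optimal_generation_time(41, 0.841, lam)
  expect_equal(top, 45.6425, tolerance = 1e-3)
  # a population can at most e-fold per generation when a_raT = 1
  expect_equal(lam^top, exp(1), tolerance = 1e-9)
})

test_that("limiting behaviour of the fixed point", {
  # vanishing allometric constant: no growth
  expect_equal(solve_lambda_max(1e-12, 41, 0.841), 1, tolerance = 1e-10)
  # enormous maturation age kills growth
  expect_equal(solve_lambda_max(1, 1e6, 0.841), 1, tolerance = 1e-5)
  # generation time collapses to alpha as survival vanishes
  expect_equal(optimal_generation_time(41, 1e-12, 1.02), 41, tolerance = 1e-9)
  expect_error(optimal_generation_time(41, 0.9, 0.85), "exceed")
})

test_that("fixed-point iteration agrees with bisection on random valid triples", {
  set.seed(41)
  n <- 2000
  a <- rlnorm(n, -0.074, 0.385)
  alpha <- runif(n, 1, 80)
  s <- runif(n, 0.05, 0.95)
  lam <- solve_lambda_max(a, alpha, s)
  for (i in sample(n, 300)) {
    expect_equal(lam[i], bisect_lambda(a[i], alpha[i], s[i]),
                 tolerance = 1e-9)
  }
  # bounds hold for every draw
  expect_true(all(lam > 1))
  expect_true(all(lam <= exp(a / alpha) + 1e-12))
  # fixed-point identity lambda^Top = exp(a_raT)
  top <- optimal_generation_time(alpha, s, lam)
  expect_lt(max(abs(top * log(lam) - a)), 1e-9)
})

test_that("lambda_max is monotone in each input", {
  lam_a <- solve_lambda_max(c(0.5, 1, 1.5), 41, 0.841)
  expect_true(all(diff(lam_a) > 0))       # increasing in a_raT
  lam_al <- solve_lambda_max(1, c(20, 41, 60), 0.841)
  expect_true(all(diff(lam_al) < 0))      # decreasing in alpha
  lam_s <- solve_lambda_max(1, 41, c(0.5, 0.7, 0.9))
  expect_true(all(diff(lam_s) < 0))       # underestimated survival inflates lambda
})

test_that("solver input validation", {
  expect_error(solve_lambda_max(-1, 41, 0.8), "positive")
  expect_error(solve_lambda_max(1, 0.5, 0.8), "at least 1")
  expect_error(solve_lambda_max(1, 41, 1.2), "inside")
})

test_that("degenerate Monte Carlo inputs collapse to the single-triple solution", {
  mc <- run_monte_carlo(rep(41, 100),
                        survival = trunc_beta_spec(0.841, 1e-6, 0.840, 0.842),
                        a_raT_dist = lognormal_spec(1, 1e-9),
                        n = 1e3, seed = 1)
  ref <- solve_lambda_max(1, 41, 0.841)
  expect_lt(max(abs(mc$draws$lambda_max - ref)), 1e-3)
  expect_lt(sd(mc$draws$R_max), 1e-4)
})

test_that("Monte Carlo runs are bit-identical under a fixed seed", {
  alpha <- slice_ages(small_meta_fit(), n = 1e4, seed = 3)
  m1 <- run_monte_carlo(alpha, n = 1e3, seed = 77)
  m2 <- run_monte_carlo(alpha, n = 1e3, seed = 77)
  expect_identical(m1$draws, m2$draws)
  # per-draw invariants
  expect_true(all(m1$draws$lambda_max > 1))
  expect_true(all(m1$draws$top > m1$draws$alpha))
  expect_lt(max(abs(m1$draws$lambda_max^m1$draws$top - exp(m1$draws$a_raT))),
            1e-6)
})

test_that("the top-level pipeline object carries coherent summaries and methods", {
  fit <- rmax_dim(n = 2e4, chains = 2, iter = 2000, burn = 500, seed = 5)
  co <- coef(fit)
  expect_named(co, c("Rmax_mean", "Rmax_median", "Rmax_mode",
                     "Rmax_hdi_low", "Rmax_hdi_high"))
  expect_gt(co["Rmax_mean"], 0)
  expect_lt(co["Rmax_mean"], 0.2)
  expect_lte(co["Rmax_hdi_low"], co["Rmax_median"])
  s <- summary(fit)
  expect_s3_class(s$R_max, "summary_stats")
  sims <- simulate(fit, nsim = 2, seed = 9, n = 1e3)
  expect_equal(dim(sims), c(1e3, 2))
  expect_output(print(fit), "R_max")
})
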