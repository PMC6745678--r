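test_that("beta moment matching reproduces the requested moments exactly", {
  cases <- list(c(0.841, 0.035), c(0.5, 0.1), c(0.2, 0.05), c(0.95, 0.01))
  for (cs in cases) {
    sh <- beta_from_moments(cs[1], cs[2])
    m <- sh["a"] / (sh["a"] + sh["b"])
    v <- sh["a"] * sh["b"] / ((sh["a"] + sh["b"])^2 * (sh["a"] + sh["b"] + 1))
    expect_equal(unname(m), cs[1], tolerance = 1e-12)
    expect_equal(unname(sqrt(v)), cs[2], tolerance = 1e-12)
  }
  # survival distribution shapes
  sh <- beta_from_moments(0.841, 0.035)
  expect_equal(unname(sh), c(90.96, 17.20), tolerance = 1e-3)
  # uniform case and symmetry
  expect_equal(unname(beta_from_moments(0.5, sqrt(1 / 12))), c(1, 1),
               tolerance = 1e-12)
  sh <- beta_from_moments(0.5, 0.1)
  expect_equal(unname(sh["a"]), unname(sh["b"]), tolerance = 1e-12)
})

test_that("infeasible beta variance and out-of-range means are rejected", {
  expect_error(beta_from_moments(0.5, 0.5), "infeasible")
  expect_error(beta_from_moments(1.2, 0.1), "inside")
  expect_error(beta_from_moments(0.5, 0), "positive")
})

test_that("lognormal moment matching inverts the natural-scale moments", {
  p <- lognormal_from_moments(1, 0.4)
  expect_equal(unname(p), c(-0.0742100, 0.3852532), tolerance = 1e-6)
  # round trip through the analytic lognormal moments
  for (cs in list(c(1, 0.4), c(2, 0.8), c(0.5, 0.01))) {
    p <- lognormal_from_moments(cs[1], cs[2])
    expect_equal(exp(p["mu_log"] + p["sigma_log"]^2 / 2), cs[1],
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(sqrt((exp(p["sigma_log"]^2) - 1)) * cs[1], cs[2],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # scale equivariance at fixed CV
  p1 <- lognormal_from_moments(1, 0.4)
  p2 <- lognormal_from_moments(2, 0.8)
  expect_equal(unname(p2["mu_log"]), log(2) + unname(p1["mu_log"]),
               tolerance = 1e-12)
  expect_equal(unname(p2["sigma_log"]), unname(p1["sigma_log"]),
               tolerance = 1e-12)
  # sd -> 0 limit collapses to a point mass at the mean
  p <- lognormal_from_moments(1, 1e-12)
  expect_equal(unname(p["mu_log"]), 0, tolerance = 1e-8)
  expect_lt(unname(p["sigma_log"]), 1e-10)
})

test_that("truncated samplers respect their bounds and are seed-reproducible", {
  spec <- trunc_beta_spec(0.841, 0.035, 0.770, 0.925)
  x <- draw_samples(spec, 1e5, seed = 7)
  expect_gte(min(x), 0.770)
  expect_lte(max(x), 0.925)
  expect_identical(x, draw_samples(spec, 1e5, seed = 7))

  tn <- trunc_normal_spec(1, 2, 0, Inf)
  y <- draw_samples(tn, 1e4, seed = 7)
  expect_gte(min(y), 0)
})

test_that("truncated beta draws match the quadrature law", {
  spec <- trunc_beta_spec(0.841, 0.035, 0.770, 0.925)
  n <- 1e5
  x <- draw_samples(spec, n, seed = 11)
  m_true <- trunc_beta_mean_quad(spec$a, spec$b, spec$lower, spec$upper)
  se <- sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - m_true), 3 * se)
  # KS distance against the truncated CDF
  plo <- pbeta(spec$lower, spec$a, spec$b)
  phi <- pbeta(spec$upper, spec$a, spec$b)
  cdf <- (pbeta(sort(x), spec$a, spec$b) - plo) / (phi - plo)
  ks <- max(abs(cdf - seq_len(n) / n))
  expect_lt(ks, 0.01)
})

test_that("near-degenerate truncation pins draws to the bound", {
  spec <- trunc_beta_spec(0.841, 0.035, 0.8410, 0.8412)
  x <- draw_samples(spec, 1000, seed = 1)
  expect_true(all(abs(x - 0.841) < 2e-4))
})

test_that("negligible-mass truncation regions raise a sampling error", {
  spec <- trunc_beta_spec(0.5, 0.01, lower = 0.99, upper = 0.995)
  expect_error(draw_samples(spec, 10, seed = 1), "negligible")
})

test_that("lognormal draws with natural mean 1, sd 0.4 average to 1", {
  spec <- lognormal_spec(1, 0.4)
  n <- 1e6
  x <- draw_samples(spec, n, seed = 13)
  expect_lt(abs(mean(x) - 1), 3 * sd(x) / sqrt(n))
  expect_lt(abs(sd(x) - 0.4), 0.01)
})

test_that("specs serialise to config lists and back", {
  for (spec in list(trunc_beta_spec(0.841, 0.035, 0.770, 0.925),
                    trunc_normal_spec(1, 2, 0, Inf),
                    lognormal_spec(1, 0.4),
                    normal_spec(91.2, 4.72))) {
    rt <- spec_from_list(spec_to_list(spec))
    expect_identical(class(rt), class(spec))
    expect_equal(spec_to_list(rt), spec_to_list(spec))
  }
})
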