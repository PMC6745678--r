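# Independent oracles used across the suite. Each deliberately avoids the
# package's own code path for the quantity it checks.

# Power iteration for the dominant eigenpair of a non-negative matrix.
power_iteration <- function(A, iter = 5000, tol = 1e-13) {
  w <- rep(1, nrow(A)) / nrow(A)
  lam <- NA_real_
  for (i in seq_len(iter)) {
    z <- drop(A %*% w)
    lam_new <- sum(z)
    z <- z / lam_new
    if (all(abs(z - w) < tol)) { w <- z; lam <- lam_new; break }
    w <- z; lam <- lam_new
  }
  v <- rep(1, nrow(A)) / nrow(A)
  for (i in seq_len(iter)) {
    z <- drop(crossprod(A, v))
    z <- z / sum(z)
    if (all(abs(z - v) < tol)) { v <- z; break }
    v <- z
  }
  v <- v / sum(v * w)
  list(lambda_max = lam, w = w, v = v)
}

# Bisection oracle for the fixed-point equation.
bisect_lambda <- function(a_raT, alpha, s, tol = 1e-14) {
  g <- function(l) l - exp(a_raT / (alpha + s / (l - s)))
  stats::uniroot(g, c(1 + 1e-9, exp(a_raT / alpha)), tol = tol)$root
}

# Brute-force shortest interval containing ceiling(mass * n) sorted points.
hdi_brute <- function(x, mass) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    if (x[i + m - 1] - x[i] < best[2] - best[1]) best <- c(x[i], x[i + m - 1])
  }
  best
}

# Quadrature mean of a truncated Beta density.
trunc_beta_mean_quad <- function(a, b, lo, hi) {
  z <- stats::integrate(function(x) stats::dbeta(x, a, b), lo, hi)$value
  stats::integrate(function(x) x * stats::dbeta(x, a, b), lo, hi)$value / z
}

loggerhead_growth_table <- function() {
  read_growth_table(system.file("extdata", "growth_studies_nwa.csv",
                                package = "dimrmax"))
}

# Small meta-analysis fit shared by age-slicing tests (cached per session).
small_meta_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- fit_growth_meta(loggerhead_growth_table(), chains = 2,
                                iter = 3000, burn = 1000, seed = 42)
    cache
  }
})
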