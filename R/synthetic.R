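#' Synthetic (r_max, T_op) pairs obeying the allometric invariant
#'
#' Generates regression inputs satisfying `r_max * T_op = a_raT` up to
#' multiplicative lognormal scatter: generation times are uniform on
#' `top_range` (default 1-50 years, the span of turtle matrix models) and
#' `r_max = (a_raT / T_op) * exp(eps)`, `eps ~ Normal(0, log_scatter_sd^2)`
#' — the same error structure the log-log regression assumes.
#'
#' @param n_populations Number of pairs (>= 2; default 14, the size of the
#'   turtle matrix-model compilation).
#' @param true_a_raT True dimensionless constant (default 1).
#' @param log_scatter_sd Residual sd on the log scale (default 0.2).
#' @param top_range Range of generation times in years.
#' @param seed Integer seed.
#' @return A [regression_data] frame with columns `label`, `r_max`,
#'   `t_op_bar`.
#' @export
gen_allometric_pairs <- function(n_populations = 14L, true_a_raT = 1,
                                 log_scatter_sd = 0.2,
                                 top_range = c(1, 50), seed = 1L) {
  if (n_populations < 2) stop("'n_populations' must be at least 2")
  if (true_a_raT <= 0) stop("'true_a_raT' must be positive")
  if (log_scatter_sd < 0) stop("'log_scatter_sd' must be non-negative")
  set.seed(seed)
  top <- stats::runif(n_populations, top_range[1], top_range[2])
  eps <- if (log_scatter_sd > 0) stats::rnorm(n_populations, 0, log_scatter_sd)
         else numeric(n_populations)
  regression_data(data.frame(label = sprintf("pop_%02d", seq_len(n_populations)),
                             r_max = (true_a_raT / top) * exp(eps),
                             t_op_bar = top))
}

#' Synthetic growth-study tables from the assumed bivariate law
#'
#' Draws study-level `(L_inf, log k)` pairs from
#' `BVN(true_mu, true_sigma)` and back-transforms `k = exp(log k)`, so every
#' generated `k` is positive by construction. Defaults emulate the northwest
#' Atlantic loggerhead compilation: mean asymptotic length 100 cm SCL, mean
#' log growth coefficient -2.85 (k about 0.058/yr), between-study variances
#' 40 (cm^2) and 0.13.
#'
#' @param n_studies Number of studies (>= 2).
#' @param true_mu Length-2 mean vector `(L_inf_bar, ln_k_bar)`.
#' @param true_sigma 2x2 between-study covariance (positive definite).
#' @param seed Integer seed.
#' @return Growth-study table (data frame `study`, `L_inf_cm`, `k_per_year`).
#' @export
gen_growth_studies <- function(n_studies = 9L,
                               true_mu = c(100, -2.85),
                               true_sigma = diag(c(40, 0.13)),
                               seed = 1L) {
  if (n_studies < 2) stop("'n_studies' must be at least 2")
  true_sigma <- as.matrix(true_sigma)
  ev <- eigen(true_sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < 0)) stop("'true_sigma' must be positive semi-definite")
  set.seed(seed)
  # symmetric square root via eigendecomposition: tolerates semi-definite
  # (including degenerate point-mass) covariances
  es <- eigen(true_sigma, symmetric = TRUE)
  Rt <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  z <- matrix(stats::rnorm(2L * n_studies), n_studies, 2L)
  theta <- sweep(z %*% Rt, 2, true_mu, `+`)
  data.frame(study = sprintf("synth_%03d", seq_len(n_studies)),
             L_inf_cm = theta[, 1],
             k_per_year = exp(theta[, 2]))
}

#' Synthetic Leslie projection matrices
#'
#' Builds an age-classified (Leslie) projection matrix from per-age survival
#' and fecundity vectors, with the fertility split on the first row; the
#' scalar case (`n_ages = 1`) returns a 1x1 matrix. These have
#' oracle-checkable growth rates and generation times: a semelparous matrix
#' reproducing only at age `a` with `lambda = 1` has generation time exactly
#' `a`.
#'
#' @param survival Survival probabilities between successive age classes
#'   (length `n_ages - 1`; empty for the scalar case).
#' @param fecundity Per-age fecundities (length `n_ages`, first row of `F`).
#' @param label Record label.
#' @return An [mpm_record].
#' @examples
#' # semelparous: mature at 3, survival 1, fecundity balancing lambda = 1
#' rec <- gen_leslie_mpm(c(1, 1), c(0, 0, 1), "semelparous_age3")
#' generation_time(rec)  # 3
#' @export
gen_leslie_mpm <- function(survival, fecundity, label = "leslie") {
  n_ages <- length(fecundity)
  if (n_ages < 1) stop("need at least one age class")
  if (length(survival) != n_ages - 1)
    stop("'survival' must have length(fecundity) - 1 entries")
  if (any(survival < 0 | survival > 1)) stop("survival must lie in [0, 1]")
  if (any(fecundity < 0)) stop("fecundity must be non-negative")
  A <- matrix(0, n_ages, n_ages)
  A[1, ] <- fecundity
  if (n_ages > 1)
    A[cbind(2:n_ages, 1:(n_ages - 1))] <- survival
  F <- matrix(0, n_ages, n_ages)
  F[1, ] <- fecundity
  mpm_record(A, F, label = label, source = "synthetic Leslie builder")
}

#' Random synthetic Leslie matrices
#'
#' Convenience generator for property tests and the optimal-conditions
#' filter: random survivals and fecundities with a configurable number of
#' age classes.
#'
#' @param n_matrices Number of records.
#' @param max_ages Maximum number of age classes (uniform on 2..max_ages).
#' @param seed Integer seed.
#' @return List of [mpm_record]s.
#' @export
gen_random_leslie <- function(n_matrices = 10L, max_ages = 8L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_matrices), function(i) {
    k <- sample(2:max_ages, 1)
    surv <- stats::runif(k - 1, 0.3, 0.95)
    fec <- c(rep(0, k - 1), stats::runif(1, 0.5, 5))
    fec[k - 1] <- stats::runif(1, 0, 1)   # some iteroparity
    gen_leslie_mpm(surv, fec, label = sprintf("rand_leslie_%02d", i))
  })
}
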