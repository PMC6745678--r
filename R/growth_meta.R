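#' Log-transform a growth-study table
#'
#' Maps each study's von Bertalanffy pair `(L_inf, k)` to `(L_inf, log k)`.
#' Working on the log scale keeps the Brody growth coefficient positive when
#' the pairs are modelled as bivariate normal.
#'
#' @param table Data frame with columns `L_inf_cm` and `k_per_year` (a
#'   growth-study table as returned by [read_growth_table()]).
#' @return Numeric matrix with columns `L_inf` and `ln_k`, one row per study.
#' @export
log_transform_studies <- function(table) {
  if (!all(c("L_inf_cm", "k_per_year") %in% names(table)))
    stop("'table' needs columns L_inf_cm and k_per_year")
  if (any(table$k_per_year <= 0))
    stop("all k must be positive to take logs")
  cbind(L_inf = table$L_inf_cm, ln_k = log(table$k_per_year))
}

# Conditional Wishart update for the precision matrix given mu and the
# observations (rows of theta). Convention: the prior is Wishart with scale
# matrix R and df degrees of freedom in the trace parameterisation
# p(Omega) propto |Omega|^((df-p-1)/2) exp(-tr(R Omega)/2), i.e. prior mean
# df * R^-1 (stats::rWishart(df, solve(R))). The conjugate update is then
# Omega | mu, theta ~ Wishart(df + n, scale (R + S)^-1) with
# S = sum_i (theta_i - mu)(theta_i - mu)'.
draw_omega <- function(theta, mu, R, df) {
  centred <- sweep(theta, 2, mu)
  S <- crossprod(centred)
  stats::rWishart(1, df + nrow(theta), solve(R + S))[, , 1]
}

# Conditional bivariate-normal update for mu given Omega: vague independent
# univariate normal priors N(m0_j, precision tau0) combine with the
# likelihood precision n * Omega.
draw_mu <- function(theta, omega, m0, tau0) {
  n <- nrow(theta)
  P <- diag(tau0, ncol(theta)) + n * omega
  b <- tau0 * m0 + omega %*% colSums(theta)
  U <- chol(P)
  m <- backsolve(U, forwardsolve(t(U), b))
  drop(m + backsolve(U, stats::rnorm(ncol(theta))))
}

#' Hierarchical meta-analysis of von Bertalanffy growth parameters
#'
#' Gibbs sampler for the bivariate normal-lognormal (NLN) model: each study's
#' `(L_inf_i, log k_i)` is a draw from `BVN(mu, Sigma)`, with vague
#' independent univariate normal priors on the components of `mu` (default
#' mean 0, precision 1e-3) and a Wishart prior on the precision matrix
#' `Omega = Sigma^-1` (default: identity scale, 2 degrees of freedom). The
#' two full conditionals are conjugate, so the sampler alternates exact
#' draws of `mu | Omega` and `Omega | mu`.
#'
#' @param table Growth-study table (columns `study`, `L_inf_cm`,
#'   `k_per_year`), e.g. from [read_growth_table()] or
#'   [gen_growth_studies()].
#' @param prior_mu_mean Length-2 prior mean of `mu` (default `c(0, 0)`).
#' @param prior_mu_precision Scalar prior precision of each component
#'   (default 1e-3).
#' @param wishart_scale 2x2 scale matrix `R` of the Wishart prior (default
#'   identity).
#' @param wishart_df Degrees of freedom (default 2; must be >= dimension).
#' @param chains,iter,burn MCMC size: defaults 4 chains x 10000 draws, 2000
#'   burn-in each.
#' @param seed Integer seed; each chain uses a derived child seed.
#' @return Object of class `growth_meta`: list with `draws` (data frame of
#'   kept joint draws `L_inf_bar`, `ln_k_bar`, `omega_11`, `omega_12`,
#'   `omega_22`), `n_studies`, `settings`, `seed`.
#' @examples
#' tab <- read_growth_table(system.file("extdata", "growth_studies_nwa.csv",
#'                                      package = "dimrmax"))
#' fit <- fit_growth_meta(tab, chains = 2, iter = 2000, burn = 500, seed = 1)
#' coef(fit)
#' @export
fit_growth_meta <- function(table,
                            prior_mu_mean = c(0, 0),
                            prior_mu_precision = 1e-3,
                            wishart_scale = diag(2),
                            wishart_df = 2,
                            chains = 4L, iter = 10000L, burn = 2000L,
                            seed = 1L) {
  theta <- log_transform_studies(table)
  n <- nrow(theta)
  if (n < 2) stop("need at least 2 studies to fit the hierarchical model")
  if (wishart_df < ncol(theta))
    stop("Wishart degrees of freedom must be >= the dimension (2)")
  if (prior_mu_precision <= 0) stop("'prior_mu_precision' must be positive")
  if (burn >= iter) stop("'burn' must be smaller than 'iter'")
  R <- as.matrix(wishart_scale)

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    mu <- colMeans(theta)
    omega <- tryCatch(solve(stats::cov(theta)), error = function(e) diag(2))
    keep <- iter - burn
    out <- matrix(NA_real_, keep, 5)
    for (it in seq_len(iter)) {
      omega <- draw_omega(theta, mu, R, wishart_df)
      mu <- draw_mu(theta, omega, prior_mu_mean, prior_mu_precision)
      if (it > burn)
        out[it - burn, ] <- c(mu, omega[1, 1], omega[1, 2], omega[2, 2])
    }
    out
  }

  draws <- do.call(rbind, lapply(seq_len(chains),
                                 function(cc) run_chain(child_seed(seed, cc))))
  draws <- as.data.frame(draws)
  names(draws) <- c("L_inf_bar", "ln_k_bar", "omega_11", "omega_12", "omega_22")
  structure(list(draws = draws, n_studies = n,
                 settings = list(prior_mu_mean = prior_mu_mean,
                                 prior_mu_precision = prior_mu_precision,
                                 wishart_scale = R, wishart_df = wishart_df,
                                 chains = chains, iter = iter, burn = burn),
                 seed = seed),
            class = "growth_meta")
}

#' @export
print.growth_meta <- function(x, ...) {
  cat(sprintf("NLN growth meta-analysis: %d studies, %d kept draws\n",
              x$n_studies, nrow(x$draws)))
  cat("L_inf_bar (cm SCL): "); print(summary_stats(x$draws$L_inf_bar))
  cat("k_bar (/year):      "); print(summary_stats(exp(x$draws$ln_k_bar)))
  invisible(x)
}

#' @export
coef.growth_meta <- function(object, ...) {
  c(L_inf_bar = mean(object$draws$L_inf_bar),
    ln_k_bar = mean(object$draws$ln_k_bar),
    k_bar = exp(mean(object$draws$ln_k_bar)))
}

#' @export
summary.growth_meta <- function(object, mass = 0.95, ...) {
  out <- list(L_inf_bar = summary_stats(object$draws$L_inf_bar, mass),
              ln_k_bar = summary_stats(object$draws$ln_k_bar, mass),
              n_studies = object$n_studies)
  structure(out, class = "summary.growth_meta")
}

#' @export
print.summary.growth_meta <- function(x, ...) {
  cat("L_inf_bar: "); print(x$L_inf_bar)
  cat("ln_k_bar:  "); print(x$ln_k_bar)
  invisible(x)
}

#' @export
plot.growth_meta <- function(x, ...) {
  plot(x$draws$L_inf_bar, x$draws$ln_k_bar, pch = ".",
       xlab = "L_inf_bar (cm SCL)", ylab = "ln k_bar",
       main = "Joint posterior of the population-level growth means", ...)
  invisible(x)
}
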