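#' Solve the demographic-invariant fixed point for the finite maximum growth rate
#'
#' Solves `lambda = exp(a_raT / (alpha + s / (lambda - s)))` for the finite
#' annual maximum growth rate `lambda_max`, given the dimensionless allometric
#' constant `a_raT`, age-at-first-reproduction `alpha` (years) and constant
#' adult survival `s`. The bracketed term is the optimal generation time, so
#' the solution satisfies `lambda_max ^ T_op = exp(a_raT)` exactly: a
#' population can grow at most `e^a_raT`-fold per generation.
#'
#' Damped-free fixed-point iteration from
#' `lambda_0 = exp(a_raT / (alpha + s/(1 - s)))`; the map is a strong
#' contraction over biologically plausible parameters. Draws not converged
#' within `max_iter` sweeps fall back to bisection on
#' `(1 + 1e-12, exp(a_raT / alpha))`, which brackets the unique root.
#'
#' @param a_raT Allometric constant (> 0); vectorised.
#' @param alpha Age-at-first-reproduction in years (>= 1); vectorised.
#' @param s Annual adult survival in (0, 1); vectorised.
#' @param tol Convergence tolerance on the fixed-point residual
#'   (default 1e-12).
#' @param max_iter Iteration cap before the bisection fallback (default 200).
#' @return `lambda_max`, same length as the recycled inputs; every value lies
#'   in `(1, exp(a_raT / alpha)]`.
#' @examples
#' solve_lambda_max(1, 41, 0.841)  # about 1.0222
#' @export
solve_lambda_max <- function(a_raT, alpha, s, tol = 1e-12, max_iter = 200L) {
  n <- max(length(a_raT), length(alpha), length(s))
  a_raT <- rep_len(a_raT, n); alpha <- rep_len(alpha, n); s <- rep_len(s, n)
  if (any(a_raT <= 0)) stop("'a_raT' must be positive")
  if (any(alpha < 1)) stop("'alpha' must be at least 1 year")
  if (any(s <= 0 | s >= 1)) stop("'s' must lie strictly inside (0, 1)")
  if (tol <= 0) stop("'tol' must be positive")

  fmap <- function(lam, i) exp(a_raT[i] / (alpha[i] + s[i] / (lam - s[i])))
  lam <- exp(a_raT / (alpha + s / (1 - s)))
  active <- seq_len(n)
  for (it in seq_len(max_iter)) {
    nxt <- fmap(lam[active], active)
    moved <- abs(nxt - lam[active]) >= tol
    lam[active] <- nxt
    active <- active[moved]
    if (length(active) == 0L) break
  }
  if (length(active) > 0L) {
    for (i in active) {
      g <- function(l) l - exp(a_raT[i] / (alpha[i] + s[i] / (l - s[i])))
      lo <- 1 + 1e-12; hi <- exp(a_raT[i] / alpha[i])
      if (g(lo) > 0 || g(hi) < 0)
        stop(sprintf("bracket failure for (a_raT, alpha, s) = (%g, %g, %g)",
                     a_raT[i], alpha[i], s[i]))
      lam[i] <- stats::uniroot(g, c(lo, hi), tol = tol)$root
      if (abs(g(lam[i])) > 1e-6)
        stop(sprintf("solver failed to converge for (a_raT, alpha, s) = (%g, %g, %g)",
                     a_raT[i], alpha[i], s[i]))
    }
  }
  lam
}

#' Optimal generation time
#'
#' `T_op = alpha + s / (lambda_max - s)`: age-at-first-reproduction plus the
#' mean adult reproductive lifespan discounted by population growth.
#'
#' @param alpha Age-at-first-reproduction (years).
#' @param s Annual adult survival.
#' @param lambda_max Finite annual growth rate; must exceed `s`.
#' @return Generation time in years.
#' @examples
#' optimal_generation_time(41, 0.841, solve_lambda_max(1, 41, 0.841))
#' @export
optimal_generation_time <- function(alpha, s, lambda_max) {
  if (any(lambda_max <= s))
    stop("'lambda_max' must exceed 's' (generation time undefined otherwise)")
  alpha + s / (lambda_max - s)
}

#' Monte Carlo propagation to the maximum-growth-rate distribution
#'
#' Draws `n` independent triples — the allometric constant from its assumed
#' lognormal, adult survival from its truncated Beta, and
#' age-at-first-reproduction resampled with replacement from an
#' [slice_ages()] result — solves the fixed point for each, and summarises
#' `R_max = lambda_max - 1` (the finite approximation of the instantaneous
#' rate; `r_max = log(lambda_max)` is also stored).
#'
#' @param alpha_samples An [alpha_samples] object (or a bare numeric vector
#'   of ages).
#' @param survival [trunc_beta_spec] for adult survival; default truncated
#'   Beta(mean 0.841, sd 0.035) on (0.770, 0.925).
#' @param a_raT_dist [lognormal_spec] for the allometric constant; default
#'   natural-scale mean 1, sd 0.4.
#' @param n Number of Monte Carlo draws (>= 1000; default 1e6).
#' @param seed Integer seed.
#' @return Object of class `rmax_mc`: list with `draws` (data frame
#'   `a_raT`, `alpha`, `s`, `lambda_max`, `top`, `r_max`, `R_max`),
#'   `summary` ([summary_stats] of `R_max`), `n`, `seed`.
#' @export
run_monte_carlo <- function(alpha_samples,
                            survival = trunc_beta_spec(0.841, 0.035, 0.770, 0.925),
                            a_raT_dist = lognormal_spec(1, 0.4),
                            n = 1e6, seed = 1L) {
  ages <- if (inherits(alpha_samples, "alpha_samples")) alpha_samples$ages
          else as.numeric(alpha_samples)
  if (length(ages) == 0L) stop("'alpha_samples' is empty")
  if (n < 1e3) stop("'n' must be at least 1000")
  set.seed(seed)
  alpha <- pmax(ages[sample.int(length(ages), n, replace = TRUE)], 1)
  s <- draw_samples(survival, n)
  a <- draw_samples(a_raT_dist, n)
  lam <- solve_lambda_max(a, alpha, s)
  top <- optimal_generation_time(alpha, s, lam)
  draws <- data.frame(a_raT = a, alpha = alpha, s = s,
                      lambda_max = lam, top = top,
                      r_max = log(lam), R_max = lam - 1)
  structure(list(draws = draws, summary = summary_stats(draws$R_max),
                 n = n, seed = seed,
                 survival = survival, a_raT_dist = a_raT_dist),
            class = "rmax_mc")
}

#' @export
print.rmax_mc <- function(x, ...) {
  cat(sprintf("Monte Carlo R_max distribution (n = %d draws)\n", x$n))
  cat("R_max (/year): "); print(x$summary)
  invisible(x)
}

#' @export
summary.rmax_mc <- function(object, mass = 0.95, ...) {
  list(R_max = summary_stats(object$draws$R_max, mass),
       r_max = summary_stats(object$draws$r_max, mass),
       lambda_max = summary_stats(object$draws$lambda_max, mass),
       top = summary_stats(object$draws$top, mass))
}

#' @export
plot.rmax_mc <- function(x, ...) {
  d <- stats::density(x$draws$R_max)
  plot(d, main = "Approximate maximum population growth rate",
       xlab = "R_max (/year)", ...)
  graphics::abline(v = x$summary$median, lty = 2)
  invisible(x)
}

#' Demographic-invariant estimate of the maximum population growth rate
#'
#' Top-level fitter running the full pipeline: (1) hierarchical NLN
#' meta-analysis of the growth-study table ([fit_growth_meta()]); (2) age
#' slicing of the neophyte-nester size distribution into
#' age-at-first-reproduction ([slice_ages()]); (3) Monte Carlo propagation
#' through the fixed-point equation ([run_monte_carlo()]). Defaults
#' reproduce the northwest Atlantic loggerhead analysis. Each stage receives
#' a child seed derived from `seed`.
#'
#' @param growth_table Growth-study table (see [read_growth_table()]); default
#'   the packaged northwest Atlantic loggerhead table.
#' @param nesters [normal_spec] for neophyte-nester sizes (cm SCL).
#' @param survival [trunc_beta_spec] for annual adult survival.
#' @param a_raT_dist [lognormal_spec] for the allometric constant.
#' @param tmax,hatchling_length Age-slicing constants (years; cm SCL).
#' @param n Monte Carlo draw count for both age slicing and the propagation
#'   stage (default 1e6).
#' @param chains,iter,burn MCMC size of the growth meta-analysis.
#' @param seed Master seed.
#' @return Object of class `rmax_dim`: list with the stage results
#'   `growth_meta`, `alpha`, `mc`, the `summary` ([summary_stats] of
#'   `R_max`), and `seed`.
#' @examples
#' \donttest{
#' fit <- rmax_dim(n = 1e4, chains = 2, iter = 3000, burn = 1000, seed = 1)
#' summary(fit)
#' }
#' @export
rmax_dim <- function(growth_table = read_growth_table(
                       system.file("extdata", "growth_studies_nwa.csv",
                                   package = "dimrmax")),
                     nesters = normal_spec(91.2, 4.72),
                     survival = trunc_beta_spec(0.841, 0.035, 0.770, 0.925),
                     a_raT_dist = lognormal_spec(1, 0.4),
                     tmax = 100, hatchling_length = 4.5,
                     n = 1e6,
                     chains = 4L, iter = 10000L, burn = 2000L,
                     seed = 1L) {
  meta <- fit_growth_meta(growth_table, chains = chains, iter = iter,
                          burn = burn, seed = child_seed(seed, 1))
  alpha <- slice_ages(meta, nesters = nesters, tmax = tmax,
                      hatchling_length = hatchling_length,
                      n = n, seed = child_seed(seed, 2))
  mc <- run_monte_carlo(alpha, survival = survival, a_raT_dist = a_raT_dist,
                        n = n, seed = child_seed(seed, 3))
  structure(list(growth_meta = meta, alpha = alpha, mc = mc,
                 summary = mc$summary, n = n, seed = seed),
            class = "rmax_dim")
}

#' @export
print.rmax_dim <- function(x, ...) {
  cat("Demographic-invariant maximum population growth rate\n")
  cat(sprintf("  growth meta-analysis: %d studies; age slicing + Monte Carlo: n = %d\n",
              x$growth_meta$n_studies, x$n))
  cat("  R_max (/year): "); print(x$summary)
  invisible(x)
}

#' @export
summary.rmax_dim <- function(object, mass = 0.95, ...) {
  structure(list(growth = summary(object$growth_meta, mass),
                 alpha = summary_stats(object$alpha$ages, mass),
                 R_max = summary_stats(object$mc$draws$R_max, mass),
                 lambda_max = summary_stats(object$mc$draws$lambda_max, mass)),
            class = "summary.rmax_dim")
}

#' @export
print.summary.rmax_dim <- function(x, ...) {
  print(x$growth)
  cat("alpha (years): "); print(x$alpha)
  cat("R_max (/year): "); print(x$R_max)
  invisible(x)
}

#' @export
coef.rmax_dim <- function(object, ...) {
  s <- object$summary
  c(Rmax_mean = s$mean, Rmax_median = s$median, Rmax_mode = s$mode,
    Rmax_hdi_low = s$hdi_low, Rmax_hdi_high = s$hdi_high)
}

#' @export
plot.rmax_dim <- function(x, ...) {
  plot(x$mc, ...)
}

#' Re-draw the Monte Carlo stage of a fitted pipeline
#'
#' `simulate` re-runs the propagation stage (new seeds, same fitted growth
#' posterior and age distribution), returning one `R_max` draw vector per
#' simulation.
#'
#' @param object A fitted [rmax_dim()] object.
#' @param nsim Number of replicate Monte Carlo runs.
#' @param seed Base seed for the replicates.
#' @param n Draws per replicate (default: a tenth of the fitted size).
#' @param ... Unused.
#' @return Data frame with `nsim` columns of `R_max` draws.
#' @export
simulate.rmax_dim <- function(object, nsim = 1, seed = 1L,
                              n = max(1e3, object$n / 10), ...) {
  out <- lapply(seq_len(nsim), function(i) {
    run_monte_carlo(object$alpha, survival = object$mc$survival,
                    a_raT_dist = object$mc$a_raT_dist,
                    n = n, seed = child_seed(seed, i))$draws$R_max
  })
  names(out) <- paste0("sim_", seq_len(nsim))
  as.data.frame(out)
}
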