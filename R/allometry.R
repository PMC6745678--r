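#' Regression data for the allometric-constant fit
#'
#' Validates a table of `(r_max, t_op_bar)` pairs — per-year instantaneous
#' maximum growth rates and mean optimal generation times — as produced by
#' [filter_optimal()] or [gen_allometric_pairs()].
#'
#' @param data Data frame with numeric columns `r_max` and `t_op_bar`, all
#'   strictly positive.
#' @return The validated data frame, classed `regression_data`.
#' @export
regression_data <- function(data) {
  if (!all(c("r_max", "t_op_bar") %in% names(data)))
    stop("'data' needs columns r_max and t_op_bar")
  if (nrow(data) > 0 && (any(data$r_max <= 0) || any(data$t_op_bar <= 0)))
    stop("all r_max and t_op_bar must be strictly positive (log-log regression)")
  class(data) <- unique(c("regression_data", class(data)))
  data
}

# Exact conditional draw of the residual sd under its Uniform(0,1) prior:
# the precision 1/sigma^2 is Gamma((n-1)/2, rate SS/2) truncated to > 1,
# drawn by inverse-CDF restriction. n = 0 returns a plain uniform draw
# (prior recovery).
draw_sigma <- function(n, SS) {
  if (n < 2 || SS <= 0) return(stats::runif(1))
  shape <- (n - 1) / 2
  rate <- SS / 2
  p1 <- stats::pgamma(1, shape, rate = rate)
  u <- stats::runif(1, p1, 1)
  x <- stats::qgamma(u, shape, rate = rate)
  if (!is.finite(x) || x <= 1) x <- 1 + 1e-12
  1 / sqrt(x)
}

# Random-walk Metropolis kernel on one positive/real parameter; returns the
# new value and whether the proposal was accepted.
mh_step <- function(cur, log_post, step, positive = FALSE) {
  prop <- cur + stats::rnorm(1, 0, step)
  if (positive && prop <= 0) return(list(value = cur, accepted = FALSE))
  lr <- log_post(prop) - log_post(cur)
  if (is.finite(lr) && log(stats::runif(1)) < lr)
    list(value = prop, accepted = TRUE)
  else
    list(value = cur, accepted = FALSE)
}

split_rhat <- function(draws_by_chain) {
  halves <- unlist(lapply(draws_by_chain, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  mu <- vapply(halves, mean, 0)
  s2 <- vapply(halves, stats::var, 0)
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bayesian log-log regression for the dimensionless allometric constant
#'
#' Fits `log(r_max_i) = beta1 * log(T_op_i) + log(a_raT) + eps_i`,
#' `eps_i ~ Normal(0, sigma^2)`, by Metropolis-within-Gibbs. With
#' `slope = "fixed"` the slope is held at -1, reducing the model to an
#' intercept-only fit on `y_i = log(r_max_i) + log(T_op_i)`; with
#' `slope = "free"` the slope is estimated (vague Normal(0, 10) prior) and the
#' fit reports whether its HDI covers -1.
#'
#' Priors: `a_raT ~ Normal(1, 2)` truncated to positives (configurable), and
#' `sigma ~ Uniform(0, 1)`, honoured exactly. The `a_raT` update is
#' random-walk Metropolis on the natural scale (positivity enforced), with the
#' proposal scale adapted toward 20--50% acceptance during burn-in only; the
#' `sigma` update is an exact draw from its conditional.
#'
#' @param data A [regression_data] table (or coercible data frame).
#' @param slope `"fixed"` (slope -1) or `"free"`.
#' @param prior_araT [trunc_normal_spec] prior on the constant; lower bound
#'   must be 0.
#' @param prior_beta1_sd Prior sd of the free slope (mean 0).
#' @param chains,iter,burn MCMC size: `chains` chains of `iter` draws each,
#'   first `burn` discarded. Defaults 4 x 10000, burn 2000.
#' @param seed Integer seed (chain c uses a derived child seed).
#' @return An object of class `allometry_fit` with elements `draws` (data
#'   frame of kept posterior draws: `araT`, `sigma`, and `beta1` when free),
#'   `model`, `diagnostics` (split R-hat, acceptance rates), `prior`, `n_data`,
#'   and for the free-slope model `beta1_hdi_covers_minus1`.
#' @export
fit_allometry <- function(data,
                          slope = c("fixed", "free"),
                          prior_araT = trunc_normal_spec(1, 2, 0, Inf),
                          prior_beta1_sd = 10,
                          chains = 4L, iter = 10000L, burn = 2000L,
                          seed = 1L) {
  slope <- match.arg(slope)
  data <- regression_data(as.data.frame(data))
  n <- nrow(data)
  if (slope == "fixed" && n > 0 && n < 2)
    stop("fixed-slope fit needs at least 2 data pairs")
  if (slope == "free" && n < 3)
    stop("free-slope fit needs at least 3 data pairs (3 parameters)")
  if (prior_araT$lower != 0)
    stop("prior on a_raT must be truncated at 0")
  if (burn >= iter) stop("'burn' must be smaller than 'iter'")

  x <- log(data$t_op_bar)
  y <- log(data$r_max)
  # sufficient statistics -> O(1) per-iteration likelihood evaluation
  if (slope == "fixed") {
    z <- y + x                       # intercept-only observations
    Sz <- sum(z); Szz <- sum(z * z)
    SSfun <- function(a, b1) Szz - 2 * log(a) * Sz + n * log(a)^2
  } else {
    Sx <- sum(x); Sxx <- sum(x * x); Sy <- sum(y); Syy <- sum(y * y)
    Sxy <- sum(x * y)
    SSfun <- function(a, b1) {
      b0 <- log(a)
      Syy + n * b0^2 + b1^2 * Sxx - 2 * b0 * Sy - 2 * b1 * Sxy + 2 * b1 * b0 * Sx
    }
  }

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    a <- if (n > 0) max(exp(mean(y + if (slope == "fixed") x else 0)), 1e-6)
         else prior_araT$mu
    b1 <- -1
    sig <- 0.5
    step_a <- 0.5; step_b <- 0.5
    keep <- iter - burn
    out_a <- numeric(keep); out_s <- numeric(keep)
    out_b <- if (slope == "free") numeric(keep) else NULL
    acc_a <- 0L; acc_b <- 0L
    lp_a <- function(av) stats::dnorm(av, prior_araT$mu, prior_araT$sigma, log = TRUE) -
      n * log(sig) - SSfun(av, b1) / (2 * sig^2)
    lp_b <- function(bv) stats::dnorm(bv, 0, prior_beta1_sd, log = TRUE) -
      n * log(sig) - SSfun(a, bv) / (2 * sig^2)
    for (it in seq_len(iter)) {
      st <- mh_step(a, lp_a, step_a, positive = TRUE)
      a <- st$value
      if (it <= burn) {       # Robbins-Monro-style adaptation, burn-in only
        step_a <- step_a * exp(0.5 * ((st$accepted) - 0.35) / sqrt(it))
      } else acc_a <- acc_a + st$accepted
      if (slope == "free") {
        st <- mh_step(b1, lp_b, step_b)
        b1 <- st$value
        if (it <= burn) step_b <- step_b * exp(0.5 * ((st$accepted) - 0.35) / sqrt(it))
        else acc_b <- acc_b + st$accepted
      }
      sig <- draw_sigma(n, SSfun(a, b1))
      if (it > burn) {
        out_a[it - burn] <- a
        out_s[it - burn] <- sig
        if (slope == "free") out_b[it - burn] <- b1
      }
    }
    list(araT = out_a, sigma = out_s, beta1 = out_b,
         acc_a = acc_a / keep, acc_b = if (slope == "free") acc_b / keep else NA)
  }

  res <- lapply(seq_len(chains), function(cc) run_chain(child_seed(seed, cc)))
  draws <- data.frame(araT = unlist(lapply(res, `[[`, "araT")),
                      sigma = unlist(lapply(res, `[[`, "sigma")))
  if (slope == "free")
    draws$beta1 <- unlist(lapply(res, `[[`, "beta1"))
  rhat <- split_rhat(lapply(res, `[[`, "araT"))
  diagnostics <- list(chains = chains, iter = iter, burn = burn,
                      rhat_araT = rhat,
                      accept_araT = mean(vapply(res, `[[`, 0, "acc_a")),
                      accept_beta1 = mean(vapply(res, `[[`, 0, "acc_b")))
  if (is.finite(rhat) && rhat > 1.05)
    warning(sprintf("split R-hat for a_raT is %.3f (> 1.05): chains may not have converged", rhat))
  fit <- structure(list(draws = draws, model = slope, n_data = n,
                        prior = list(araT = prior_araT, beta1_sd = prior_beta1_sd),
                        diagnostics = diagnostics, seed = seed),
                   class = "allometry_fit")
  if (slope == "free") {
    ci <- hdi(draws$beta1, 0.95)
    fit$beta1_hdi <- ci
    fit$beta1_hdi_covers_minus1 <- ci["low"] <= -1 && -1 <= ci["high"]
  }
  fit
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf("Allometric-constant regression (%s slope), n = %d pairs\n",
              x$model, x$n_data))
  cat("a_raT: "); print(summary_stats(x$draws$araT))
  if (x$model == "free") {
    cat("beta1: "); print(summary_stats(x$draws$beta1))
    cat(sprintf("95%% HDI for beta1 %s -1\n",
                if (x$beta1_hdi_covers_minus1) "covers" else "excludes"))
  }
  invisible(x)
}

#' @export
coef.allometry_fit <- function(object, ...) {
  out <- c(araT = mean(object$draws$araT), sigma = mean(object$draws$sigma))
  if (object$model == "free") out <- c(out, beta1 = mean(object$draws$beta1))
  out
}

#' @export
summary.allometry_fit <- function(object, mass = 0.95, ...) {
  out <- list(araT = summary_stats(object$draws$araT, mass),
              sigma = summary_stats(object$draws$sigma, mass))
  if (object$model == "free")
    out$beta1 <- summary_stats(object$draws$beta1, mass)
  out$diagnostics <- object$diagnostics
  structure(out, class = "summary.allometry_fit")
}

#' @export
print.summary.allometry_fit <- function(x, ...) {
  for (nm in setdiff(names(x), "diagnostics")) {
    cat(nm, ": ", sep = ""); print(x[[nm]])
  }
  cat(sprintf("split R-hat (a_raT): %.3f; acceptance %.2f\n",
              x$diagnostics$rhat_araT, x$diagnostics$accept_araT))
  invisible(x)
}

#' @export
plot.allometry_fit <- function(x, ...) {
  d <- stats::density(x$draws$araT)
  plot(d, main = "Posterior of the allometric constant a_raT",
       xlab = "a_raT (dimensionless)", ...)
  graphics::abline(v = mean(x$draws$araT), lty = 2)
  invisible(x)
}
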