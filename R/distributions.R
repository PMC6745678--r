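#' Moment-match a Beta distribution
#'
#' Solves for the shape parameters of a Beta distribution with the requested
#' mean and standard deviation. Used to parameterise the adult-survival
#' distribution from its published moments.
#'
#' @param mean Target mean, strictly inside (0, 1).
#' @param sd Target standard deviation; must satisfy `sd^2 < mean * (1 - mean)`.
#' @return Named numeric vector `c(a = , b = )` of Beta shapes.
#' @examples
#' beta_from_moments(0.841, 0.035)
#' @export
beta_from_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1L, length(sd) == 1L)
  if (mean <= 0 || mean >= 1)
    stop("'mean' must lie strictly inside (0, 1)")
  if (sd <= 0)
    stop("'sd' must be positive")
  v <- sd^2
  if (v >= mean * (1 - mean))
    stop(sprintf("infeasible variance: sd^2 = %g >= mean*(1-mean) = %g",
                 v, mean * (1 - mean)))
  nu <- mean * (1 - mean) / v - 1
  c(a = mean * nu, b = (1 - mean) * nu)
}

#' Moment-match a lognormal distribution
#'
#' Converts a natural-scale mean and standard deviation into log-scale
#' parameters, so that `exp(mu_log + sigma_log^2/2) = mean` and the natural
#' variance equals `sd^2`.
#'
#' @param mean Natural-scale mean (> 0).
#' @param sd Natural-scale standard deviation (>= 0; 0 returns the point-mass
#'   limit `c(log(mean), 0)`).
#' @return Named numeric vector `c(mu_log = , sigma_log = )`.
#' @examples
#' lognormal_from_moments(1, 0.4)
#' @export
lognormal_from_moments <- function(mean, sd) {
  stopifnot(length(mean) == 1L, length(sd) == 1L)
  if (mean <= 0) stop("'mean' must be positive")
  if (sd < 0) stop("'sd' must be non-negative")
  s2 <- log1p((sd / mean)^2)
  c(mu_log = log(mean) - s2 / 2, sigma_log = sqrt(s2))
}

#' Distribution specifications
#'
#' Small S3 constructors for the input distributions of the pipeline: a
#' truncated Beta (adult survival), a truncated normal (regression prior on
#' the allometric constant), a moment-parameterised lognormal (the assumed
#' allometric-constant distribution) and a plain normal (neophyte-nester
#' carapace lengths). The Beta and lognormal are parameterised by their
#' untruncated natural-scale moments; shapes are moment-matched at
#' construction.
#'
#' @param mean,sd Natural-scale moments.
#' @param lower,upper Truncation bounds (truncated families only).
#' @param mu,sigma Location and scale of the underlying normal
#'   (`trunc_normal_spec`).
#' @return An object of class `trunc_beta_spec`, `trunc_normal_spec`,
#'   `lognormal_spec` or `normal_spec`; all inherit from `dist_spec`.
#' @examples
#' trunc_beta_spec(0.841, 0.035, 0.770, 0.925)
#' lognormal_spec(1, 0.4)
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
trunc_beta_spec <- function(mean, sd, lower = 0, upper = 1) {
  if (!(0 <= lower && lower < upper && upper <= 1))
    stop("need 0 <= lower < upper <= 1")
  sh <- beta_from_moments(mean, sd)
  structure(list(family = "trunc_beta", mean = mean, sd = sd,
                 lower = lower, upper = upper,
                 a = unname(sh["a"]), b = unname(sh["b"])),
            class = c("trunc_beta_spec", "dist_spec"))
}

#' @rdname dist_spec
#' @export
trunc_normal_spec <- function(mu, sigma, lower = -Inf, upper = Inf) {
  if (sigma <= 0) stop("'sigma' must be positive")
  if (!(lower < upper)) stop("need lower < upper")
  structure(list(family = "trunc_normal", mu = mu, sigma = sigma,
                 lower = lower, upper = upper),
            class = c("trunc_normal_spec", "dist_spec"))
}

#' @rdname dist_spec
#' @export
lognormal_spec <- function(mean, sd) {
  p <- lognormal_from_moments(mean, sd)
  structure(list(family = "lognormal", mean = mean, sd = sd,
                 mu_log = unname(p["mu_log"]), sigma_log = unname(p["sigma_log"])),
            class = c("lognormal_spec", "dist_spec"))
}

#' @rdname dist_spec
#' @export
normal_spec <- function(mean, sd) {
  if (sd <= 0) stop("'sd' must be positive")
  structure(list(family = "normal", mean = mean, sd = sd),
            class = c("normal_spec", "dist_spec"))
}

#' @export
print.dist_spec <- function(x, ...) {
  bounds <- if (!is.null(x$lower))
    sprintf(" on [%g, %g]", x$lower, x$upper) else ""
  par <- if (!is.null(x$mean))
    sprintf("mean %g, sd %g", x$mean, x$sd)
  else
    sprintf("mu %g, sigma %g", x$mu, x$sigma)
  cat(sprintf("<%s: %s%s>\n", x$family, par, bounds))
  invisible(x)
}

#' Draw samples from a distribution specification
#'
#' Seeded, reproducible sampling. Truncated families sample by inverse-CDF
#' restriction of the uniform draw to the truncation region (never rejection),
#' so a run is deterministic given its seed and the draw count.
#'
#' @param spec A [dist_spec] object.
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed; when supplied the RNG state is set
#'   before drawing.
#' @return Numeric vector of length `n`; truncated families return draws
#'   strictly inside `[lower, upper]`.
#' @examples
#' draw_samples(trunc_beta_spec(0.841, 0.035, 0.770, 0.925), 5, seed = 1)
#' @export
draw_samples <- function(spec, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  UseMethod("draw_samples")
}

trunc_unif <- function(n, p_lo, p_hi) {
  if (p_hi - p_lo < 1e-6)
    stop("truncation region has negligible probability mass (", p_hi - p_lo, ")")
  stats::runif(n, p_lo, p_hi)
}

#' @export
draw_samples.trunc_beta_spec <- function(spec, n, seed = NULL) {
  p <- trunc_unif(n, stats::pbeta(spec$lower, spec$a, spec$b),
                  stats::pbeta(spec$upper, spec$a, spec$b))
  stats::qbeta(p, spec$a, spec$b)
}

#' @export
draw_samples.trunc_normal_spec <- function(spec, n, seed = NULL) {
  p <- trunc_unif(n, stats::pnorm(spec$lower, spec$mu, spec$sigma),
                  stats::pnorm(spec$upper, spec$mu, spec$sigma))
  stats::qnorm(p, spec$mu, spec$sigma)
}

#' @export
draw_samples.lognormal_spec <- function(spec, n, seed = NULL) {
  if (spec$sigma_log == 0) return(rep(spec$mean, n))
  stats::rlnorm(n, spec$mu_log, spec$sigma_log)
}

#' @export
draw_samples.normal_spec <- function(spec, n, seed = NULL) {
  stats::rnorm(n, spec$mean, spec$sd)
}

#' Density of a truncated specification
#'
#' Normalised density on the truncation region; used by tests as a quadrature
#' oracle and by plotting.
#'
#' @param spec A truncated [dist_spec].
#' @param x Evaluation points.
#' @return Density values (0 outside the bounds).
#' @export
dens_trunc <- function(spec, x) {
  if (inherits(spec, "trunc_beta_spec")) {
    z <- stats::pbeta(spec$upper, spec$a, spec$b) -
      stats::pbeta(spec$lower, spec$a, spec$b)
    d <- stats::dbeta(x, spec$a, spec$b) / z
  } else if (inherits(spec, "trunc_normal_spec")) {
    z <- stats::pnorm(spec$upper, spec$mu, spec$sigma) -
      stats::pnorm(spec$lower, spec$mu, spec$sigma)
    d <- stats::dnorm(x, spec$mu, spec$sigma) / z
  } else stop("not a truncated spec")
  d[x < spec$lower | x > spec$upper] <- 0
  d
}

#' Serialise / deserialise a distribution specification
#'
#' Converts specs to and from the plain named lists used in pipeline
#' configuration files (keys: `family`, `mean`, `sd`, `lower`, `upper`,
#' `mu`, `sigma`).
#'
#' @param spec A [dist_spec] (for `spec_to_list`).
#' @param x A named list with a `family` key (for `spec_from_list`).
#' @return A plain list, or a [dist_spec].
#' @export
spec_to_list <- function(spec) {
  keep <- intersect(c("family", "mean", "sd", "lower", "upper", "mu", "sigma"),
                    names(spec))
  unclass(spec)[keep]
}

#' @rdname spec_to_list
#' @export
spec_from_list <- function(x) {
  switch(x$family,
    trunc_beta = trunc_beta_spec(x$mean, x$sd, x$lower, x$upper),
    trunc_normal = trunc_normal_spec(x$mu, x$sigma,
                                     if (is.null(x$lower)) -Inf else x$lower,
                                     if (is.null(x$upper)) Inf else x$upper),
    lognormal = lognormal_spec(x$mean, x$sd),
    normal = normal_spec(x$mean, x$sd),
    stop("unknown distribution family: ", x$family))
}
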