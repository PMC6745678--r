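#' von Bertalanffy growth parameters
#'
#' @param L_inf Asymptotic length (cm SCL, > 0).
#' @param k Brody growth coefficient (per year, > 0).
#' @param t0 Hypothetical age at length 0 (years; typically negative).
#' @return Object of class `vbgf_params`.
#' @export
vbgf_params <- function(L_inf, k, t0 = 0) {
  if (any(L_inf <= 0)) stop("'L_inf' must be positive")
  if (any(k <= 0)) stop("'k' must be positive")
  structure(list(L_inf = L_inf, k = k, t0 = t0), class = "vbgf_params")
}

#' @export
print.vbgf_params <- function(x, ...) {
  cat(sprintf("<vbgf: L_inf %g cm, k %g /yr, t0 %g yr>\n",
              x$L_inf[1], x$k[1], x$t0[1]))
  invisible(x)
}

#' von Bertalanffy length at age
#'
#' `L(t) = L_inf * (1 - exp(-k (t - t0)))`.
#'
#' @param t Age (years); vectorised.
#' @param params A [vbgf_params].
#' @return Length (cm SCL).
#' @export
length_at_age <- function(t, params) {
  -params$L_inf * expm1(-params$k * (t - params$t0))
}

#' Anchor the growth curve at hatchling size
#'
#' Mark-recapture fits report no `t0`; it is recovered by inverting the
#' growth function at age 0 and hatchling length:
#' `t0 = (1/k) * log((L_inf - hatchling) / L_inf)`. Evaluating the forward
#' curve at age 0 then returns exactly the hatchling length.
#'
#' @param L_inf,k von Bertalanffy parameters (vectorised).
#' @param hatchling_length Length at age 0 (cm SCL; default 4.5, northwest
#'   Atlantic loggerhead hatchlings). Must be below `L_inf`.
#' @return `t0` in years (non-positive).
#' @examples
#' t0_from_hatchling(99.70, 0.0530)  # about -0.871
#' @export
t0_from_hatchling <- function(L_inf, k, hatchling_length = 4.5) {
  if (any(hatchling_length < 0)) stop("'hatchling_length' must be non-negative")
  if (any(hatchling_length >= L_inf))
    stop("'hatchling_length' must be below L_inf")
  log((L_inf - hatchling_length) / L_inf) / k
}

#' Age from length by growth-curve inversion
#'
#' `t = log(1 - L/L_inf) / (-k) + t0`. Only lengths strictly below `L_inf`
#' are invertible; callers applying the age-slicing filter must remove
#' individuals at or above `L_inf` before calling.
#'
#' @param L Length (cm SCL), `0 < L < L_inf`; vectorised.
#' @param params A [vbgf_params].
#' @return Age in years.
#' @examples
#' p <- vbgf_params(101.14, 0.0577, -0.789)
#' age_from_length(91.2, p)  # about 39.4 years
#' @export
age_from_length <- function(L, params) {
  if (any(L >= params$L_inf))
    stop("length at or above L_inf: all individuals greater than L_inf must be ",
         "removed before age slicing")
  if (any(L < 0)) stop("'L' must be non-negative")
  log1p(-L / params$L_inf) / (-params$k) + params$t0
}

#' Age-at-first-reproduction by age slicing
#'
#' Converts a neophyte-nester carapace-length distribution into an
#' age-at-first-reproduction distribution. Each Monte Carlo draw pairs a
#' nester length `L ~ Normal(mean, sd)` with one joint posterior draw of
#' `(L_inf_bar, ln_k_bar)` from the growth meta-analysis (the pair is taken
#' from the same MCMC iteration, preserving their posterior correlation),
#' anchors `t0` at the hatchling length, and inverts the growth curve.
#' Draws with `L >= L_inf` are removed (unsliceable), as are ages exceeding
#' `tmax`; lengths below the hatchling length are removed with their own
#' counter. Ages are kept continuous.
#'
#' @param meta A fitted [fit_growth_meta()] object.
#' @param nesters A [normal_spec] for nester sizes (cm SCL); default
#'   Normal(91.2, 4.72), the northwest Atlantic neophyte-nester distribution.
#' @param tmax Maximum credible age in years (default 100, about three
#'   generations); older age-sliced estimates are discarded.
#' @param hatchling_length Hatchling size in cm SCL (default 4.5).
#' @param n Number of proposed draws (>= 1000).
#' @param seed Integer seed.
#' @return Object of class `alpha_samples`: list with `ages` (accepted draws,
#'   years), `n_proposed`, `n_rejected_size`, `n_rejected_age`,
#'   `n_rejected_below_hatchling`, `tmax`, `hatchling_length`, `seed`.
#' @export
slice_ages <- function(meta,
                       nesters = normal_spec(91.2, 4.72),
                       tmax = 100, hatchling_length = 4.5,
                       n = 1e6, seed = 1L) {
  stopifnot(inherits(meta, "growth_meta"), inherits(nesters, "normal_spec"))
  if (n < 1e3) stop("'n' must be at least 1000")
  if (tmax <= 0) stop("'tmax' must be positive")
  set.seed(seed)
  m <- nrow(meta$draws)
  idx <- if (m >= n) sample.int(m, n) else sample.int(m, n, replace = TRUE)
  L_inf <- meta$draws$L_inf_bar[idx]
  k <- exp(meta$draws$ln_k_bar[idx])
  L <- stats::rnorm(n, nesters$mean, nesters$sd)

  below <- L < hatchling_length
  too_big <- !below & L >= L_inf
  ok <- !below & !too_big
  t0 <- log((L_inf[ok] - hatchling_length) / L_inf[ok]) / k[ok]
  age <- log1p(-L[ok] / L_inf[ok]) / (-k[ok]) + t0
  nonfinite <- !is.finite(age)
  too_old <- is.finite(age) & age > tmax
  ages <- age[!nonfinite & !too_old]

  accept_rate <- length(ages) / n
  if (accept_rate < 0.01)
    stop(sprintf(
      "age-slicing acceptance rate %.4f < 1%%: nester-size and growth posteriors are inconsistent",
      accept_rate))
  structure(list(ages = ages,
                 n_proposed = n,
                 n_rejected_size = sum(too_big),
                 n_rejected_age = sum(too_old),
                 n_rejected_below_hatchling = sum(below),
                 n_nonfinite = sum(nonfinite),
                 tmax = tmax, hatchling_length = hatchling_length,
                 nesters = nesters, seed = seed),
            class = "alpha_samples")
}

#' @export
print.alpha_samples <- function(x, ...) {
  cat(sprintf(
    "Age-at-first-reproduction: %d accepted of %d proposed (%d over L_inf, %d over tmax = %g)\n",
    length(x$ages), x$n_proposed, x$n_rejected_size, x$n_rejected_age, x$tmax))
  print(summary_stats(x$ages))
  invisible(x)
}

#' @export
summary.alpha_samples <- function(object, mass = 0.95, ...) {
  summary_stats(object$ages, mass)
}

#' @export
plot.alpha_samples <- function(x, ...) {
  d <- stats::density(x$ages)
  plot(d, main = "Age-at-first-reproduction", xlab = "age (years)", ...)
  invisible(x)
}
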