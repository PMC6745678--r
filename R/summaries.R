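#' Highest density interval of a sample
#'
#' Shortest contiguous interval over the sorted sample containing
#' `ceiling(mass * n)` points (Chen & Shao estimator). Ties in window width
#' are broken by the lowest starting index. Appropriate for unimodal samples;
#' a multimodal density would call for a union of intervals, which this does
#' not attempt.
#'
#' @param samples Numeric vector, length >= 1 (length 1 returns a degenerate
#'   interval).
#' @param mass Probability mass to cover, in (0, 1). Default 0.95.
#' @return Named numeric vector `c(low = , high = )`.
#' @examples
#' hdi(rnorm(1e4), 0.95)
#' @export
hdi <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n == 0L) stop("empty sample")
  if (mass <= 0 || mass >= 1) stop("'mass' must be in (0, 1)")
  x <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(low = x[1L], high = x[n]))
  widths <- x[m:n] - x[seq_len(n - m + 1L)]
  i <- which.min(widths)   # which.min returns the first minimum: lowest start
  c(low = x[i], high = x[i + m - 1L])
}

#' Mode of a sample by kernel density estimation
#'
#' Argmax of a Gaussian kernel density estimate (Silverman's rule-of-thumb
#' bandwidth, 512-point grid). Matches how a mode is read off a smooth
#' posterior density curve.
#'
#' @param samples Numeric vector, length >= 10.
#' @param n_grid Grid resolution (default 512).
#' @return The estimated mode (scalar).
#' @export
kde_mode <- function(samples, n_grid = 512L) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 10L) stop("need at least 10 samples for a KDE mode")
  if (max(samples) == min(samples)) return(samples[1L])
  d <- stats::density(samples, bw = "nrd0", n = n_grid)
  d$x[which.max(d$y)]
}

#' Posterior-style summary of a sample
#'
#' Mean, median, KDE mode and highest-density interval, bundled with the
#' sample size and interval mass.
#'
#' @param samples Numeric vector.
#' @param mass HDI probability mass (default 0.95).
#' @return An object of class `summary_stats`: a list with elements `mean`,
#'   `median`, `mode`, `hdi_low`, `hdi_high`, `mass`, `n`.
#' @export
summary_stats <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 2L) stop("need at least 2 finite samples")
  ci <- hdi(samples, mass)
  structure(list(mean = mean(samples),
                 median = stats::median(samples),
                 mode = if (length(samples) >= 10L) kde_mode(samples) else NA_real_,
                 hdi_low = unname(ci["low"]),
                 hdi_high = unname(ci["high"]),
                 mass = mass,
                 n = length(samples)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, digits = 4, ...) {
  cat(sprintf(
    "mean %s  median %s  mode %s  %g%% HDI [%s, %s]  (n = %d)\n",
    signif(x$mean, digits), signif(x$median, digits),
    signif(x$mode, digits), 100 * x$mass,
    signif(x$hdi_low, digits), signif(x$hdi_high, digits), x$n))
  invisible(x)
}

#' @export
as.data.frame.summary_stats <- function(x, ...) {
  data.frame(mean = x$mean, median = x$median, mode = x$mode,
             hdi_low = x$hdi_low, hdi_high = x$hdi_high,
             mass = x$mass, n = x$n)
}

# Deterministic child-seed derivation: a pipeline run takes one master seed
# and hands each stochastic stage its own stream. Linear-congruential step of
# the Lehmer/Park-Miller generator keeps everything inside 32-bit integer
# range, so set.seed() accepts the result.
child_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  m <- 2147483647
  x <- (abs(as.numeric(master)) + 1) %% m
  for (i in seq_len(stage)) x <- (x * 48271) %% m
  as.integer(x)
}
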