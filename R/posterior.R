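#' Posterior for concentration given a single count
#'
#' Bayesian posterior for the true source concentration given one observed
#' count from a sample of known volume, assuming Poisson sampling error,
#' perfect or constant analytical recovery, and a relatively uninformative
#' semi-infinite uniform prior on concentration. The posterior is
#' Gamma(shape = count + 1, rate = recovery_p * volume); for a non-detect
#' (count 0) in 1 L it is Exponential(1).
#'
#' The flat prior on `[0, Inf)` is improper but yields a proper gamma
#' posterior for any count, so no truncation constant is needed.
#'
#' @param count Observed organism count (single non-negative integer).
#' @param volume Analytical sample volume in liters (positive scalar).
#' @param recovery_p Constant analytical recovery fraction in (0, 1];
#'   default 1 (perfect recovery). Beta-distributed recovery is not
#'   conjugate and is not supported here.
#'
#' @return An object of class `gamma_posterior` with fields `shape`, `rate`,
#'   `mean` (= shape/rate) and `mode` (= count / (recovery_p * volume)).
#'
#' @examples
#' posterior_from_count(0, 1)   # Exponential(1)
#' posterior_from_count(2, 1)   # Gamma(3, 1)
#' @export
posterior_from_count <- function(count, volume, recovery_p = 1) {
  if (!is.numeric(count) || length(count) != 1L || !is.finite(count) ||
      count < 0 || count != round(count)) {
    stop("`count` must be a single non-negative integer", call. = FALSE)
  }
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) ||
      volume <= 0) {
    stop("`volume` must be a single positive finite value", call. = FALSE)
  }
  if (!is.numeric(recovery_p) || length(recovery_p) != 1L ||
      !is.finite(recovery_p) || recovery_p <= 0 || recovery_p > 1) {
    stop("`recovery_p` must be a single value in (0, 1]", call. = FALSE)
  }
  shape <- count + 1
  rate <- recovery_p * volume
  structure(
    list(shape = shape, rate = rate,
         mean = shape / rate, mode = count / rate),
    class = "gamma_posterior"
  )
}

#' @export
print.gamma_posterior <- function(x, ...) {
  cat(sprintf(
    "Gamma posterior for concentration: shape %.6g, rate %.6g /L\n",
    x$shape, x$rate))
  cat(sprintf("  mean %.6g, mode %.6g organisms/L\n", x$mean, x$mode))
  ci <- credible_interval(x, 0.95)
  cat(sprintf("  95%% credible interval (%.6g, %.6g)\n", ci[1], ci[2]))
  invisible(x)
}

#' Posterior exceedance probability
#'
#' Probability that the true concentration exceeds a threshold (for example
#' a purported method detection limit of one organism per analysed volume),
#' under a [posterior_from_count()] posterior.
#'
#' @param posterior A `gamma_posterior`.
#' @param threshold Concentration threshold, organisms per liter
#'   (non-negative).
#' @return Upper-tail probability `P(c > threshold)`.
#'
#' @examples
#' # a non-detect in 1 L leaves a ~37% chance the concentration exceeds 1/L
#' prob_exceeds(posterior_from_count(0, 1), 1)
#' # a count of 2 in 1 L leaves a ~8% chance it is below 1/L
#' 1 - prob_exceeds(posterior_from_count(2, 1), 1)
#' @export
prob_exceeds <- function(posterior, threshold) {
  stopifnot(inherits(posterior, "gamma_posterior"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 0) {
    stop("`threshold` must be a single non-negative value", call. = FALSE)
  }
  stats::pgamma(threshold, shape = posterior$shape, rate = posterior$rate,
                lower.tail = FALSE)
}

#' Equal-tailed credible interval
#'
#' @param posterior A `gamma_posterior`.
#' @param level Interval probability in (0, 1), e.g. 0.95.
#' @return Numeric vector `c(low, high)` in organisms per liter.
#'
#' @examples
#' credible_interval(posterior_from_count(0, 1), 0.95)
#' @export
credible_interval <- function(posterior, level) {
  stopifnot(inherits(posterior, "gamma_posterior"))
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 1) {
    stop("`level` must be a single probability strictly inside (0, 1)",
         call. = FALSE)
  }
  tail <- (1 - level) / 2
  stats::qgamma(c(tail, 1 - tail), shape = posterior$shape,
                rate = posterior$rate)
}
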