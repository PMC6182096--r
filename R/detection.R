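#' Probability of a non-detect
#'
#' Probability of observing a count of zero organisms in a sample of volume
#' `volume` liters drawn from a source at `concentration` organisms per
#' liter, assuming Poisson random sampling error and the given analytical
#' recovery profile.
#'
#' With perfect recovery the non-detect probability is `exp(-c V)`; with
#' constant recovery `p` it is `exp(-c V p)`; with beta-distributed recovery
#' it is the beta expectation `E[exp(-c V R)]`, which equals the confluent
#' hypergeometric function 1F1(a; a + b; -c V).
#'
#' @param concentration Source concentration, organisms per liter
#'   (non-negative; vectorised).
#' @param volume Analytical sample volume in liters (positive scalar).
#' @param recovery A [recovery_model]; defaults to perfect recovery.
#'
#' @return Probability (or vector of probabilities) in (0, 1].
#'
#' @examples
#' prob_nondetect(1, volume = 1)                       # exp(-1)
#' prob_nondetect(10, 1, recovery_constant(0.4))       # exp(-4)
#' prob_nondetect(10, 1, recovery_beta(2, 3))          # 1F1(2; 5; -10)
#' @export
prob_nondetect <- function(concentration, volume, recovery = recovery_perfect()) {
  if (!is.numeric(concentration) || any(!is.finite(concentration)) ||
      any(concentration < 0)) {
    stop("`concentration` must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) ||
      volume <= 0) {
    stop("`volume` must be a single positive finite value", call. = FALSE)
  }
  recovery <- as_recovery(recovery)
  cv <- concentration * volume
  switch(recovery$variant,
    perfect  = exp(-cv),
    constant = exp(-cv * recovery$p),
    beta     = beta_zero_prob(cv, recovery$a, recovery$b)
  )
}

# E[exp(-t R)] for R ~ Beta(a, b): 1F1(a; a+b; -t), evaluated through the
# Kummer transformation 1F1(a; b; -t) = exp(-t) 1F1(b - a; b; t), whose
# series has all-positive terms for t >= 0 (no catastrophic cancellation).
beta_zero_prob <- function(t, a, b) {
  vapply(t, function(ti) {
    if (ti == 0) return(1)
    if (ti > 5e4) return(beta_zero_prob_quad(ti, a, b))
    exp(-ti + log_kummer_series(b, a + b, ti))
  }, numeric(1))
}

# log 1F1(a; b; x) for x >= 0, a, b > 0 by direct series in log space
# (all terms positive, so incremental log-sum-exp is exact); evaluating the
# log avoids overflow of the ~e^x growth before the e^{-x} prefactor.
log_kummer_series <- function(a, b, x) {
  stopifnot(x >= 0)
  log_term <- 0
  log_total <- 0
  lx <- log(x)
  for (k in 0:100000) {
    log_term <- log_term + log(a + k) + lx - log(b + k) - log(k + 1)
    m <- max(log_total, log_term)
    log_total <- m + log1p(exp(min(log_total, log_term) - m))
    if (log_term < log_total - 40) break
  }
  log_total
}

# Quadrature route for the beta expectation; used as a fallback and as an
# internal cross-check of the series evaluation.
beta_zero_prob_quad <- function(t, a, b) {
  vapply(t, function(ti) {
    stats::integrate(function(r) stats::dbeta(r, a, b) * exp(-ti * r),
                     0, 1, rel.tol = 1e-12)$value
  }, numeric(1))
}

#' Method sensitivity limit (MSL)
#'
#' The concentration beyond which a non-detect becomes improbable: the
#' unique concentration at which the non-detect probability equals `alpha`
#' for the given analytical volume and recovery profile. The MSL
#' characterises the sensitivity of an enumeration method, in contrast to
#' the "purported MDL" of one organism per analysed volume.
#'
#' Closed forms `log(1/alpha) / V` (perfect recovery) and
#' `log(1/alpha) / (p V)` (constant recovery) are used directly; the
#' beta-recovery case is solved by monotone root-finding on
#' [prob_nondetect()].
#'
#' @param volume Analytical sample volume in liters (positive scalar).
#' @param recovery A [recovery_model]; defaults to perfect recovery.
#' @param alpha Non-detect probability threshold in (0, 1); default 0.01,
#'   i.e. a non-detect is called "improbable" below 1% probability.
#'
#' @return Concentration in organisms per liter.
#'
#' @examples
#' msl(1)                          # 4.61 organisms/L
#' msl(1, recovery_constant(0.4))  # 11.5 organisms/L
#' msl(1, recovery_beta(2, 3))     # 32.5 organisms/L
#' msl(100)                        # scales as 1/volume
#' @export
msl <- function(volume, recovery = recovery_perfect(), alpha = 0.01) {
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) ||
      volume <= 0) {
    stop("`volume` must be a single positive finite value", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single probability strictly inside (0, 1)",
         call. = FALSE)
  }
  recovery <- as_recovery(recovery)
  if (recovery$variant == "perfect") return(log(1 / alpha) / volume)
  if (recovery$variant == "constant") {
    return(log(1 / alpha) / (recovery$p * volume))
  }
  # beta recovery: bracket [0, hi], doubling hi from the mean-recovery
  # guess until P(ND) falls below alpha (guaranteed by monotonicity)
  hi <- log(1 / alpha) / (volume * recovery_mean(recovery))
  while (prob_nondetect(hi, volume, recovery) > alpha) hi <- 2 * hi
  stats::uniroot(
    function(cc) prob_nondetect(cc, volume, recovery) - alpha,
    lower = 0, upper = hi, tol = 1e-12
  )$root
}

#' Most probable number (MPN) estimate from presence/absence tests
#'
#' Maximum likelihood estimate of concentration from a series of
#' presence/absence tests on aliquots of (possibly different) volumes. A
#' positive test is an inherently censored count of "at least one", entering
#' the likelihood through `1 - exp(-c V)`; a negative test is an exact zero
#' count contributing `exp(-c V)`.
#'
#' @param volume Numeric vector of aliquot volumes in liters.
#' @param positive Logical vector, same length: was growth/signal observed?
#'
#' @return A list of class `mpn_fit` with elements `estimate` (organisms per
#'   liter; `0` when all tests are negative, `Inf` when all are positive),
#'   `loglik`, and `identifiable` (`FALSE` for the all-positive series,
#'   where the likelihood increases without bound).
#'
#' @examples
#' mpn_estimate(rep(1, 10), c(rep(TRUE, 5), rep(FALSE, 5)))  # log(2)
#' mpn_estimate(rep(1, 5), rep(FALSE, 5))                    # boundary: 0
#' @export
mpn_estimate <- function(volume, positive) {
  if (length(volume) == 0L) stop("at least one test is required", call. = FALSE)
  if (length(volume) != length(positive)) {
    stop("`volume` and `positive` must have equal length", call. = FALSE)
  }
  if (!is.numeric(volume) || any(!is.finite(volume)) || any(volume <= 0)) {
    stop("all volumes must be positive and finite", call. = FALSE)
  }
  positive <- as.logical(positive)
  if (anyNA(positive)) stop("`positive` must be TRUE/FALSE", call. = FALSE)

  ll <- function(c) {
    sum(log1p(-exp(-c * volume[positive]))) - c * sum(volume[!positive])
  }
  if (!any(positive)) {
    out <- list(estimate = 0, loglik = 0, identifiable = TRUE)
  } else if (all(positive)) {
    # likelihood -> 1 as c -> Inf: no finite MLE
    out <- list(estimate = Inf, loglik = 0, identifiable = FALSE)
  } else {
    # score: sum_pos V e^{-cV}/(1 - e^{-cV}) - sum_neg V, strictly decreasing
    score <- function(c) {
      e <- exp(-c * volume[positive])
      sum(volume[positive] * e / (1 - e)) - sum(volume[!positive])
    }
    hi <- 1 / min(volume)
    while (score(hi) > 0) hi <- 2 * hi
    lo <- hi / 2
    while (score(lo) < 0) lo <- lo / 2
    est <- stats::uniroot(score, lower = lo, upper = hi, tol = 1e-12)$root
    out <- list(estimate = est, loglik = ll(est), identifiable = TRUE)
  }
  structure(out, class = "mpn_fit")
}

#' @export
print.mpn_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("MPN estimate: non-identifiable (all tests positive; MLE unbounded)\n")
  } else {
    cat(sprintf("MPN estimate: %.6g organisms/L (log-likelihood %.4f)\n",
                x$estimate, x$loglik))
  }
  invisible(x)
}
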