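#' Lognormal fit container
#'
#' @description
#' All five non-detect handling approaches return a `lognormal_fit`: the
#' log-scale parameters of the fitted lognormal concentration distribution
#' together with its arithmetic moments, the scale on which source water
#' statistics are customarily compared:
#' `arith_mean = exp(meanlog + sdlog^2/2)` and
#' `arith_sd = arith_mean * sqrt(exp(sdlog^2) - 1)`.
#'
#' @param meanlog,sdlog Log-scale parameters (`sdlog >= 0`).
#' @param loglik Maximised log-likelihood.
#' @param approach Label, one of `"A"`, `"B"`, `"C"`, `"D"`, `"E"` (or a
#'   free label for direct fits).
#' @param converged Did the optimiser report convergence?
#' @return A list of class `lognormal_fit`.
#' @export
lognormal_fit <- function(meanlog, sdlog, loglik = NA_real_,
                          approach = "direct", converged = TRUE) {
  stopifnot(is.finite(meanlog), is.finite(sdlog), sdlog >= 0)
  m <- lnorm_arith_moments(meanlog, sdlog)
  structure(
    list(meanlog = meanlog, sdlog = sdlog,
         arith_mean = m[["mean"]], arith_sd = m[["sd"]],
         loglik = loglik, approach = approach, converged = converged),
    class = "lognormal_fit"
  )
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("Lognormal fit (approach %s)%s\n", x$approach,
              if (x$converged) "" else "  [NOT converged]"))
  cat(sprintf("  meanlog %.4f  sdlog %.4f\n", x$meanlog, x$sdlog))
  cat(sprintf("  arithmetic mean %.4f  sd %.4f organisms/L\n",
              x$arith_mean, x$arith_sd))
  if (is.finite(x$loglik)) cat(sprintf("  log-likelihood %.4f\n", x$loglik))
  invisible(x)
}

#' Lognormal arithmetic moments and their inverse
#'
#' @param meanlog,sdlog Log-scale lognormal parameters.
#' @return `lnorm_arith_moments`: named vector `c(mean, sd)`.
#' @export
lnorm_arith_moments <- function(meanlog, sdlog) {
  m <- exp(meanlog + sdlog^2 / 2)
  c(mean = m, sd = m * sqrt(expm1(sdlog^2)))
}

#' @rdname lnorm_arith_moments
#' @param mean,sd Arithmetic mean (> 0) and standard deviation (>= 0).
#' @return `lnorm_params_from_moments`: named vector `c(meanlog, sdlog)`.
#' @export
lnorm_params_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  s2 <- log1p((sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Convert raw counts to legacy reported concentrations
#'
#' Emulates the reporting convention the legacy approaches operate on:
#' detects become concentration `count / volume`; zero counts become
#' non-detects recorded as "< 1 organism per analysed volume", i.e. a
#' per-sample reporting limit of `1 / volume` (so limits differ between
#' samples of different volume).
#'
#' @param observations A [count_data] table without TNTC rows.
#' @return A [reported_data] table, one row per observation.
#'
#' @examples
#' to_reported(count_data(count = c(1, 0), volume = c(64.4, 50.2)))
#' @export
to_reported <- function(observations) {
  stopifnot(inherits(observations, "count_data"))
  if (has_tntc(observations)) {
    stop("TNTC observations have no single reported concentration; ",
         "analyse them with approach_pln()", call. = FALSE)
  }
  nd <- observations$count == 0
  reported_data(
    sample_id = observations$sample_id,
    value = ifelse(nd, NA_real_, observations$count / observations$volume),
    nondetect = nd,
    limit = ifelse(nd, 1 / observations$volume, NA_real_)
  )
}

#' Uncensored lognormal maximum likelihood fit
#'
#' MLE of lognormal parameters from positive concentrations: `meanlog` is
#' the mean of the logs and `sdlog` the root mean squared deviation with
#' divisor `n` (the MLE, not the `n - 1` sample estimator).
#'
#' @param values Positive concentrations, organisms/L (length >= 2).
#' @param approach Label recorded on the fit.
#' @return A [lognormal_fit].
#' @export
fit_lognormal_mle <- function(values, approach = "direct") {
  if (length(values) < 2L) {
    stop("need at least 2 values to fit a lognormal", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all values must be positive and finite", call. = FALSE)
  }
  lx <- log(values)
  ml <- mean(lx)
  sl <- sqrt(mean((lx - ml)^2))
  ll <- sum(stats::dlnorm(values, ml, sl, log = TRUE))
  lognormal_fit(ml, sl, loglik = ll, approach = approach)
}

#' Approach A: omit non-detects
#'
#' Fits the lognormal MLE to detect concentrations only, discarding every
#' non-detect. The textbook worst practice: it conditions on detection and
#' biases the mean high.
#'
#' @param data A [reported_data] table with at least 2 detects.
#' @return A [lognormal_fit] labelled `"A"`.
#' @export
approach_omit <- function(data) {
  stopifnot(inherits(data, "reported_data"))
  detects <- data$value[!data$nondetect]
  if (length(detects) < 2L) {
    stop("approach A needs at least 2 detects", call. = FALSE)
  }
  fit_lognormal_mle(detects, approach = "A")
}

#' Approaches B and C: substitute the reporting limit
#'
#' Replaces each non-detect with `factor` times its per-sample reporting
#' limit (the purported MDL, `1/volume`) and fits the uncensored lognormal
#' MLE to all values. `factor = 1` is approach B (substitute the MDL),
#' `factor = 0.5` approach C (substitute half the MDL).
#'
#' @param data A [reported_data] table.
#' @param factor Substitution multiplier, conventionally 1 or 0.5.
#' @return A [lognormal_fit] labelled `"B"`, `"C"`, or `"subst"`.
#' @export
approach_substitute <- function(data, factor = 1) {
  stopifnot(inherits(data, "reported_data"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop("`factor` must be a single positive value", call. = FALSE)
  }
  values <- ifelse(data$nondetect, factor * data$limit, data$value)
  label <- if (factor == 1) "B" else if (factor == 0.5) "C" else "subst"
  fit_lognormal_mle(values, approach = label)
}

#' Approach D: left-censored lognormal MLE
#'
#' Treats non-detects as left-censored below their per-sample reporting
#' limit: detects contribute the lognormal density, non-detects the
#' cumulative density between zero and the limit. The likelihood is
#' maximised numerically over `(meanlog, log sdlog)` with multiple starts
#' (moment-based, half-limit substitution, and a perturbed start).
#'
#' @param data A [reported_data] table with at least one detect.
#' @return A [lognormal_fit] labelled `"D"`; `converged` is `FALSE` if no
#'   start converged (parameters from the best start are still returned).
#' @export
approach_censored_mle <- function(data) {
  stopifnot(inherits(data, "reported_data"))
  detects <- data$value[!data$nondetect]
  limits <- data$limit[data$nondetect]
  if (length(detects) < 1L) {
    stop("approach D needs at least 1 detect", call. = FALSE)
  }
  negll <- function(par) {
    m <- par[1]; s <- exp(par[2])
    -(sum(stats::dlnorm(detects, m, s, log = TRUE)) +
        sum(stats::plnorm(limits, m, s, log.p = TRUE)))
  }
  sub <- approach_substitute(data, 0.5)
  starts <- list(
    c(sub$meanlog, log(max(sub$sdlog, 1e-3))),
    c(mean(log(detects)), log(max(stats::sd(c(log(detects), log(limits))), 0.3))),
    c(sub$meanlog - 0.5, log(max(sub$sdlog, 1e-3)) + 0.5)
  )
  best <- optimise_multistart(negll, starts)
  lognormal_fit(best$par[1], exp(best$par[2]), loglik = -best$value,
                approach = "D", converged = best$converged)
}

# Nelder-Mead over each start; keep the best objective value.
optimise_multistart <- function(negll, starts) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, negll, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best$converged <- fit$convergence == 0
    }
  }
  if (is.null(best)) stop("likelihood optimisation failed from all starts",
                          call. = FALSE)
  best
}

#' Poisson-lognormal marginal log-likelihood
#'
#' Log-likelihood of raw count observations under the hierarchical model
#' `c_i ~ Lognormal(meanlog, sdlog)`, `x_i ~ Poisson(c_i * volume_i)`. Each
#' observation contributes the marginal probability
#' `integral Poisson(x_i; c v_i) dLognormal(c) dc`; TNTC rows contribute the
#' survival term `P(X >= threshold)` inside the integral. The integral is
#' evaluated by Gauss-Hermite quadrature in log-concentration (default 61
#' nodes); `method = "integrate"` uses adaptive quadrature instead and
#' serves as a cross-check.
#'
#' @param meanlog,sdlog Lognormal parameters of the concentration
#'   distribution (`sdlog >= 0`).
#' @param observations A [count_data] table.
#' @param method `"ghq"` (Gauss-Hermite) or `"integrate"` (adaptive).
#' @param nodes Number of Gauss-Hermite nodes.
#' @return The log-likelihood (a single number).
#' @export
pln_loglik <- function(meanlog, sdlog, observations,
                       method = c("ghq", "integrate"), nodes = 61) {
  stopifnot(inherits(observations, "count_data"), sdlog >= 0)
  method <- match.arg(method)
  is_tntc <- !is.na(observations$tntc_threshold)
  term <- function(conc, i) {
    lam <- conc * observations$volume[i]
    if (is_tntc[i]) {
      stats::ppois(observations$tntc_threshold[i] - 1, lam,
                   lower.tail = FALSE)
    } else {
      stats::dpois(observations$count[i], lam)
    }
  }
  if (sdlog == 0) {
    # degenerate lognormal: all mass at exp(meanlog)
    return(sum(vapply(seq_len(nrow(observations)),
                      function(i) log(term(exp(meanlog), i)), numeric(1))))
  }
  if (method == "ghq") {
    gh <- gauss_hermite_cached(nodes)
    conc <- exp(meanlog + sqrt(2) * sdlog * gh$x)
    w <- gh$w / sqrt(pi)
    ll <- vapply(seq_len(nrow(observations)),
                 function(i) log(sum(w * term(conc, i))), numeric(1))
  } else {
    ll <- vapply(seq_len(nrow(observations)), function(i) {
      v <- stats::integrate(
        function(z) term(exp(meanlog + sdlog * z), i) * stats::dnorm(z),
        -Inf, Inf, rel.tol = 1e-10
      )$value
      log(v)
    }, numeric(1))
  }
  sum(ll)
}

ghq_cache <- new.env(parent = emptyenv())
gauss_hermite_cached <- function(n) {
  key <- as.character(n)
  if (is.null(ghq_cache[[key]])) {
    ghq_cache[[key]] <- pracma::gaussHermite(n)
  }
  ghq_cache[[key]]
}

#' Approach E: Poisson-lognormal MLE on raw counts
#'
#' Fits the hierarchical Poisson-lognormal model to raw (count, volume)
#' records: concentrations vary between sampling events following a
#' lognormal distribution, and each observed count is Poisson with mean
#' `concentration * volume`. Zero counts are legitimate observations with
#' positive probability under the model — no censoring construct is needed.
#' This is the only approach that uses the raw data and accounts for random
#' sampling error.
#'
#' The marginal likelihood is evaluated by Gauss-Hermite quadrature
#' ([pln_loglik()]) and maximised over `(meanlog, log sdlog)` from multiple
#' starts.
#'
#' @param observations A [count_data] table with >= 2 rows and at least one
#'   positive (or TNTC) count; an all-zero dataset has no finite MLE and is
#'   rejected.
#' @param nodes Gauss-Hermite node count passed to [pln_loglik()].
#' @return A [lognormal_fit] labelled `"E"`.
#' @export
approach_pln <- function(observations, nodes = 61) {
  stopifnot(inherits(observations, "count_data"))
  if (nrow(observations) < 2L) {
    stop("approach E needs at least 2 observations", call. = FALSE)
  }
  is_tntc <- !is.na(observations$tntc_threshold)
  if (all(observations$count[!is_tntc] == 0) && !any(is_tntc)) {
    stop("all counts are zero: the Poisson-lognormal MLE is not ",
         "identifiable without an informative prior", call. = FALSE)
  }
  negll <- function(par) -pln_loglik(par[1], exp(par[2]), observations,
                                     method = "ghq", nodes = nodes)
  pooled <- sum(observations$count[!is_tntc]) /
    sum(observations$volume[!is_tntc])
  start_mu <- log(max(pooled, 1e-8))
  starts <- list(
    c(start_mu, log(0.8)),
    c(start_mu - 0.3, log(0.3)),
    c(start_mu + 0.5, log(1.5))
  )
  best <- optimise_multistart(negll, starts)
  lognormal_fit(best$par[1], exp(best$par[2]), loglik = -best$value,
                approach = "E", converged = best$converged)
}

#' Naive pooled mean concentration
#'
#' Total organisms counted divided by total volume analysed. Weighing zero
#' counts with the non-zero counts by their analytical volumes is the
#' correct simple point estimate of the mean concentration — no special
#' treatment of non-detects is needed.
#'
#' @param observations A [count_data] table without TNTC rows.
#' @return Mean concentration, organisms per liter.
#' @export
naive_pooled_mean <- function(observations) {
  stopifnot(inherits(observations, "count_data"))
  if (has_tntc(observations)) {
    stop("pooled mean is undefined with TNTC rows", call. = FALSE)
  }
  sum(observations$count) / sum(observations$volume)
}

#' Fit all five non-detect handling approaches
#'
#' Runs approaches A (omit), B (substitute MDL), C (substitute half MDL),
#' D (left-censored lognormal MLE) on the reported-concentration view of
#' the data and E (Poisson-lognormal MLE) on the raw counts.
#'
#' @param observations A [count_data] table without TNTC rows.
#' @return A named list of [lognormal_fit]s (`A` to `E`).
#'
#' @examples
#' fits <- fit_all_approaches(load_fixture())
#' sapply(fits, function(f) f$arith_mean)
#' @export
fit_all_approaches <- function(observations) {
  reported <- to_reported(observations)
  list(
    A = approach_omit(reported),
    B = approach_substitute(reported, 1),
    C = approach_substitute(reported, 0.5),
    D = approach_censored_mle(reported),
    E = approach_pln(observations)
  )
}

#' Bias ratios of legacy approaches relative to the Poisson-lognormal fit
#'
#' Ratio of each legacy approach's arithmetic-mean estimate to the
#' Poisson-lognormal (approach E) arithmetic mean — the factor by which
#' inappropriate non-detect handling inflates the estimated mean.
#'
#' @param fits A named list of [lognormal_fit]s containing `E` and at least
#'   one of `A`-`D` (as returned by [fit_all_approaches()]).
#' @return A list with `ratios` (named vector, one per legacy approach),
#'   `min` and `max`.
#' @export
bias_ratio <- function(fits) {
  if (is.null(fits$E)) stop("`fits` must contain approach E", call. = FALSE)
  if (!all(vapply(fits, function(f) isTRUE(f$converged), logical(1)))) {
    stop("all fits must have converged", call. = FALSE)
  }
  if (fits$E$arith_mean <= 0) {
    stop("approach E mean is zero: ratios undefined", call. = FALSE)
  }
  legacy <- fits[setdiff(names(fits), "E")]
  if (length(legacy) == 0L) stop("no legacy fits supplied", call. = FALSE)
  ratios <- vapply(legacy, function(f) f$arith_mean / fits$E$arith_mean,
                   numeric(1))
  list(ratios = ratios, min = min(ratios), max = max(ratios))
}
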