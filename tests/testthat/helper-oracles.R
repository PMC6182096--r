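# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: quadrature instead of series, grid search instead
# of gradient-based optimisation, Monte Carlo instead of closed forms.

# Beta-mixed zero probability by adaptive quadrature of the beta density.
oracle_beta_pnd <- function(cv, a, b) {
  integrate(function(r) dbeta(r, a, b) * exp(-cv * r), 0, 1,
            rel.tol = 1e-12)$value
}

# MPN log-likelihood argmax by dense grid search.
oracle_mpn_grid <- function(volume, positive, c_max, n_grid = 20000) {
  grid <- seq(0, c_max, length.out = n_grid)
  ll <- vapply(grid, function(c) {
    sum(log(1 - exp(-c * volume[positive]))) - c * sum(volume[!positive])
  }, numeric(1))
  grid[which.max(ll)]
}

# Censored lognormal log-likelihood (detect densities + ND CDF terms).
oracle_censored_ll <- function(meanlog, sdlog, detects, limits) {
  sum(dlnorm(detects, meanlog, sdlog, log = TRUE)) +
    sum(plnorm(limits, meanlog, sdlog, log.p = TRUE))
}

# Giardia source-water records used as the worked dataset throughout.
giardia_counts <- c(1, 0, 0, 0, 0, 0, 0, 2)
giardia_volumes <- c(64.4, 50.2, 50.0, 53.2, 50.2, 50.4, 50.4, 50.7)
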