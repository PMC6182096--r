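table1 <- function() count_data(count = giardia_counts, volume = giardia_volumes)

test_that("raw counts convert to the legacy reporting convention and back", {
  rep <- to_reported(table1())
  expect_equal(rep$value[1], 1 / 64.4)
  expect_true(rep$nondetect[2])
  expect_equal(rep$limit[2], 1 / 50.2)
  expect_equal(rep$value[8], 2 / 50.7)
  # the per-100-L display view matches how the records were reported
  expect_equal(signif(rep$value[c(1, 8)] * 100, 2), c(1.6, 3.9))
  expect_equal(signif(rep$limit[2:7] * 100, 2), c(2.0, 2.0, 1.9, 2.0, 2.0, 2.0))
  # detect round trip preserves the count exactly
  det <- !rep$nondetect
  expect_equal(rep$value[det] * giardia_volumes[det], giardia_counts[det],
               ignore_attr = TRUE, tolerance = 1e-15)

  tntc <- count_data(count = c(5, NA), volume = c(1, 1),
                     tntc_threshold = c(NA, 200))
  expect_error(to_reported(tntc), "TNTC")
})

test_that("uncensored lognormal MLE uses the n-divisor and matches an optimiser", {
  set.seed(5)
  x <- rlnorm(10, -2, 0.7)
  fit <- fit_lognormal_mle(x)
  opt <- optim(c(0, 0), function(p) -sum(dlnorm(x, p[1], exp(p[2]), log = TRUE)),
               control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(fit$meanlog, opt$par[1], tolerance = 1e-5)
  expect_equal(fit$sdlog, exp(opt$par[2]), tolerance = 1e-5)
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-8)

  deg <- fit_lognormal_mle(c(0.4, 0.4))
  expect_equal(deg$meanlog, log(0.4))
  expect_equal(deg$sdlog, 0)
  expect_equal(deg$arith_sd, 0)
  expect_error(fit_lognormal_mle(0.4), "at least 2")
  expect_error(fit_lognormal_mle(c(1, -1)), "positive")
})

test_that("arithmetic-moment conversion round-trips", {
  set.seed(9)
  for (i in 1:50) {
    ml <- runif(1, -8, 2); sl <- runif(1, 0, 2)
    m <- lnorm_arith_moments(ml, sl)
    back <- lnorm_params_from_moments(m[["mean"]], m[["sd"]])
    expect_equal(back[["meanlog"]], ml, tolerance = 1e-12)
    expect_equal(back[["sdlog"]], sl, tolerance = 1e-12)
  }
})

test_that("all legacy approaches coincide when the data contain no non-detects", {
  obs <- count_data(count = c(3, 1, 7, 2), volume = c(10, 12, 9, 11))
  rep <- to_reported(obs)
  fits <- list(approach_omit(rep), approach_substitute(rep, 1),
               approach_substitute(rep, 0.5), approach_censored_mle(rep))
  direct <- fit_lognormal_mle(rep$value)
  for (f in fits) {
    expect_equal(f$meanlog, direct$meanlog, tolerance = 1e-6)
    expect_equal(f$sdlog, direct$sdlog, tolerance = 1e-6)
  }
})

test_that("substituting the full limit shifts the fitted log-mean upward", {
  # the provable ordering is on meanlog (every substituted value doubles);
  # the arithmetic mean need not be ordered because halving the limits can
  # also shrink sdlog, and exp(meanlog + sdlog^2/2) trades the two off
  set.seed(21)
  for (i in 1:20) {
    sim <- simulate_counts(12, runif(1, -5, -3), runif(1, 0.3, 1.2),
                           volume = runif(12, 20, 80), seed = 100 + i)
    rep <- to_reported(sim$observations)
    if (!any(rep$nondetect) || sum(!rep$nondetect) < 2) next
    k <- sum(rep$nondetect)
    expect_equal(approach_substitute(rep, 1)$meanlog,
                 approach_substitute(rep, 0.5)$meanlog + k * log(2) / 12,
                 tolerance = 1e-10)
  }
  # on the worked dataset the arithmetic means are ordered as published
  rep1 <- to_reported(table1())
  expect_gt(approach_substitute(rep1, 1)$arith_mean,
            approach_substitute(rep1, 0.5)$arith_mean)
})

test_that("censored lognormal MLE matches a dense grid search", {
  rep <- reported_data(
    value = c(0.05, 0.12, NA, NA, 0.30),
    nondetect = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    limit = c(NA, NA, 0.04, 0.06, NA)
  )
  fit <- approach_censored_mle(rep)
  expect_true(fit$converged)
  mls <- seq(fit$meanlog - 0.5, fit$meanlog + 0.5, length.out = 201)
  sls <- seq(max(fit$sdlog - 0.5, 0.01), fit$sdlog + 0.5, length.out = 201)
  ll <- outer(mls, sls, Vectorize(function(m, s) {
    oracle_censored_ll(m, s, c(0.05, 0.12, 0.30), c(0.04, 0.06))
  }))
  top <- which(ll == max(ll), arr.ind = TRUE)
  expect_equal(fit$meanlog, mls[top[1]], tolerance = 0.01)
  expect_equal(fit$sdlog, sls[top[2]], tolerance = 0.01)
  expect_gte(fit$loglik, max(ll) - 1e-6)
})

test_that("censored lognormal MLE agrees with fitdistrplus on the worked dataset", {
  skip_if_not_installed("fitdistrplus")
  rep <- to_reported(table1())
  cens <- data.frame(
    left = ifelse(rep$nondetect, NA, rep$value),
    right = ifelse(rep$nondetect, rep$limit, rep$value)
  )
  ref <- fitdistrplus::fitdistcens(cens, "lnorm")
  fit <- approach_censored_mle(rep)
  expect_equal(fit$meanlog, unname(ref$estimate["meanlog"]), tolerance = 1e-3)
  expect_equal(fit$sdlog, unname(ref$estimate["sdlog"]), tolerance = 1e-3)
})

test_that("Poisson-lognormal likelihood: Gauss-Hermite agrees with adaptive quadrature", {
  obs <- table1()
  for (par in list(c(-5.3, 0.83), c(-4, 0.4), c(-6, 1.5))) {
    ll_gh <- pln_loglik(par[1], par[2], obs, method = "ghq")
    ll_ad <- pln_loglik(par[1], par[2], obs, method = "integrate")
    expect_equal(ll_gh, ll_ad, tolerance = 1e-6)
  }
  # counts up to 10 over the worked volume range
  obs2 <- count_data(count = c(0, 3, 10, 1), volume = c(50, 64.4, 55, 60))
  expect_equal(pln_loglik(-4.8, 0.9, obs2, method = "ghq"),
               pln_loglik(-4.8, 0.9, obs2, method = "integrate"),
               tolerance = 1e-6)
})

test_that("degenerate sdlog reduces the marginal likelihood to plain Poisson", {
  obs <- count_data(count = c(0, 2, 1), volume = c(10, 10, 10))
  expect_equal(pln_loglik(log(0.05), 0, obs),
               sum(dpois(c(0, 2, 1), 0.05 * 10, log = TRUE)))
})

test_that("Poisson-lognormal MLE is a local optimum and near the pooled mean on tight data", {
  obs <- table1()
  fit <- approach_pln(obs)
  expect_true(fit$converged)
  set.seed(31)
  for (i in 1:100) {
    m <- fit$meanlog + runif(1, -0.1, 0.1)
    s <- max(fit$sdlog + runif(1, -0.1, 0.1), 1e-4)
    expect_gte(fit$loglik, pln_loglik(m, s, obs) - 1e-7)
  }

  # near-homogeneous concentrations: the fitted mean approaches the Poisson
  # MLE total count / total volume
  sim <- simulate_counts(40, log(0.2), 0.05, volume = 25, seed = 4)
  fit2 <- approach_pln(sim$observations)
  pooled <- naive_pooled_mean(sim$observations)
  expect_equal(fit2$arith_mean, pooled, tolerance = 0.05)
})

test_that("TNTC rows enter the Poisson-lognormal likelihood as survival terms", {
  obs <- count_data(count = c(2, NA, 0), volume = c(1, 1, 1),
                    tntc_threshold = c(NA, 5, NA))
  ll <- pln_loglik(0.5, 0.4, obs, method = "ghq")
  manual <- local({
    f <- function(c, term) term(c) * dlnorm(c, 0.5, 0.4)
    t1 <- integrate(function(c) dpois(2, c) * dlnorm(c, 0.5, 0.4), 0, Inf,
                    rel.tol = 1e-10)$value
    t2 <- integrate(function(c) ppois(4, c, lower.tail = FALSE) *
                      dlnorm(c, 0.5, 0.4), 0, Inf, rel.tol = 1e-10)$value
    t3 <- integrate(function(c) dpois(0, c) * dlnorm(c, 0.5, 0.4), 0, Inf,
                    rel.tol = 1e-10)$value
    log(t1) + log(t2) + log(t3)
  })
  expect_equal(ll, manual, tolerance = 1e-6)
})

test_that("all-zero count data are rejected as non-identifiable", {
  obs <- count_data(count = c(0, 0, 0), volume = c(50, 50, 50))
  expect_error(approach_pln(obs), "not.*identifiable|identifiable")
})

test_that("the pooled mean weighs zero counts by their volumes", {
  expect_equal(naive_pooled_mean(table1()), 3 / 419.5)
  expect_equal(naive_pooled_mean(count_data(count = 0, volume = 5)), 0)
  expect_equal(naive_pooled_mean(count_data(count = 4, volume = 8)), 0.5)
})

test_that("bias ratios compare legacy means to the Poisson-lognormal mean", {
  f <- lognormal_fit(-5, 0.8, approach = "E")
  same <- list(A = lognormal_fit(-5, 0.8, approach = "A"), E = f)
  expect_equal(bias_ratio(same)$ratios[["A"]], 1)

  double <- list(A = lognormal_fit(-5 + log(2), 0.8, approach = "A"), E = f)
  expect_equal(bias_ratio(double)$max, 2, tolerance = 1e-12)

  bad <- list(A = lognormal_fit(-5, 0.8, converged = FALSE), E = f)
  expect_error(bias_ratio(bad), "converged")
  expect_error(bias_ratio(list(A = f)), "approach E")
})
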