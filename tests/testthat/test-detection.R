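test_that("non-detect probability matches closed forms", {
  expect_equal(prob_nondetect(0, 1), 1)
  expect_equal(prob_nondetect(log(100), 1), 0.01)
  expect_equal(prob_nondetect(2, 3), exp(-6))
  # constant recovery is a pure rescaling of concentration
  expect_equal(prob_nondetect(10, 1, recovery_constant(0.4)),
               prob_nondetect(4, 1))
})

test_that("beta-recovery probability agrees with quadrature of the beta mixture", {
  # hypergeometric series vs adaptive quadrature across the working range
  for (cv in c(0.01, 0.5, 1, 5, 10, 32.5, 50, 100, 200)) {
    expect_equal(prob_nondetect(cv, 1, recovery_beta(2, 3)),
                 oracle_beta_pnd(cv, 2, 3), tolerance = 1e-8)
    expect_equal(prob_nondetect(cv, 1, recovery_beta(0.5, 1.7)),
                 oracle_beta_pnd(cv, 0.5, 1.7), tolerance = 1e-8)
  }
})

test_that("non-detect probability decreases in concentration and volume", {
  set.seed(41)
  for (i in 1:50) {
    # ranges keep c*V small enough that the probability stays above the
    # double-precision underflow floor, so strict ordering is observable
    c1 <- runif(1, 0.01, 5); c2 <- c1 * runif(1, 1.01, 3)
    v1 <- runif(1, 0.1, 10); v2 <- v1 * runif(1, 1.01, 3)
    rec <- switch(sample(3, 1), recovery_perfect(),
                  recovery_constant(runif(1, 0.05, 1)),
                  recovery_beta(runif(1, 0.3, 5), runif(1, 0.3, 5)))
    expect_lt(prob_nondetect(c2, v1, rec), prob_nondetect(c1, v1, rec))
    expect_lt(prob_nondetect(c1, v2, rec), prob_nondetect(c1, v1, rec))
  }
})

test_that("variable recovery inflates the non-detect probability (Jensen)", {
  set.seed(42)
  for (i in 1:100) {
    a <- runif(1, 0.2, 6); b <- runif(1, 0.2, 6)
    cc <- runif(1, 0.01, 30); v <- runif(1, 0.1, 10)
    expect_gte(prob_nondetect(cc, v, recovery_beta(a, b)),
               prob_nondetect(cc, v, recovery_constant(a / (a + b))))
  }
})

test_that("inputs outside the domain are rejected", {
  expect_error(prob_nondetect(-1, 1), "non-negative")
  expect_error(prob_nondetect(1, 0), "positive")
  expect_error(prob_nondetect(Inf, 1), "finite")
  expect_error(recovery_beta(-2, 3), "positive")
  expect_error(recovery_constant(1.2), "\\(0, 1\\]")
  expect_error(msl(1, alpha = 0), "\\(0, 1\\)")
  expect_error(msl(1, alpha = 1), "\\(0, 1\\)")
})

test_that("method sensitivity limit honours closed forms and scales as 1/volume", {
  expect_equal(msl(1), log(100))
  expect_equal(msl(1, recovery_constant(0.4)), log(100) / 0.4)
  expect_equal(msl(100), log(100) / 100)
  expect_equal(msl(2.5, recovery_beta(2, 3)) * 2.5, msl(1, recovery_beta(2, 3)),
               tolerance = 1e-9)
  # non-default alpha
  expect_equal(msl(1, alpha = 0.05), log(20))
})

test_that("non-detect probability at the MSL equals alpha for every recovery profile", {
  for (rec in list(recovery_perfect(), recovery_constant(0.4),
                   recovery_beta(2, 3), recovery_beta(0.8, 4))) {
    for (alpha in c(0.01, 0.1)) {
      cstar <- msl(1.0, rec, alpha)
      expect_equal(prob_nondetect(cstar, 1.0, rec), alpha, tolerance = 1e-6)
    }
  }
})

test_that("MPN estimation covers boundary, closed-form and error cases", {
  all_neg <- mpn_estimate(rep(1, 5), rep(FALSE, 5))
  expect_equal(all_neg$estimate, 0)
  expect_true(all_neg$identifiable)

  all_pos <- mpn_estimate(rep(1, 4), rep(TRUE, 4))
  expect_false(all_pos$identifiable)
  expect_identical(all_pos$estimate, Inf)

  # equal volumes: MLE = -log(negatives/total)/V
  half <- mpn_estimate(rep(1, 10), rep(c(TRUE, FALSE), each = 5))
  expect_equal(half$estimate, log(2), tolerance = 1e-9)
  third <- mpn_estimate(rep(0.5, 9), rep(c(TRUE, FALSE, FALSE), 3))
  expect_equal(third$estimate, -log(2 / 3) / 0.5, tolerance = 1e-9)

  expect_error(mpn_estimate(numeric(0), logical(0)), "at least one")
  expect_error(mpn_estimate(c(1, -1), c(TRUE, FALSE)), "positive")
})

test_that("MPN MLE equals the grid-search argmax on random mixed-volume series", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    vols <- sample(c(0.1, 1, 10), n, replace = TRUE)
    pos <- runif(n) < 0.5
    if (all(pos) || !any(pos)) next
    fit <- mpn_estimate(vols, pos)
    c_max <- 4 * fit$estimate + 1
    grid_est <- oracle_mpn_grid(vols, pos, c_max)
    expect_lt(abs(fit$estimate - grid_est), 2 * c_max / 20000)
  }
})
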