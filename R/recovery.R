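#' Analytical recovery models
#'
#' Analytical recovery is the fraction of organisms in the processed sample
#' that the enumeration method actually observes. Three profiles are
#' supported: perfect recovery (every organism captured is observed),
#' constant recovery (each organism observed independently with fixed
#' probability `p`), and beta-distributed recovery (the per-sample recovery
#' fraction varies between samples following a Beta(a, b) distribution).
#'
#' Under Poisson sampling of a source at concentration `c` with analytical
#' volume `V`, the expected count is `c * V * R` where `R` is the recovery
#' realised for that sample.
#'
#' @param p Recovery fraction in (0, 1] for the constant model.
#' @param a,b Positive shape parameters of the beta model; the mean recovery
#'   is `a / (a + b)`.
#'
#' @return An object of class `recovery_model`.
#'
#' @examples
#' recovery_perfect()
#' recovery_constant(0.4)
#' recovery_beta(2, 3)  # mean recovery 0.4, substantial between-sample spread
#'
#' @name recovery_model
NULL

#' @rdname recovery_model
#' @export
recovery_perfect <- function() {
  structure(list(variant = "perfect"), class = "recovery_model")
}

#' @rdname recovery_model
#' @export
recovery_constant <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 1) {
    stop("constant recovery fraction `p` must be a single value in (0, 1]",
         call. = FALSE)
  }
  structure(list(variant = "constant", p = p), class = "recovery_model")
}

#' @rdname recovery_model
#' @export
recovery_beta <- function(a, b) {
  ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  if (!ok(a) || !ok(b)) {
    stop("beta recovery shapes `a` and `b` must be single positive values",
         call. = FALSE)
  }
  structure(list(variant = "beta", a = a, b = b), class = "recovery_model")
}

#' @export
print.recovery_model <- function(x, ...) {
  switch(x$variant,
    perfect  = cat("Analytical recovery: perfect (100%)\n"),
    constant = cat(sprintf("Analytical recovery: constant at %.4g\n", x$p)),
    beta     = cat(sprintf(
      "Analytical recovery: Beta(%.4g, %.4g), mean %.4g\n",
      x$a, x$b, x$a / (x$a + x$b)))
  )
  invisible(x)
}

#' Mean of a recovery model
#'
#' @param recovery A [recovery_model] object.
#' @return The expected recovery fraction.
#' @export
recovery_mean <- function(recovery) {
  stopifnot(inherits(recovery, "recovery_model"))
  switch(recovery$variant,
    perfect  = 1,
    constant = recovery$p,
    beta     = recovery$a / (recovery$a + recovery$b)
  )
}

#' Draw per-sample recovery fractions
#'
#' @param n Number of draws.
#' @param recovery A [recovery_model] object.
#' @return Numeric vector of length `n` of recovery fractions.
#' @export
recovery_draw <- function(n, recovery) {
  stopifnot(inherits(recovery, "recovery_model"))
  switch(recovery$variant,
    perfect  = rep(1, n),
    constant = rep(recovery$p, n),
    beta     = stats::rbeta(n, recovery$a, recovery$b)
  )
}

as_recovery <- function(recovery) {
  if (inherits(recovery, "recovery_model")) return(recovery)
  stop("`recovery` must be a recovery_model (see recovery_perfect(), ",
       "recovery_constant(), recovery_beta())", call. = FALSE)
}
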