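#!/usr/bin/env Rscript
# Non-detect probability curves and method sensitivity limits.
#
# A zero count is an ordinary Poisson outcome, not a censored measurement:
# even at concentrations well above the "purported MDL" of 1 organism per
# analysed volume, a non-detect has appreciable probability. This script
# tabulates P(non-detect) as a function of concentration for a 1.0-L sample
# under three analytical recovery profiles sharing (where applicable) a 40%
# mean recovery, and computes the concentration at which a non-detect
# becomes improbable (<1%) — the method sensitivity limit (MSL).

library(ndcount)
dir.create("results", showWarnings = FALSE)

profiles <- list(
  perfect        = recovery_perfect(),
  constant_0.4   = recovery_constant(0.4),
  beta_2_3       = recovery_beta(2, 3)
)

conc <- seq(0, 40, by = 0.1)
curves <- do.call(rbind, lapply(names(profiles), function(nm) {
  data.frame(recovery = nm, concentration = conc,
             p_nondetect = prob_nondetect(conc, volume = 1, profiles[[nm]]))
}))
write.csv(curves, "results/nd_probability_curves.csv", row.names = FALSE)

msl_tab <- data.frame(
  recovery = names(profiles),
  volume_L = 1.0,
  alpha = 0.01,
  msl_per_L = vapply(profiles, function(r) msl(1.0, r, 0.01), numeric(1))
)
write.csv(msl_tab, "results/msl_table.csv", row.names = FALSE)

cat("Method sensitivity limits (1.0-L sample, alpha = 1%):\n")
print(transform(msl_tab, msl_per_L = signif(msl_per_L, 3)), row.names = FALSE)
cat("\nVariable (beta) recovery at the same 40% mean raises the MSL from",
    signif(msl_tab$msl_per_L[2], 3), "to", signif(msl_tab$msl_per_L[3], 3),
    "organisms/L:\nvariability in recovery, not just its mean, degrades",
    "method sensitivity.\n")
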