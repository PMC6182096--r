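#!/usr/bin/env Rscript
# Directional check of non-detect handling bias under simulation.
#
# Generates datasets with the structure the estimators assume (lognormal
# concentrations across events, Poisson counts given concentration x
# volume) at three non-detect loads, and compares the mean concentration
# estimate from each approach across replicates. No numeric targets are
# claimed here: the point is the direction and growth of the bias with the
# non-detect fraction.

library(ndcount)
dir.create("results", showWarnings = FALSE)

# n = 24 mimics two years of monthly monitoring; concentration scenarios
# span low (mostly non-detects, like the worked Giardia data) to high
# (few non-detects)
scenarios <- data.frame(
  n = 24,
  meanlog = c(-5.3, -4.3, -3.3),
  sdlog = 0.83,
  volume = 50
)

out <- bias_experiment(scenarios, n_replicates = 25, seed = 42)
out$true_mean <- exp(scenarios$meanlog[out$scenario] +
                       scenarios$sdlog[out$scenario]^2 / 2)
out$rel_bias <- out$mean_estimate / out$true_mean - 1
write.csv(out, "results/bias_experiment.csv", row.names = FALSE)

print(transform(out, mean_estimate = signif(mean_estimate, 3),
                sd_estimate = signif(sd_estimate, 3),
                nd_fraction = round(nd_fraction, 2),
                true_mean = signif(true_mean, 3),
                rel_bias = round(rel_bias, 2)),
      row.names = FALSE)

hi_nd <- subset(out, scenario == 1)
cat(sprintf(
  "\nAt ~%.0f%% non-detects, omission (A) overshoots the true mean by %.0f%%
while the Poisson-lognormal fit (E) is off by %.0f%%; as the non-detect
fraction falls (scenarios 2-3) the approaches converge.\n",
  100 * hi_nd$nd_fraction[1],
  100 * hi_nd$rel_bias[hi_nd$approach == "A"],
  100 * hi_nd$rel_bias[hi_nd$approach == "E"]))
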