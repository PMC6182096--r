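#!/usr/bin/env Rscript
# Five ways to handle non-detects, one small real dataset.
#
# Eight raw water Giardia cyst samples (City of Calgary, October 2012):
# counts 1,0,0,0,0,0,0,2 in 50-64 L volumes. Six of eight samples are
# non-detects. We estimate the arithmetic mean and SD of the cyst
# concentration distribution (lognormal across sampling events) five ways:
#   A  omit non-detects
#   B  substitute the per-sample reporting limit (1/volume)
#   C  substitute half the limit
#   D  left-censored lognormal MLE
#   E  Poisson-lognormal MLE on the raw counts (zeros are data)
# Only E uses the raw counts and models sampling error; A-D operate on the
# legacy "reported concentration" view.

library(ndcount)
dir.create("results", showWarnings = FALSE)

giardia <- load_fixture("calgary_giardia_2012")
cat("Dataset:", nrow(giardia), "samples,", sum(giardia$count), "cysts in",
    sum(giardia$volume), "L total\n")
cat("Reported view (cysts/100 L):",
    paste(format_reported_per_100L(to_reported(giardia)), collapse = "  "),
    "\n\n")

fits <- fit_all_approaches(giardia)
tab <- do.call(rbind, lapply(names(fits), function(ap) {
  f <- fits[[ap]]
  data.frame(approach = ap, meanlog = f$meanlog, sdlog = f$sdlog,
             arith_mean = f$arith_mean, arith_sd = f$arith_sd,
             loglik = f$loglik, converged = f$converged)
}))
write.csv(tab, "results/giardia_approaches.csv", row.names = FALSE)
print(transform(tab, arith_mean = round(arith_mean, 4),
                arith_sd = round(arith_sd, 4),
                meanlog = round(meanlog, 3), sdlog = round(sdlog, 3),
                loglik = round(loglik, 3)),
      row.names = FALSE)

cat(sprintf("\nNaive pooled mean (total count / total volume): %.4f /L\n",
            naive_pooled_mean(giardia)))

br <- bias_ratio(fits)
ratio_tab <- data.frame(approach = names(br$ratios),
                        mean_ratio_vs_E = br$ratios)
write.csv(ratio_tab, "results/giardia_bias_ratios.csv", row.names = FALSE)
cat("\nOverestimation of the mean relative to the count model (E):\n")
print(transform(ratio_tab, mean_ratio_vs_E = round(mean_ratio_vs_E, 2)),
      row.names = FALSE)
cat(sprintf(
  "\nOmitting non-detects inflates the mean %.1f-fold; even the censored-data
treatment inflates it %.1f-fold. The Poisson-lognormal mean (%.4f /L)
essentially matches the pooled count ratio, as it should: zeros carry
information.\n",
  br$ratios[["A"]], br$ratios[["D"]], fits$E$arith_mean))
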