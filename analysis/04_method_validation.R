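#!/usr/bin/env Rscript
# Step 4 — quantitative validation of the deconvolution and the statistics.
#
# Four studies, written to results/validation/:
#   (a) noise-free parameter recovery over a CBF x MTT grid,
#   (b) CBF error under acquisition noise at baseline SNR 50,
#   (c) bolus-delay sensitivity of simple vs block-circulant SVD,
#   (d) power and type-I calibration of the cohort statistics.

suppressPackageStartupMessages(library(dscperf))
out <- "results/validation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cat("(a) Noise-free recovery (unregularised inversion, truncation 1e-6)\n")
nf <- recovery_experiment(seed = 1)
write.csv(nf, file.path(out, "recovery_noise_free.csv"), row.names = FALSE)
cat(sprintf("    max |CBF error| %.3g%%, max |MTT error| %.3g%% over %d cells\n",
            100 * max(abs(nf$cbf_rel_err)), 100 * max(abs(nf$mtt_rel_err)),
            nrow(nf)))

cat("(b) SNR-50 noise robustness (clinical truncation 0.03)\n")
noisy <- recovery_experiment(snr = 50, n_rep = 40, seed = 2)
write.csv(noisy, file.path(out, "recovery_snr50.csv"), row.names = FALSE)
cat(sprintf("    median |CBF error| %.3g%% over %d noisy curves\n",
            100 * median(abs(noisy$cbf_rel_err)), nrow(noisy)))
agg <- aggregate(abs(cbf_rel_err) ~ mtt_true, data = noisy, FUN = median)
names(agg) <- c("mtt_s", "median_abs_cbf_err")
print(agg, row.names = FALSE, digits = 3)

cat("(c) Delay sensitivity (tissue delayed 0-3 frames)\n")
d <- delay_experiment(delays_frames = 0:3)
write.csv(d, file.path(out, "delay_sensitivity.csv"), row.names = FALSE)
print(d, row.names = FALSE, digits = 4)
cat("    circulant mode is invariant under the shift; the truncated\n",
    "   simple mode underestimates at every nonzero delay, with the\n",
    "   sawtooth profile typical of hard singular-value truncation.\n")

cat("(d) Cohort statistics: power and calibration\n")
pw <- power_experiment(n_rep = 200, seed = 3)
cat(sprintf("    power of the MCA-terminal %%increase test: %.2f (200 cohorts)\n",
            pw$power))
cat(sprintf("    most-significant territory is MCA-terminal in %.0f%% of cohorts\n",
            100 * pw$modal_share))
cal <- null_calibration(n_rep = 1000, seed = 4)
cat("    null-cohort rejection rates at alpha 0.05 (5000 trials each):\n")
print(round(cal$rates, 4))
jsonlite::write_json(list(power = pw$power, modal_share = pw$modal_share,
                          null_rates = as.list(cal$rates)),
                     file.path(out, "statistics_validation.json"),
                     auto_unbox = TRUE, digits = NA)
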