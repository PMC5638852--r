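#!/usr/bin/env Rscript
# Simulation calibration of the fitting and search machinery: parameter
# recovery on two-regime data, shift detection at 3 stationary SDs, the
# false-shift rate on single-peak data, and the search-dominance rate on
# paper-like datasets.  Writes results/calibration.json.

suppressPackageStartupMessages({
  library(oulandscape)
  library(jsonlite)
})
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

rec <- recovery_harness(n_tips = 128, reps = 30, seed = seed)
cat(sprintf("theta recovery: median error %.3f log-kg; median t1/2 %.2f Ma (truth 1)\n",
            rec$median_theta_error, half_life(rec$median_alpha_hat)))
det <- shift_detection_harness(n_tips = 128, reps = 20, seed = seed)
cat(sprintf("shift detection at 3 SD: %.0f%%\n", 100 * det$recovery_rate))
fs <- false_shift_harness(n_tips = 64, reps = 30, seed = seed)
cat(sprintf("false-shift rate on single-peak data: %.0f%%\n",
            100 * fs$false_shift_rate))
dom <- dominance_harness(seeds = seed * 10L + 1:10, n_tips = 87)
cat(sprintf("search dominance over fixed hypotheses: %.0f%%\n",
            100 * dom$dominance_rate))

dir.create("results", showWarnings = FALSE)
write_json(list(median_theta_error = rec$median_theta_error,
                median_half_life = half_life(rec$median_alpha_hat),
                shift_detection_rate = det$recovery_rate,
                false_shift_rate = fs$false_shift_rate,
                dominance_rate = dom$dominance_rate),
           "results/calibration.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/calibration.json\n")
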