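#!/usr/bin/env Rscript
# Step 5: simulation studies of the model-selection procedure.
# (a) Selection consistency: how often does the comparison pick the true
#     partition as the best model, as birds are added to the experiment?
# (b) Parameter recovery: are the stage-transition rates estimated without
#     bias when the full pipeline (simulate -> code -> aggregate) runs?

suppressMessages(library(predseq))

out_dir <- "results/recovery"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cat("(a) selection consistency, spicauda-different truth",
    "(attack p = 0.2/0.2/0.5):\n")
cons <- selection_consistency(
  c(euptychiina = 0.2, heliconius = 0.2, spicauda = 0.5),
  "spicauda_different", n_birds_vec = c(50, 200, 800),
  n_replicates = 200, seed = 7)
print(cons, row.names = FALSE)
write.csv(cons, file.path(out_dir, "selection_consistency.csv"),
          row.names = FALSE)
cat("note: the frequency approaches P(chisq_1 < 2 ln 10) ~ 0.97, the\n",
    "asymptotic ceiling of best-model AICc selection, rather than 1.\n")

cat("\n    all-equal truth (p = 0.3 everywhere), n = 131:\n")
null_cons <- selection_consistency(
  c(euptychiina = 0.3, heliconius = 0.3, spicauda = 0.3),
  "all_equal", n_birds_vec = 131, n_replicates = 200, seed = 7)
print(null_cons, row.names = FALSE)

cat("\n(b) parameter recovery, study-calibrated configuration,",
    "20 replicates:\n")
rec <- parameter_recovery(sim_config(seed = 20260921), n_replicates = 20)
write.csv(rec$rates, file.path(out_dir, "recovery_rates.csv"),
          row.names = FALSE)
det <- rec$rates[rec$rates$transition == "detect", ]
cat("detection rates (truth vs mean estimate):\n")
with(det, cat(sprintf("  %s: %.3f vs %.3f (bias %+.3f, 3-SE coverage %.2f)\n",
                      prey_type, truth, mean_estimate, bias, coverage_3se)))
cat("best-model frequencies on the attacked stage:\n")
print(rec$selection)
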