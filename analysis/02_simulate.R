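#!/usr/bin/env Rscript
# Simulate synthetic eye-tracking sessions for both presentation modes and
# write them in the package's TSV dialects, ground truth alongside.
# Writes: results/sessions/<participant>_{trace,trials}.tsv, ground_truth.yaml

suppressMessages(library(vwpupil))
out <- "results/sessions"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

n_per_preset <- 4
for (preset in c("NS", "DS")) {
  truth <- ground_truth(preset)
  for (i in seq_len(n_per_preset)) {
    id <- sprintf("%s_p%02d", preset, i)
    cfg <- session_config(presentation = preset,
                          seed = 1000L + 500L * (preset == "DS") + i)
    ses <- generate_session(cfg, truth = truth, participant = id)
    write_ocular_tsv(ses$trace, file.path(out, paste0(id, "_trace.tsv")))
    write_trials_tsv(ses$trials, file.path(out, paste0(id, "_trials.tsv")))
  }
  yaml::write_yaml(unclass(truth), file.path(out, paste0("ground_truth_", preset, ".yaml")))
  tc <- true_crossover_offset(truth)
  cat(sprintf("%s truth: crossover %d/%d ms, offset %d ms; ERPD peak %d ms\n",
              preset, tc$crossover[1], tc$crossover[2], tc$offset_ms,
              truth$erpd$peak_ms))
}
cat("wrote", 2 * n_per_preset, "sessions to", out, "\n")
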