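#!/usr/bin/env Rscript
# Read the simulated sessions back from disk, apply the screening and
# blink-repair rules, epoch the kept trials and attach %ERPD under both
# baselines. Reports exclusion counts per rule.
# Reads:  results/sessions/   Writes: results/preprocessed/

suppressMessages({library(vwpupil); library(dplyr)})
ses_dir <- "results/sessions"
out <- "results/preprocessed"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

trial_files <- list.files(ses_dir, "_trials\\.tsv$", full.names = TRUE)
epochs <- list(); screening <- list()
for (tf in trial_files) {
  id <- sub("_trials\\.tsv$", "", basename(tf))
  ses <- list(trials = read_trials_tsv(tf),
              trace = read_ocular_tsv(sub("_trials", "_trace", tf)),
              participant = id)
  pre <- preprocess_session(ses)
  screening[[id]] <- count(pre$trials, exclude_reason) |> mutate(participant = id)
  if (pre$participant_keep) epochs[[id]] <- pre$epochs
  cat(sprintf("%s: %d/%d trials kept, baseline2 = %.1f\n", id,
              sum(pre$trials$keep), nrow(pre$trials), pre$baseline2))
}
readr::write_tsv(bind_rows(screening), file.path(out, "screening.tsv"))
readr::write_tsv(bind_rows(epochs), file.path(out, "epochs.tsv"))
cat("wrote", file.path(out, "epochs.tsv"), "\n")
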