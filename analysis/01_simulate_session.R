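#!/usr/bin/env Rscript
# Stage 1: simulate the study sessions.
#
# Two sessions of 240 trials (60 per condition, pseudo-random order with at
# most 4 repeats, durations ~ 7.26 +/- 1.91 s, 5 s rest): one whose EEG
# carries the coupling index through a distributed nonlinear code (the
# configuration under which only the multivariate readout should succeed),
# and one univariate control where only the C3 alpha envelope is informative.
# Writes full archives (EEG + trajectories + ground truth) under results/.

suppressPackageStartupMessages(library(coupledraw))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

for (mode in c("distributed_nonlinear", "univariate")) {
  cfg <- session_config(encoding_mode = mode, snr = 1,
                        seed = if (mode == "univariate") seed + 3L else seed)
  message("simulating ", mode, " session (seed ", cfg$seed, ") ...")
  s <- generate_session(cfg)
  out <- file.path("results", paste0("session_", mode))
  write_session_archive(s, out)
  message("  ", nrow(s$trials), " trials, ",
          round(nrow(s$eeg$signals) / s$eeg$sfreq / 60, 1),
          " min of EEG -> ", out)
}
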