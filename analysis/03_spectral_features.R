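#!/usr/bin/env Rscript
# Stage 3: spectral preprocessing and feature extraction.
#
# For both sessions: 0.5-35 Hz zero-phase Butterworth filter, epochs from
# -2 s to trial offset, Morlet log-ratio maps (50 frequencies, baseline
# -2000..-500 ms, 200 normalised time points), the 18 ERD values per trial
# and the 3600-long multivariate feature vector per trial.

suppressPackageStartupMessages({library(coupledraw); library(data.table)})

for (mode in c("distributed_nonlinear", "univariate")) {
  ses_dir <- file.path("results", paste0("session_", mode))
  message("spectral features for ", mode, " session ...")
  eeg <- read_eeg_archive(file.path(ses_dir, "eeg"), expected_sfreq = 256)
  sp <- spectral_features(eeg)
  fwrite(sp$erd, file.path("results", paste0("erd_", mode, ".csv")))
  feat <- data.table(feature = rownames(sp$features), sp$features)
  setnames(feat, c("feature", paste0("trial_", colnames(sp$features))))
  fwrite(feat, file.path("results", paste0("features_", mode, ".csv")))
  if (nrow(sp$excluded) > 0) print(sp$excluded)
  message("  ", ncol(sp$features), " trials x ", nrow(sp$features),
          " features; ", nrow(sp$erd), " ERD rows")
}
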