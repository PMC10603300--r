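#!/usr/bin/env Rscript
# Stage 4: distributed univariate features.
#
# Welch magnitude-squared coherence (1 s Hann windows, 50% overlap) within
# each trial epoch, averaged over the three pairs of each motor channel
# group and over in-band frequencies: 3 groups x 2 bands = 6 values/trial.

suppressPackageStartupMessages({library(coupledraw); library(data.table)})

ses_dir <- file.path("results", "session_distributed_nonlinear")
eeg <- read_eeg_archive(file.path(ses_dir, "eeg"), expected_sfreq = 256)
ct <- coherence_table(eeg)
fwrite(ct$coherence, file.path("results", "coherence.csv"))
if (nrow(ct$excluded) > 0) print(ct$excluded)
message(nrow(ct$coherence), " trials x 6 group-band coherence values")
print(summary(as.matrix(ct$coherence[, -(1:2)])))
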