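#!/usr/bin/env Rscript
# Stage 5: multivariate prediction.
#
# Trains the 3600-100-1 network over repeated random 85/5/10 splits
# (variable-learning-rate backpropagation, early stopping), averages each
# trial's predictions over the iterations where it sat in the test set, and
# reports the mean test-set Pearson r across iterations. 50 iterations keep
# the run short; the iteration budget extends itself until every trial has
# at least 5 test appearances.

suppressPackageStartupMessages({library(coupledraw); library(data.table)})
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 2L
n_iter <- if (length(args) >= 2) as.integer(args[2]) else 50L

feat <- fread(file.path("results", "features_distributed_nonlinear.csv"))
features <- as.matrix(feat[, -1]); rownames(features) <- feat$feature
colnames(features) <- sub("^trial_", "", colnames(features))
beh <- fread(file.path("results", "behaviour.csv"))
ci <- beh$ci[match(colnames(features), as.character(beh$trial_id))]
stopifnot(!anyNA(ci))

res <- iterate_splits(features, ci, n_iter = n_iter, seed = seed)
fwrite(res$predictions, file.path("results", "ann_predictions.csv"))
fwrite(res$iterations, file.path("results", "ann_iterations.csv"))
message(sprintf("%d iterations (%d requested): mean test r = %.3f",
                res$n_iter_total, n_iter, res$mean_r))
message(sprintf("test appearances per trial: min %d, median %d",
                min(res$predictions$n_test_appearances),
                median(res$predictions$n_test_appearances)))
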