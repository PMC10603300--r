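#!/usr/bin/env Rscript
# Stage 6: cross-approach comparison.
#
# Correlates each neural measure with the behavioural coupling index:
# 18 ERD correlations (univariate), 6 coherence correlations (distributed
# univariate), and the single correlation between network-estimated and
# actual CI (multivariate). A permutation null for the maximum absolute
# correlation across all 24 univariate features provides the familywise
# chance level. Also verifies that, in the univariate control session, the
# encoded C3-alpha channel is detected by the plain ERD correlation.

suppressPackageStartupMessages({library(coupledraw); library(data.table)})

beh <- as.data.frame(fread(file.path("results", "behaviour.csv")))
ci_tab <- data.frame(trial_id = beh$trial_id, ci = beh$ci)
erd <- as.data.frame(fread(file.path("results", "erd_distributed_nonlinear.csv")))
coh <- as.data.frame(fread(file.path("results", "coherence.csv")))
pred <- as.data.frame(fread(file.path("results", "ann_predictions.csv")))

reports <- list(erd = correlate_erd(erd, ci_tab),
                coherence = correlate_coherence(coh, ci_tab),
                ann = evaluate_ann(pred, ci_tab))
fwrite(do.call(rbind, reports), file.path("results", "correlations.csv"))

cmp <- compare_approaches(reports)
fwrite(cmp, file.path("results", "comparison.csv"))
print(cmp, digits = 3)

uni_feats <- cbind(as.matrix(erd[, -(1:2)]), as.matrix(coh[, -(1:2)]))
bound <- perm_null_max_abs_r(uni_feats, ci_tab$ci, n_perm = 2000, seed = 7)
message(sprintf(paste0("max univariate |r| = %.3f vs permutation-null 95%% ",
                       "bound %.3f; ann r = %.3f"),
                max(abs(c(reports$erd$r, reports$coherence$r))), bound,
                reports$ann$r))

# univariate control session: the coded channel-band is found
erd_u <- as.data.frame(fread(file.path("results", "erd_univariate.csv")))
ses_u <- file.path("results", "session_univariate")
truth_u <- as.data.frame(fread(file.path(ses_u, "ground_truth.csv")))
rep_u <- correlate_erd(erd_u, data.frame(trial_id = truth_u$trial_id,
                                         ci = truth_u$true_ci))
c3a <- rep_u[rep_u$feature == "C3.alpha", ]
message(sprintf("univariate control: C3.alpha r = %.3f (p = %.2g)",
                c3a$r, c3a$p))

pdf(file.path("results", "ann_fit.pdf"), width = 5, height = 5)
plot_ann_fit(pred)
dev.off()
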