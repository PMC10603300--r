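#!/usr/bin/env Rscript
# Stage 2: behavioural analysis.
#
# Recomputes per-trial curvature (horizontal extent per hand) and the
# coupling index CI = 1 / max(|c_left - c_right|, 1 px) from the stored pen
# trajectories, summarises them per condition, and checks the two expected
# phenomena: curvature ordering line-line < incongruent < circle-circle for
# both hands, and higher mean CI in congruent than incongruent trials.

suppressPackageStartupMessages({library(coupledraw); library(data.table)})

ses_dir <- file.path("results", "session_distributed_nonlinear")
traj <- trajectories_from_table(fread(file.path(ses_dir, "trajectories.csv")))
trials <- as.data.frame(fread(file.path(ses_dir, "trials.csv")))

beh <- curvature_table(traj[as.character(trials$trial_id)], trials)
fwrite(beh, file.path("results", "behaviour.csv"))

cs <- summarise_conditions(beh)
fwrite(cs, file.path("results", "condition_summary.csv"))
print(cs, digits = 3)

ord <- check_extent_ordering(cs)
cong <- is_congruent(beh$condition)
message(sprintf("curvature ordering holds: left %s, right %s",
                ord["left"], ord["right"]))
message(sprintf("mean CI congruent %.3f vs incongruent %.4f",
                mean(beh$ci[cong]), mean(beh$ci[!cong])))
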