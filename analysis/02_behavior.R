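#!/usr/bin/env Rscript

# Step 2 — score Go/NoGo behavior.
#
# Classifies every trial of the task-inclusive blocks into
# Hit/Miss/FA/CR, computes per-subject d' (log-linear corrected) and RT
# summaries per condition, and runs the 2 (Group) x 3 (Condition) mixed
# ANOVA on d' and RT with Greenhouse-Geisser correction, followed by
# Bonferroni pairwise contrasts on the condition factor.

library(mobigng)

study <- "scratch/study"
blocks <- study_blocks(study)
rate <- jsonlite::read_json(file.path(study, "manifest.json"))$rate

beh <- stage_behavior(blocks, rate)
dir.create("results", showWarnings = FALSE)
write.csv(beh$summary, "results/behavior.csv", row.names = FALSE)
write.csv(beh$anova, "results/behavior_anova.csv", row.names = FALSE)

message("per-group d' (mean over subjects x conditions):")
print(aggregate(dprime ~ group, beh$summary, mean))
message("\nmixed ANOVA (d' and RT):")
print(beh$anova[, c("dv", "effect", "F", "df", "df_error", "p_gg",
                    "partial_eta_sq")], digits = 3)

ph <- pairwise_posthoc(beh$summary[beh$summary$group == "TD", ],
                       dv = "dprime", factor = "condition")
message("\nTD condition contrasts on d' (Bonferroni):")
print(ph[, c("level_1", "level_2", "t", "p_bonf", "cohens_d")], digits = 3)
write.csv(ph, "results/behavior_posthoc_td.csv", row.names = FALSE)
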