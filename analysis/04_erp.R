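#!/usr/bin/env Rscript

# Step 4 — ERP extraction.
#
# For every task block: 0.25-40 Hz zero-phase band-pass, average
# reference, bad-channel detection with spherical-spline interpolation,
# stimulus-locked -100..800 ms epochs (461 samples at 512 Hz) with
# baseline correction, subject averages per condition x response type.
# Grand averages drive the two-pass peak windows (group peak latency
# +/- 25 ms for P2/N2, +/- 50 ms for P3); per-subject peak measures feed
# 3 (Condition) x 2 (Response Type) x Group mixed ANOVAs per component,
# and CR - Hit difference waves with 50 ms topographic segment means are
# exported. Subject averages are cached for the cluster stage.

library(mobigng)

study <- "scratch/study"
blocks <- study_blocks(study)
rate <- jsonlite::read_json(file.path(study, "manifest.json"))$rate

message("running ERP stage (filter, reference, interpolate, epoch) ...")
erp <- stage_erp(blocks, rate, default_config())

dir.create("results", showWarnings = FALSE)
write.csv(erp$measures, "results/erp_measures.csv", row.names = FALSE)
write.csv(erp$windows, "results/erp_windows.csv", row.names = FALSE)
write.csv(erp$anova, "results/erp_anova.csv", row.names = FALSE)
saveRDS(list(subject_avgs = erp$subject_avgs, time = erp$time),
        "scratch/subject_avgs.rds")

message("two-pass peak windows per group:")
print(erp$windows, digits = 4)

message("\nCR vs Hit P3 amplitude by group (subject-average means):")
m <- erp$measures[erp$measures$component == "P3", ]
print(aggregate(amplitude ~ group + response_type, m, mean), digits = 3)

message("\nper-component mixed ANOVAs (GG-corrected p):")
print(erp$anova[, c("dv", "effect", "F", "p_gg", "partial_eta_sq")],
      digits = 3)

## difference-wave topographic segments (10 x 50 ms bins, 100-600 ms)
for (nm in names(erp$diff_waves)) {
  seg <- topo_segments(erp$diff_waves[[nm]], erp$time)
  write.csv(seg, sprintf("results/diff_topo_%s.csv", nm))
}
message("\nwrote ", length(erp$diff_waves), " difference-wave topographies")
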