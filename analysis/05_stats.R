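#!/usr/bin/env Rscript

# Step 5 — pointwise cluster statistics.
#
# Runs the consecutive-sample cluster analysis on the cached subject
# averages: per group and task condition a paired Hit-vs-CR t-map over
# every channel x time point, and per condition a two-sample map comparing
# the groups' CR - Hit difference waves. A point survives only inside a
# run of >= 10 consecutive sub-alpha samples within its channel
# (alpha = 0.05). Nine maps in total; t-matrices and masks land under
# results/cluster_maps/.

library(mobigng)

cache <- readRDS("scratch/subject_avgs.rds")
maps <- cluster_contrast_suite(cache$subject_avgs)

dir.create("results/cluster_maps", recursive = TRUE, showWarnings = FALSE)
for (nm in names(maps)) {
  write.csv(maps[[nm]]$t, sprintf("results/cluster_maps/%s_t.csv", nm))
  write.csv(maps[[nm]]$mask * 1L,
            sprintf("results/cluster_maps/%s_mask.csv", nm))
}

summ <- data.frame(
  contrast = names(maps),
  df = vapply(maps, function(m) m$df, 0),
  masked_points = vapply(maps, function(m) sum(m$mask), 0),
  channels_hit = vapply(maps, function(m) sum(apply(m$mask, 1, any)), 0))
write.csv(summ, "results/cluster_summary.csv", row.names = FALSE)
message("cluster map summary (points surviving the 10-sample criterion):")
print(summ, row.names = FALSE)
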