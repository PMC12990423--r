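#!/usr/bin/env Rscript

# Step 1 — materialize a synthetic two-group MoBI study.
#
# Builds an on-disk study emulating the experiment's recording streams:
# per subject and condition one block of the visual Go/NoGo task (Go 'X' /
# NoGo 'O', 20% NoGo, 400 ms stimuli, 200-400 ms ISI) with 64-channel
# 512 Hz EEG carrying P2/N2/P3 components, plus 100 Hz heel-marker
# trajectories for walking blocks. Group parameter sets follow the study's
# printed group contrasts (TD more sensitive d', narrower step width, less
# variable stride timing than ASD).
#
# The study tree lands in scratch/study (BDF + TSV + CSV + ground truth).

library(mobigng)

out_dir <- "scratch/study"
spec <- scenario_spec(
  n_subjects = c(TD = 4, ASD = 4),
  n_blocks = 1,
  trials_per_block = 60,   # scaled-down block; the design ratio is intact
  noise_rms = 6,
  seed = 20260927)

message("building synthetic study under ", out_dir, " ...")
t0 <- Sys.time()
man <- build_scenario(spec, out_dir, force = TRUE)
message(sprintf("done in %.1f s: %d blocks, %d subjects",
                as.numeric(difftime(Sys.time(), t0, units = "secs")),
                length(man$blocks), length(man$subjects)))
message("NoGo proportion per block is exact: ",
        sum(generate_trial_stream(spec$trials_per_block, 0.2,
                                  seed = 1)$stim == "NoGo"),
        "/", spec$trials_per_block)
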