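test_that("trial stream honors the exact-proportion design parameters", {
  s <- generate_trial_stream(180, 0.2, c(200, 400), 400, seed = 1)
  expect_equal(sum(s$stim == "NoGo"), 36L)
  expect_equal(sum(s$stim == "Go"), 144L)
  expect_true(all(s$isi >= 200 & s$isi <= 400))
  expect_true(all(diff(s$onset) > 0))
  ## SOA = stimulus duration + preceding ISI
  expect_equal(diff(s$onset), 400 + s$isi[-nrow(s)])

  expect_identical(generate_trial_stream(50, 0.2, seed = 9),
                   generate_trial_stream(50, 0.2, seed = 9))
  expect_equal(sum(generate_trial_stream(10, 0, seed = 2)$stim == "NoGo"), 0L)
  expect_error(generate_trial_stream(10, 1), "p_nogo")
})

test_that("simulated responses match their generating rates and RT law", {
  s <- generate_trial_stream(100, 0.2, seed = 3)
  r <- simulate_behavior(s, behavior_params(hit_rate = 1, fa_rate = 0),
                         seed = 1)
  expect_true(all(r$pressed[s$stim == "Go"]))
  expect_false(any(r$pressed[s$stim == "NoGo"]))

  big <- generate_trial_stream(12500, 0.2, seed = 4)
  rb <- simulate_behavior(big, behavior_params(hit_rate = 0.9, fa_rate = 0.2,
                                               rt_mean = 350, rt_sd = 40),
                          seed = 5)
  go <- big$stim == "Go"
  n_go <- sum(go)                                  # 10,000 Go trials
  expect_equal(n_go, 10000L)
  se <- sqrt(0.9 * 0.1 / n_go)                     # binomial SE oracle
  expect_lt(abs(mean(rb$pressed[go]) - 0.9), 3 * se)
  lat <- rb$latency[go & rb$pressed]
  expect_lt(abs(mean(lat) - 350), 3 * 40 / sqrt(length(lat)))  # CLT oracle

  expect_warning(behavior_params(hit_rate = 0.3, fa_rate = 0.4), "chance")
})

test_that("noise-free EEG reproduces the injected component exactly", {
  s <- generate_trial_stream(10, 0.2, seed = 6)
  comp <- erp_component("P3", 400, 5, 60)
  rec <- simulate_eeg(s, NULL, list(comp), noise_rms = 0,
                      layout = small_layout(), seed = 1)
  ep <- epoch(rec)
  av <- apply(ep$data, c(2, 3), mean)
  rownames(av) <- ep$channels
  pk <- find_peak(av, ep$time, "CPz", c(300, 500), 1)
  expect_lt(abs(pk$latency - 400), 2)        # within one 512 Hz sample
  expect_lt(abs(pk$amplitude - 5), 0.1)
})

test_that("grand-average amplitude converges at the analytic SE rate", {
  s <- generate_trial_stream(200, 0, seed = 7)
  comp <- erp_component("P3", 400, 5, 60)
  rec <- simulate_eeg(s, NULL, list(comp), noise_rms = 10,
                      layout = small_layout(), seed = 2)
  ep <- epoch(rec)
  av <- apply(ep$data, c(2, 3), mean)
  rownames(av) <- ep$channels
  pk <- find_peak(av, ep$time, "CPz", c(300, 500), 1)
  se <- 10 / sqrt(200)
  expect_lt(abs(pk$amplitude - 5), 2 * se)
  expect_lt(abs(pk$latency - 400), 20)
})

test_that("EEG simulation is deterministic and validates latencies", {
  s <- generate_trial_stream(5, 0.2, seed = 8)
  r1 <- simulate_eeg(s, NULL, list(erp_component("P2", 240, 4)),
                     noise_rms = 3, layout = small_layout(), seed = 11)
  r2 <- simulate_eeg(s, NULL, list(erp_component("P2", 240, 4)),
                     noise_rms = 3, layout = small_layout(), seed = 11)
  expect_identical(r1$samples, r2$samples)
  expect_error(simulate_eeg(s, NULL, list(erp_component("P3", 900, 5)),
                            layout = small_layout()), "outside epoch")
  expect_error(erp_component("N2", 320, 2), "N2")
  expect_error(erp_component("P2", 240, -1), "P2")
})

test_that("noiseless gait generator yields exact stride geometry", {
  p0 <- gait_params(stride_time_cv = 0, stride_length_cv = 0,
                    step_width_cv = 0)
  sim <- simulate_gait_markers(p0, 20, seed = 1)
  expect_equal(unique(diff(sim$truth$right_strikes)), 1300)
  z <- sim$stream$markers$right_heel[, "z"]
  st <- detect_heel_strikes(z, 100, smooth = FALSE)
  expect_equal(unique(round(diff(st))), 1300)
  w <- step_widths(sim$stream$markers$left_heel[, "x"],
                   sim$stream$markers$right_heel[, "x"], st, 100)
  expect_equal(unique(round(w, 9)), 200)
  ## lift-to-strike distance = configured stride length, within one sample
  ## of belt drift
  lifts <- detect_heel_lifts(z, st, 100)
  sm <- stride_metrics(z, st, lifts, 100)
  expect_true(all(abs(sm$stride_length - 660) <= 845 / 100 + 1e-9))
})

test_that("gait generator reproduces configured variability", {
  sim <- simulate_gait_markers(gait_params(stride_time_cv = 3), 270, seed = 2)
  expect_gt(length(sim$truth$stride_times), 190)
  expect_lt(abs(cv_percent(sim$truth$stride_times) - 3), 0.6)
  expect_error(simulate_gait_markers(gait_params(stride_time_cv = 40), 100),
               "non-positive|stance")
  expect_error(simulate_gait_markers(gait_params(), 3), "5 strides")
})

test_that("electrode layout satisfies its geometric conventions", {
  lay <- electrode_layout()
  expect_equal(nrow(lay), 64L)
  expect_true(all(c("FCz", "Cz", "CPz") %in% lay$label))
  norms <- sqrt(lay$x^2 + lay$y^2 + lay$z^2)
  expect_true(all(abs(norms - 1) < 1e-9))
  expect_equal(lay$label[which.max(lay$y)], "Cz")
  ## FCz anterior of Cz, CPz posterior
  expect_gt(lay$z[lay$label == "FCz"], 0)
  expect_lt(lay$z[lay$label == "CPz"], 0)
})

test_that("build_scenario writes the expected study tree deterministically", {
  spec <- scenario_spec(n_subjects = c(TD = 1, ASD = 1),
                        trials_per_block = 10, noise_rms = 2, seed = 5)
  d1 <- withr::local_tempdir()
  build_scenario(spec, d1)
  eeg <- list.files(d1, pattern = "\\.bdf$", recursive = TRUE)
  mks <- list.files(d1, pattern = "markers\\.csv$", recursive = TRUE)
  ## 2 subjects x 5 conditions x 1 block; markers only for walking blocks
  expect_equal(length(eeg), 10L)
  expect_equal(length(mks), 8L)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_true(file.exists(file.path(d1, "ground_truth.json")))

  d2 <- withr::local_tempdir()
  build_scenario(spec, d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  f1 <- file.path(d1, "subjects", "TD01", "S-NF-T", "block_1.bdf")
  f2 <- file.path(d2, "subjects", "TD01", "S-NF-T", "block_1.bdf")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_error(build_scenario(spec, d1), "not empty")
  expect_error(scenario_spec(conditions = c("S-F-T")), "S-F-T")
})
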