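## default component sets: latencies chosen so the two-pass windows land at
## plausible group-specific values; amplitudes give CR > Hit inhibition
## effects, stronger in the TD group
default_erp_components <- function(group = c("TD", "ASD")) {
  group <- match.arg(group)
  if (group == "TD") list(
    erp_component("P2", 244, 4.0, 25, scale = c(Hit = 1, CR = 1.35)),
    erp_component("N2", 319, -3.0, 30, scale = c(Hit = 1, CR = 1.20)),
    erp_component("P3", 413, 6.0, 60, scale = c(Hit = 1, CR = 1.50)))
  else list(
    erp_component("P2", 250, 3.5, 25, scale = c(Hit = 1, CR = 1.20)),
    erp_component("N2", 321, -2.5, 30, scale = c(Hit = 1, CR = 1.15)),
    erp_component("P3", 405, 5.0, 60, scale = c(Hit = 1, CR = 1.20)))
}

default_behavior_params <- function(group = c("TD", "ASD")) {
  group <- match.arg(group)
  if (group == "TD") list(
    default = behavior_params(0.89, 0.17, 390, 80),
    `W-NF-T` = behavior_params(0.93, 0.15, 410, 80),
    `W-F-T` = behavior_params(0.93, 0.15, 425, 85))
  else list(default = behavior_params(0.85, 0.25, 420, 90))
}

default_gait_params <- function(group = c("TD", "ASD")) {
  group <- match.arg(group)
  if (group == "TD")
    gait_params(belt_speed = 845, stride_time_mean = 1300,
                stride_time_cv = 2.6, stride_length_mean = 660,
                stride_length_cv = 2.2, step_width_mean = 177.6,
                step_width_cv = 9.2)
  else
    gait_params(belt_speed = 657, stride_time_mean = 1350,
                stride_time_cv = 3.8, stride_length_mean = 515,
                stride_length_cv = 3.4, step_width_mean = 218.9,
                step_width_cv = 9.2)
}

#' Synthetic study scenario
#'
#' Full specification of a synthetic two-group study: subjects per group,
#' conditions, blocks, trials per block (study design: 180 trials, 20%
#' NoGo, 400 ms stimuli, 200-400 ms ISI), per-group behavioral / ERP / gait
#' parameters, background noise level, and the master seed. Everything
#' downstream is deterministic given the seed. Conditions outside the five
#' study combinations (e.g. S-F-T) are rejected unless `permissive`.
#'
#' @param n_subjects named integer vector, subjects per group.
#' @param conditions condition codes to simulate.
#' @param n_blocks blocks per condition.
#' @param trials_per_block trials per block.
#' @param p_nogo NoGo proportion.
#' @param behavior per-group behavioral parameters: a [behavior_params()]
#'   or a named list of them by condition with a `default` entry.
#' @param erp per-group lists of [erp_component()].
#' @param gait per-group [gait_params()]. Task blocks scale the gait CVs by
#'   `task_cv_factor`; flow blocks add `flow_width_delta` mm to step width.
#' @param task_cv_factor,flow_width_delta condition modulations of gait.
#' @param noise_rms EEG background noise RMS, microvolts.
#' @param eeg_rate,marker_rate sampling rates (study: 512 and 100 Hz).
#' @param seed master seed.
#' @param permissive allow non-study conditions.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_subjects = c(TD = 3, ASD = 3),
                          conditions = STUDY_CONDITIONS,
                          n_blocks = 1, trials_per_block = 180,
                          p_nogo = 0.2,
                          behavior = list(TD = default_behavior_params("TD"),
                                          ASD = default_behavior_params("ASD")),
                          erp = list(TD = default_erp_components("TD"),
                                     ASD = default_erp_components("ASD")),
                          gait = list(TD = default_gait_params("TD"),
                                      ASD = default_gait_params("ASD")),
                          task_cv_factor = 0.8, flow_width_delta = 4,
                          noise_rms = 10, eeg_rate = 512, marker_rate = 100,
                          seed = 1, permissive = FALSE) {
  if (!permissive) {
    badc <- setdiff(conditions, STUDY_CONDITIONS)
    if (length(badc))
      stopf("condition(s) %s not in the study design (set permissive = TRUE to allow)",
            paste(badc, collapse = ", "))
  }
  groups <- names(n_subjects)
  stopifnot(!is.null(groups), all(groups %in% names(behavior)),
            all(groups %in% names(erp)), all(groups %in% names(gait)))
  structure(list(n_subjects = n_subjects, conditions = conditions,
                 n_blocks = n_blocks, trials_per_block = trials_per_block,
                 p_nogo = p_nogo, behavior = behavior, erp = erp,
                 gait = gait, task_cv_factor = task_cv_factor,
                 flow_width_delta = flow_width_delta, noise_rms = noise_rms,
                 eeg_rate = eeg_rate, marker_rate = marker_rate,
                 seed = seed, permissive = permissive),
            class = "scenario_spec")
}

behavior_for <- function(spec, group, condition) {
  b <- spec$behavior[[group]]
  if (inherits(b, "behavior_params")) return(b)
  b[[condition]] %||% b$default
}

gait_for <- function(spec, group, condition) {
  g <- spec$gait[[group]]
  cl <- parse_condition(condition)
  if (cl$cognitive == "task") {
    g$stride_time_cv <- g$stride_time_cv * spec$task_cv_factor
    g$stride_length_cv <- g$stride_length_cv * spec$task_cv_factor
    g$step_width_cv <- g$step_width_cv * spec$task_cv_factor
  }
  if (cl$sensory == "flow")
    g$step_width_mean <- g$step_width_mean + spec$flow_width_delta
  g
}

#' Materialize a synthetic study on disk
#'
#' Writes the directory layout consumed by [run_all()]:
#' `subjects/<id>/<condition>/block_<n>.bdf` (EEG with events on the Status
#' channel), `block_<n>.events.tsv`, and for walking blocks
#' `block_<n>.markers.csv`, plus `manifest.json` (subject/group/file
#' inventory) and `ground_truth.json` (the generating parameters and
#' realized per-block gait truths, for recovery tests).
#'
#' @param spec [scenario_spec()].
#' @param out_dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return the manifest, invisibly.
#' @export
build_scenario <- function(spec, out_dir, force = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stopf("output directory %s is not empty (use force = TRUE)", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  layout <- electrode_layout()
  files <- list(); subjects <- list(); truth <- list()
  for (g in names(spec$n_subjects)) {
    for (si in seq_len(spec$n_subjects[[g]])) {
      sid <- sprintf("%s%02d", g, si)
      subjects[[sid]] <- list(id = sid, group = g)
      for (cond in spec$conditions) {
        cl <- parse_condition(cond)
        cdir <- file.path(out_dir, "subjects", sid, cond)
        dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
        for (b in seq_len(spec$n_blocks)) {
          bseed <- derive_seed(spec$seed, paste(sid, cond, b))
          stream <- generate_trial_stream(
            spec$trials_per_block, spec$p_nogo, seed = bseed)
          responses <- if (cl$cognitive == "task")
            simulate_behavior(stream, behavior_for(spec, g, cond),
                              seed = bseed + 1L) else NULL
          rec <- simulate_eeg(stream, responses, spec$erp[[g]],
                              noise_rms = spec$noise_rms,
                              rate = spec$eeg_rate, layout = layout,
                              seed = bseed + 2L)
          base <- file.path(cdir, sprintf("block_%d", b))
          write_eeg(rec, paste0(base, ".bdf"))
          ev <- rec$events
          ev <- data.frame(onset_sample = ev$sample, code = ev$code,
                           condition = cond)
          write_events(ev, paste0(base, ".events.tsv"))
          bfiles <- c(eeg = paste0(base, ".bdf"),
                      events = paste0(base, ".events.tsv"))
          if (cl$motor == "walking") {
            dur_s <- n_samples(rec) / rec$rate
            sim <- simulate_gait_markers(gait_for(spec, g, cond), dur_s,
                                         rate = spec$marker_rate,
                                         seed = bseed + 3L)
            write_markers(sim$stream, paste0(base, ".markers.csv"))
            bfiles["markers"] <- paste0(base, ".markers.csv")
            truth[[paste(sid, cond, b, sep = "/")]] <- list(
              stride_time_mean = mean(sim$truth$stride_times),
              stride_time_cv = cv_percent(sim$truth$stride_times),
              stride_length_mean = mean(sim$truth$stride_lengths),
              stride_length_cv = cv_percent(sim$truth$stride_lengths),
              step_width_mean = mean(sim$truth$step_widths),
              step_width_cv = cv_percent(sim$truth$step_widths),
              n_strides = length(sim$truth$stride_times))
          }
          files[[paste(sid, cond, b, sep = "/")]] <-
            as.list(gsub(paste0(out_dir, "/"), "", bfiles, fixed = TRUE))
        }
      }
    }
  }
  manifest <- list(rate = spec$eeg_rate, marker_rate = spec$marker_rate,
                   seed = spec$seed, subjects = subjects, blocks = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  gt <- list(seed = spec$seed,
             behavior = lapply(spec$behavior, function(b)
               if (inherits(b, "behavior_params")) unclass(b)
               else lapply(b, unclass)),
             gait = lapply(spec$gait, unclass), gait_blocks = truth)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
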