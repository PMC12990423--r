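#' Enumerate a study's blocks
#'
#' Reads `manifest.json` and returns one row per subject x condition x
#' block with the group label and the EEG / events / markers file paths.
#'
#' @param study_dir study root directory.
#' @return data.frame with columns subject, condition, block, group, eeg,
#'   events, markers (NA when absent).
#' @export
study_blocks <- function(study_dir) block_table(study_dir)

read_manifest <- function(study_dir) {
  mf <- file.path(study_dir, "manifest.json")
  if (!file.exists(mf)) stopf("no manifest.json in %s", study_dir)
  jsonlite::read_json(mf)
}

block_table <- function(study_dir) {
  man <- read_manifest(study_dir)
  groups <- vapply(man$subjects, function(s) s$group, "")
  rows <- lapply(names(man$blocks), function(key) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    b <- man$blocks[[key]]
    data.frame(subject = parts[1], condition = parts[2],
               block = as.integer(parts[3]),
               group = unname(groups[parts[1]]),
               eeg = file.path(study_dir, b$eeg),
               events = file.path(study_dir, b$events),
               markers = if (is.null(b$markers)) NA_character_
                         else file.path(study_dir, b$markers))
  })
  do.call(rbind, rows)
}

#' Classify one block's events TSV into trial records
#'
#' Reads the tab-separated event table (stimulus codes 1/2, press code 100),
#' reconstructs the trial stream and press times in ms, and applies
#' [classify_trials()].
#'
#' @param events_path events TSV path.
#' @param rate EEG sampling rate used for the sample indices.
#' @param valid_window response-validity window in ms.
#' @return classified trial records.
#' @export
classify_block <- function(events_path, rate, valid_window = c(100, 800)) {
  ev <- read_events(events_path)
  stim <- ev[ev$code %in% c(EVENT_GO, EVENT_NOGO), ]
  presses <- ev$onset_sample[ev$code == EVENT_PRESS] / rate * 1000
  stream <- data.frame(trial = seq_len(nrow(stim)),
                       onset = stim$onset_sample / rate * 1000,
                       stim = ifelse(stim$code == EVENT_GO, "Go", "NoGo"),
                       condition = stim$condition)
  classify_trials(stream, presses, valid_window)
}

#' Behavior stage: score all task blocks of a study
#'
#' @param blocks block table from [study_blocks()].
#' @param rate EEG sampling rate (from the study manifest).
#' @return list with `summary` (per subject x condition) and `anova`
#'   (d-prime and RT mixed ANOVA tables, when estimable).
#' @export
stage_behavior <- function(blocks, rate) {
  task_blocks <- blocks[blocks$condition %in% task_conditions(), ]
  trials <- do.call(rbind, lapply(seq_len(nrow(task_blocks)), function(i) {
    tr <- classify_block(task_blocks$events[i], rate)
    tr$subject <- task_blocks$subject[i]
    tr$group <- task_blocks$group[i]
    tr
  }))
  summary <- summarize_behavior(trials)
  summary$group <- sub("[0-9]+$", "", summary$subject)
  anovas <- list()
  ok <- !summary$incomplete
  if (length(unique(summary$condition[ok])) > 1 &&
      length(unique(summary$group[ok])) > 1) {
    for (dv in c("dprime", "rt_mean")) {
      at <- mixed_rm_anova(summary[ok, ], dv = dv, subject = "subject",
                           between = "group", within = "condition")
      at$dv <- dv
      anovas[[dv]] <- at
    }
  }
  list(summary = summary,
       anova = if (length(anovas)) do.call(rbind, anovas) else NULL)
}

#' Gait stage: kinematics for all walking blocks of a study
#'
#' @param blocks block table from [study_blocks()].
#' @param config pipeline config.
#' @return list with `summary` (block/condition tables) and `anova`
#'   (2 x 2 flow x task mixed ANOVAs per metric), or NULL without markers.
#' @export
stage_gait <- function(blocks, config) {
  gb <- blocks[!is.na(blocks$markers), ]
  if (!nrow(gb)) return(NULL)
  per_block <- data.frame(subject = gb$subject, condition = gb$condition,
                          block = gb$block, group = gb$group)
  per_block$events <- lapply(seq_len(nrow(gb)), function(i)
    gait_events(read_markers(gb$markers[i]), config))
  gs <- summarize_gait(per_block)
  gs$conditions$group <- sub("[0-9]+$", "", gs$conditions$subject)
  ## 2 x 2 flow x task ANOVA (+ group) on the walking conditions
  walk <- gs$conditions[gs$conditions$condition %in% walking_conditions(), ]
  walk$flow <- vapply(walk$condition,
                      function(cc) parse_condition(cc)$sensory, "")
  walk$task <- vapply(walk$condition,
                      function(cc) parse_condition(cc)$cognitive, "")
  anovas <- NULL
  complete <- all(table(walk$subject) == 4) && nrow(walk) > 0 &&
    length(unique(walk$group)) > 1
  if (complete) {
    metrics <- c("stride_time_mean", "stride_time_cv", "stride_length_mean",
                 "stride_length_cv", "step_width_mean", "step_width_cv")
    anovas <- do.call(rbind, lapply(metrics, function(mtr) {
      at <- mixed_rm_anova(walk, dv = mtr, subject = "subject",
                           between = "group", within = c("flow", "task"))
      at$dv <- mtr
      at
    }))
  }
  list(summary = gs, anova = anovas)
}

#' ERP stage: preprocess, epoch, average, and measure peaks
#'
#' @param blocks block table from [study_blocks()].
#' @param rate EEG sampling rate.
#' @param config pipeline config.
#' @param layout electrode layout.
#' @return list with subject averages, grand averages, two-pass windows,
#'   per-subject peak measures, ANOVA tables, and difference waves.
#' @export
stage_erp <- function(blocks, rate, config, layout = electrode_layout()) {
  task_blocks <- blocks[blocks$condition %in% task_conditions(), ]
  if (!nrow(task_blocks)) return(NULL)
  subject_avgs <- NULL
  warnings <- character()
  for (s in unique(task_blocks$subject)) {
    sb <- task_blocks[task_blocks$subject == s, ]
    ep_list <- list()
    for (i in seq_len(nrow(sb))) {
      rec <- read_eeg(sb$eeg[i])
      rec <- bandpass(rec, config$filter$low, config$filter$high)
      rec <- average_reference(rec)
      fix <- detect_and_interpolate_bad(rec, layout)
      if (length(fix$bad))
        warnings <- c(warnings, sprintf("%s: interpolated %s", sb$eeg[i],
                                        paste(fix$bad, collapse = ",")))
      rec <- fix$recording
      tr <- classify_block(sb$events[i], rate)
      stim_ev <- rec$events[rec$events$code %in% c(EVENT_GO, EVENT_NOGO), ]
      if (nrow(stim_ev) != nrow(tr))
        stopf("%s: %d stimulus triggers but %d trials in events TSV",
              sb$eeg[i], nrow(stim_ev), nrow(tr))
      stim_ev$response_type <- tr$outcome
      stim_ev$condition <- sb$condition[i]
      eps <- epoch(rec, stim_ev, config$epoch$window,
                   if (config$epoch$baseline_correct) config$epoch$baseline
                   else NULL)
      keep <- which(eps$trials$response_type %in% c("Hit", "CR"))
      eps$data <- eps$data[keep, , , drop = FALSE]
      eps$trials <- eps$trials[keep, , drop = FALSE]
      ep_list[[i]] <- eps
    }
    ## merge the subject's blocks and average per condition x response type
    all_data <- do.call(abind3, lapply(ep_list, function(e) e$data))
    md <- do.call(rbind, lapply(ep_list, function(e)
      e$trials[, c("condition", "response_type")]))
    merged <- structure(list(data = all_data, time = ep_list[[1]]$time,
                             rate = rate, channels = ep_list[[1]]$channels,
                             trials = md), class = "mobi_epochs")
    av <- average_epochs(merged, c("condition", "response_type"))
    av$subject <- s
    av$group <- sb$group[1]
    tm <- attr(av, "time")
    subject_avgs <- if (is.null(subject_avgs)) av else rbind(subject_avgs, av)
    attr(subject_avgs, "time") <- tm
  }
  time <- attr(subject_avgs, "time")

  ## grand averages and the two-pass group windows
  ga <- grand_average(subject_avgs, c("group", "condition", "response_type"))
  attr(ga, "time") <- time
  group_collapsed <- lapply(split(seq_len(nrow(subject_avgs)),
                                  subject_avgs$group), function(idx)
    Reduce(`+`, subject_avgs$wave[idx]) / length(idx))
  windows <- two_pass_peak_windows(group_collapsed, time, config$peaks)

  ## per-subject peak measures in the group-specific windows
  measures <- do.call(rbind, lapply(seq_len(nrow(subject_avgs)), function(i) {
    g <- subject_avgs$group[i]
    do.call(rbind, lapply(names(config$peaks), function(comp) {
      w <- windows[windows$group == g & windows$component == comp, ]
      pk <- find_peak(subject_avgs$wave[[i]], time, w$electrode,
                      c(w$low, w$high), w$polarity)
      data.frame(subject = subject_avgs$subject[i], group = g,
                 condition = subject_avgs$condition[i],
                 response_type = subject_avgs$response_type[i],
                 component = comp, electrode = w$electrode,
                 amplitude = pk$amplitude, latency = pk$latency,
                 edge = pk$edge)
    }))
  }))

  ## 3 (condition) x 2 (response type) x group ANOVAs per component/measure
  anovas <- NULL
  n_cond <- length(unique(measures$condition))
  if (n_cond > 1 && length(unique(measures$group)) > 1) {
    anovas <- do.call(rbind, lapply(names(config$peaks), function(comp) {
      do.call(rbind, lapply(c("amplitude", "latency"), function(dv) {
        sub <- measures[measures$component == comp, ]
        at <- mixed_rm_anova(sub, dv = dv, subject = "subject",
                             between = "group",
                             within = c("condition", "response_type"))
        at$dv <- paste(comp, dv, sep = "_")
        at
      }))
    }))
  }

  ## difference waves (CR - Hit) and their topographic segments
  dw <- list()
  for (i in seq_len(nrow(ga))) {
    if (ga$response_type[i] != "CR") next
    j <- which(ga$group == ga$group[i] & ga$condition == ga$condition[i] &
               ga$response_type == "Hit")
    if (length(j) == 1L)
      dw[[paste(ga$group[i], ga$condition[i], sep = "_")]] <-
        difference_wave(ga$wave[[i]], ga$wave[[j]])
  }
  list(subject_avgs = subject_avgs, grand_avgs = ga, windows = windows,
       measures = measures, anova = anovas, diff_waves = dw, time = time,
       warnings = warnings)
}

abind3 <- function(...) {
  mats <- list(...)
  mats <- mats[vapply(mats, function(m) dim(m)[1] > 0, TRUE)]
  d <- dim(mats[[1]])
  out <- array(0, dim = c(sum(vapply(mats, function(m) dim(m)[1], 0L)),
                          d[2], d[3]))
  at <- 0L
  for (m in mats) {
    n <- dim(m)[1]
    if (n) out[at + seq_len(n), , ] <- m
    at <- at + n
  }
  out
}

#' Run the full pipeline on a study directory
#'
#' Orchestrates behavior scoring, gait analysis, ERP extraction, and the
#' cluster/ANOVA statistics on a study laid out as by [build_scenario()],
#' writing tidy CSVs, cluster-map matrices, and a run manifest under
#' `out_dir`. Stages fail independently: an error in one stage is logged in
#' the manifest and the others still produce output.
#'
#' @param study_dir study root (contains `manifest.json` and `subjects/`).
#' @param config [default_config()] or a loaded config.
#' @param out_dir results directory.
#' @return invisibly, a list with each stage's in-memory results.
#' @export
run_all <- function(study_dir, config = default_config(),
                    out_dir = file.path(study_dir, "results")) {
  blocks <- block_table(study_dir)
  man <- read_manifest(study_dir)
  rate <- man$rate
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_log <- list()
  results <- list()
  tables <- list()

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      message(sprintf("stage %s failed: %s", name, conditionMessage(e)))
      structure(list(error = conditionMessage(e)), class = "stage_error")
    })
    stage_log[[name]] <<- if (inherits(res, "stage_error"))
      list(status = "failed", error = res$error) else list(status = "ok")
    if (!inherits(res, "stage_error")) results[[name]] <<- res
    invisible(NULL)
  }

  run_stage("behavior", function() stage_behavior(blocks, rate))
  run_stage("gait", function() stage_gait(blocks, config))
  if (identical(stage_log$gait$status, "ok") && is.null(results$gait)) {
    message("gait stage skipped: no walking blocks with markers")
    stage_log$gait <- list(status = "skipped",
                           reason = "no walking blocks with markers")
  }
  run_stage("erp", function() stage_erp(blocks, rate, config))
  run_stage("stats", function() {
    if (is.null(results$erp)) stopf("no ERP subject averages available")
    cluster_contrast_suite(results$erp$subject_avgs,
                           config$cluster$alpha, config$cluster$min_run)
  })

  if (!is.null(results$behavior)) {
    tables$behavior <- results$behavior$summary
    if (!is.null(results$behavior$anova))
      tables$behavior_anova <- results$behavior$anova
  }
  if (!is.null(results$gait)) {
    tables$gait <- results$gait$summary$conditions
    tables$gait_blocks <- results$gait$summary$blocks
    if (!is.null(results$gait$anova)) tables$gait_anova <- results$gait$anova
  }
  if (!is.null(results$erp)) {
    tables$erp_measures <- results$erp$measures
    tables$erp_windows <- results$erp$windows
    if (!is.null(results$erp$anova)) tables$erp_anova <- results$erp$anova
  }
  manifest <- write_results(tables, out_dir, config, seed = man$seed,
                            warnings = unlist(lapply(results, function(r)
                              r$warnings %||% character())))

  if (!is.null(results$stats)) {
    cdir <- file.path(out_dir, "cluster_maps")
    dir.create(cdir, showWarnings = FALSE)
    for (nm in names(results$stats)) {
      cm <- results$stats[[nm]]
      utils::write.csv(cm$t, file.path(cdir, paste0(nm, "_t.csv")))
      utils::write.csv(cm$mask * 1L, file.path(cdir, paste0(nm, "_mask.csv")))
    }
  }
  jsonlite::write_json(list(stages = stage_log),
                       file.path(out_dir, "stages.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Summary grid of corrected p-values per effect
#'
#' Reads a results directory written by [run_all()] and assembles the
#' effect-grid summary: one row per dependent variable, one column per
#' ANOVA effect, entries the Greenhouse-Geisser-corrected p-values (blank
#' when the effect was not estimable).
#'
#' @param results_dir directory written by [run_all()].
#' @param alpha significance threshold for marking entries.
#' @return data.frame grid (also printed).
#' @export
report_summary <- function(results_dir, alpha = 0.05) {
  anova_files <- file.path(results_dir,
                           c("behavior_anova.csv", "gait_anova.csv",
                             "erp_anova.csv"))
  anova_files <- anova_files[file.exists(anova_files)]
  if (!length(anova_files)) stopf("no results found in %s", results_dir)
  at <- do.call(rbind, lapply(anova_files, utils::read.csv))
  at$p_report <- ifelse(is.na(at$p_gg), at$p_uncorrected, at$p_gg)
  grid <- stats::reshape(at[, c("dv", "effect", "p_report")],
                         idvar = "dv", timevar = "effect",
                         direction = "wide")
  names(grid) <- sub("^p_report\\.", "", names(grid))
  rownames(grid) <- NULL
  print(grid, digits = 3)
  invisible(grid)
}
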