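## zero-phase moving-average smoother (odd window, edges padded by
## replication); used to stabilize extremum detection on noisy traces
smooth_ma <- function(x, win) {
  win <- max(1L, as.integer(win))
  if (win %% 2L == 0L) win <- win + 1L
  if (win <= 1L) return(x)
  half <- (win - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / win, win), sides = 2))[
    (half + 1L):(half + length(x))]
}

## topographic prominence of a local maximum: height above the higher of
## the two valley floors separating it from higher terrain (or the trace
## edge)
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    left <- x[seq_len(p)]
    higher_l <- which(left > x[p])
    lo_l <- min(left[(if (length(higher_l)) max(higher_l) else 1):p])
    right <- x[p:length(x)]
    higher_r <- which(right > x[p])
    lo_r <- min(right[1:(if (length(higher_r)) min(higher_r) else length(right))])
    x[p] - max(lo_l, lo_r)
  }, 0)
}

## local maxima (strict rise before, fall after; plateaus take their first
## sample), filtered by prominence then by minimum separation, keeping the
## higher peak on conflicts
find_peaks <- function(x, min_dist = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer())
  d <- diff(x)
  ## collapse plateaus: sign of change, carrying the last nonzero backwards
  s <- sign(d)
  for (i in seq_len(n - 1L)[-1L]) if (s[i] == 0) s[i] <- s[i - 1L]
  cand <- which(s[-length(s)] > 0 & s[-1L] < 0) + 1L
  if (!length(cand)) return(integer())
  prom <- peak_prominence(x, cand)
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer())
  ## greedy: accept by descending height, enforce min distance
  ord <- cand[order(-x[cand], cand)]
  kept <- integer()
  for (p in ord)
    if (!length(kept) || all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
  sort(kept)
}

#' Detect heel strikes from an anterior-posterior heel trace
#'
#' Heel strikes are the local maxima of the AP (z) trace — the most anterior
#' heel positions — separated by at least `min_stride_time` and with
#' topographic prominence of at least `min_prominence`. An optional
#' zero-phase moving-average smoothing (default on) stabilizes detection on
#' noisy traces; event times are reported at sample resolution on the raw
#' time grid.
#'
#' @param z_trace AP positions in mm.
#' @param rate sampling rate in Hz.
#' @param min_stride_time minimum strike separation in ms.
#' @param min_prominence minimum peak prominence in mm.
#' @param smooth apply smoothing before detection.
#' @param smooth_ms smoothing window in ms.
#' @return strike times in ms (0-based sample times).
#' @export
detect_heel_strikes <- function(z_trace, rate, min_stride_time = 600,
                                min_prominence = 20, smooth = TRUE,
                                smooth_ms = 50) {
  if (length(z_trace) < 2 * min_stride_time / 1000 * rate)
    stopf("trace too short: need at least 2 stride times of data")
  x <- if (smooth) smooth_ma(z_trace, round(smooth_ms / 1000 * rate)) else z_trace
  peaks <- find_peaks(x, min_dist = min_stride_time / 1000 * rate,
                      min_prominence = min_prominence)
  if (length(peaks) < 2L)
    stopf("insufficient gait: fewer than 2 heel strikes detected")
  (peaks - 1L) / rate * 1000
}

#' Detect heel lifts between consecutive heel strikes
#'
#' The heel lift of a stride is the most posterior (minimum z) sample
#' strictly between its two bounding heel strikes; ties take the earliest
#' sample.
#'
#' @param z_trace AP positions in mm.
#' @param strikes strike times in ms from [detect_heel_strikes()].
#' @param rate sampling rate in Hz.
#' @return lift times in ms, one per inter-strike interval.
#' @export
detect_heel_lifts <- function(z_trace, strikes, rate) {
  if (length(strikes) < 2L) stopf("need at least 2 strikes")
  idx <- round(strikes / 1000 * rate) + 1L
  vapply(seq_len(length(idx) - 1L), function(k) {
    span <- (idx[k] + 1L):(idx[k + 1L] - 1L)
    (span[which.min(z_trace[span])] - 1L) / rate * 1000
  }, 0)
}

#' Per-stride times and lengths
#'
#' Stride time is the interval between consecutive heel strikes of the same
#' foot; stride length is the AP distance from a heel lift to the next heel
#' strike. Strides with negative computed length are excluded with a
#' warning.
#'
#' @param z_trace AP positions in mm.
#' @param strikes,lifts event times in ms from the two detectors.
#' @param rate sampling rate in Hz.
#' @return data.frame with `stride_time` (ms) and `stride_length` (mm), one
#'   row per stride.
#' @export
stride_metrics <- function(z_trace, strikes, lifts, rate) {
  n <- length(strikes) - 1L
  if (length(lifts) != n)
    stopf("expected %d lifts for %d strikes", n, n + 1L)
  z_at <- function(t) z_trace[round(t / 1000 * rate) + 1L]
  st <- diff(strikes)
  sl <- z_at(strikes[-1L]) - z_at(lifts)
  bad <- sl < 0
  if (any(bad)) {
    warnf("excluding %d stride(s) with negative length", sum(bad))
    st <- st[!bad]; sl <- sl[!bad]
  }
  data.frame(stride_time = st, stride_length = sl)
}

#' Step widths at right heel strikes
#'
#' The lateral (x) distance between the two heel markers at each right heel
#' strike, as an absolute value.
#'
#' @param x_left,x_right lateral heel traces in mm.
#' @param right_strikes right-foot strike times in ms.
#' @param rate sampling rate in Hz.
#' @return widths in mm, one per right strike.
#' @export
step_widths <- function(x_left, x_right, right_strikes, rate) {
  idx <- round(right_strikes / 1000 * rate) + 1L
  if (any(idx < 1L) || any(idx > length(x_left)) || any(idx > length(x_right)))
    stopf("strike time outside trace coverage")
  abs(x_left[idx] - x_right[idx])
}

#' Gait events and metrics for one marker stream
#'
#' Runs strike/lift detection on both heels and assembles the per-stride
#' metrics (right foot) and per-right-strike step widths.
#'
#' @param ms [new_marker_stream()] with left_heel and right_heel.
#' @param config pipeline config (gait section).
#' @return list with per-foot event times and data.frames of stride metrics
#'   and widths, of class `gait_events`.
#' @export
gait_events <- function(ms, config = default_config()) {
  require_heel_markers(ms)
  g <- config$gait
  det <- function(z) detect_heel_strikes(z, ms$rate, g$min_stride_time,
                                         g$min_prominence, g$smooth,
                                         g$smooth_ms)
  z_r <- ms$markers$right_heel[, "z"]
  z_l <- ms$markers$left_heel[, "z"]
  r_strikes <- det(z_r)
  l_strikes <- det(z_l)
  r_lifts <- detect_heel_lifts(z_r, r_strikes, ms$rate)
  l_lifts <- detect_heel_lifts(z_l, l_strikes, ms$rate)
  structure(list(
    right = list(strikes = r_strikes, lifts = r_lifts),
    left = list(strikes = l_strikes, lifts = l_lifts),
    strides = stride_metrics(z_r, r_strikes, r_lifts, ms$rate),
    widths = step_widths(ms$markers$left_heel[, "x"],
                         ms$markers$right_heel[, "x"], r_strikes, ms$rate)),
    class = "gait_events")
}

#' Block-level gait summary and per-condition means
#'
#' For each subject x block: means and CV% (sample SD) of stride time,
#' stride length, and step width — the study's six gait dependent
#' variables. Condition values are unweighted means over the condition's
#' blocks. Blocks with fewer than 5 strides are flagged, and a QC column
#' counts strides farther than 3 MAD from the block median stride time (a
#' reproducible surrogate for visual confirmation of detected peaks).
#'
#' @param per_block data.frame with columns subject, condition, block and
#'   list-column `events` of `gait_events` objects.
#' @return list with `blocks` (per-block summaries) and `conditions`
#'   (per-subject x condition means over blocks).
#' @export
summarize_gait <- function(per_block) {
  rows <- lapply(seq_len(nrow(per_block)), function(i) {
    ev <- per_block$events[[i]]
    st <- ev$strides$stride_time
    sl <- ev$strides$stride_length
    sw <- ev$widths
    data.frame(
      subject = per_block$subject[i], condition = per_block$condition[i],
      block = per_block$block[i], n_strides = length(st),
      flagged_short = length(st) < 5L,
      n_outlier_strides = sum(abs(st - stats::median(st)) >
                                3 * stats::mad(st) + 1e-12),
      stride_time_mean = mean(st), stride_time_cv = cv_percent(st),
      stride_length_mean = mean(sl), stride_length_cv = cv_percent(sl),
      step_width_mean = mean(sw), step_width_cv = cv_percent(sw))
  })
  blocks <- do.call(rbind, rows)
  metrics <- c("stride_time_mean", "stride_time_cv", "stride_length_mean",
               "stride_length_cv", "step_width_mean", "step_width_cv")
  agg <- stats::aggregate(blocks[metrics],
                          by = blocks[c("subject", "condition")], mean)
  list(blocks = blocks, conditions = agg)
}
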