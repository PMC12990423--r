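#' Average epochs within metadata cells
#'
#' Collapses an epoch set to one waveform (channels x time matrix) per
#' combination of the given trial-metadata columns — typically per response
#' type, or per condition x response type for one subject.
#'
#' @param epochs `mobi_epochs` object.
#' @param by character vector of columns of `epochs$trials` to group by.
#' @return data.frame with the grouping columns, `n_trials`, and a
#'   list-column `wave` of channels x time matrices.
#' @export
average_epochs <- function(epochs, by) {
  md <- epochs$trials
  stopifnot(all(by %in% names(md)))
  key <- interaction(md[by], drop = TRUE)
  cells <- unique(md[by])
  cell_key <- interaction(cells, drop = TRUE)
  waves <- lapply(seq_len(nrow(cells)), function(i) {
    idx <- which(key == cell_key[i])
    w <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
    rownames(w) <- epochs$channels
    w
  })
  out <- cells
  out$n_trials <- as.integer(table(key)[as.character(cell_key)])
  out$wave <- waves
  attr(out, "time") <- epochs$time
  attr(out, "channels") <- epochs$channels
  out
}

#' Grand average across subjects
#'
#' Averages subject-level waveforms within cells: subjects are averaged
#' first (by [average_epochs()]), then the grand average is the unweighted
#' mean over subjects, so subjects with more trials do not dominate. Both
#' the subject count and the summed trial count are recorded.
#'
#' @param subject_avgs data.frame of subject-level averages: grouping
#'   columns, a `subject` column, `n_trials`, and list-column `wave`.
#' @param by grouping columns defining the grand-average cells (e.g.
#'   `c("group", "condition", "response_type")`).
#' @return data.frame with the grouping columns, `n_subjects`, `n_trials`,
#'   and list-column `wave`.
#' @export
grand_average <- function(subject_avgs, by) {
  key <- interaction(subject_avgs[by], drop = TRUE)
  cells <- unique(subject_avgs[by])
  cell_key <- interaction(cells, drop = TRUE)
  waves <- list(); ns <- integer(); nt <- integer()
  for (i in seq_len(nrow(cells))) {
    idx <- which(key == cell_key[i])
    waves[[i]] <- Reduce(`+`, subject_avgs$wave[idx]) / length(idx)
    ns[i] <- length(idx)
    nt[i] <- sum(subject_avgs$n_trials[idx])
  }
  out <- cells
  out$n_subjects <- ns
  out$n_trials <- nt
  out$wave <- waves
  attr(out, "time") <- attr(subject_avgs, "time")
  out
}

#' Find a signed ERP peak in a latency window
#'
#' Returns the extremum of the chosen polarity (max for P2/P3, min for N2)
#' at one electrode within a window. Local extrema are preferred over
#' window edges: only when the window contains no local extremum is the
#' edge value returned, flagged with `edge = TRUE`. Latency ties break to
#' the earliest sample.
#'
#' @param wave channels x time matrix (rownames = channel labels) or a
#'   single waveform vector.
#' @param time time axis in ms.
#' @param electrode channel label (ignored when `wave` is a vector).
#' @param window latency window in ms.
#' @param polarity +1 for positive components, -1 for negative.
#' @return list with `amplitude` (signed, microvolts), `latency` (ms),
#'   `electrode`, `window`, `polarity`, `edge`.
#' @export
find_peak <- function(wave, time, electrode = NULL, window, polarity = 1) {
  x <- if (is.matrix(wave)) {
    if (is.null(electrode) || !electrode %in% rownames(wave))
      stopf("electrode %s not found in waveform", electrode %||% "<null>")
    wave[electrode, ]
  } else as.numeric(wave)
  sel <- which(time >= window[1] & time <= window[2])
  if (length(sel) < 1L) stopf("window [%g, %g] outside epoch", window[1], window[2])
  y <- polarity * x[sel]
  ## strict local maxima in the window interior
  loc <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(loc)) {
    best <- loc[which.max(y[loc])]
    edge <- FALSE
  } else {
    best <- which.max(y)
    edge <- TRUE
  }
  list(amplitude = x[sel[best]], latency = time[sel[best]],
       electrode = electrode, window = window, polarity = polarity,
       edge = edge)
}

#' Group-specific peak windows (two-pass procedure)
#'
#' First pass: each group's average peak latency per component is measured
#' on the group grand average (collapsed over conditions and response
#' types) at the component's electrode inside its canonical window (P2 FCz
#' 200-280 ms, N2 FCz 280-380 ms, P3 CPz 350-500 ms). Second pass windows
#' are that latency +/- 25 ms for P2/N2 and +/- 50 ms for P3, intersected
#' with the epoch.
#'
#' @param group_waves named list of channels x time matrices, one per
#'   group (each the group's grand average collapsed over cells).
#' @param time time axis in ms.
#' @param peaks canonical peak table (see [default_config()]`$peaks`).
#' @return data.frame with group, component, electrode, polarity,
#'   center latency, window low/high (ms).
#' @export
two_pass_peak_windows <- function(group_waves, time,
                                  peaks = default_config()$peaks) {
  rows <- list()
  for (g in names(group_waves)) {
    for (comp in names(peaks)) {
      p <- peaks[[comp]]
      x <- group_waves[[g]][p$electrode, ]
      sel <- time >= p$window[1] & time <= p$window[2]
      if (diff(range(x[sel])) < 1e-12)
        stopf("flat grand average for %s in group %s: no identifiable peak",
              comp, g)
      pk <- find_peak(group_waves[[g]], time, p$electrode, p$window,
                      p$polarity)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, component = comp, electrode = p$electrode,
        polarity = p$polarity, center = pk$latency,
        low = max(pk$latency - p$half_width, min(time)),
        high = min(pk$latency + p$half_width, max(time)))
    }
  }
  do.call(rbind, rows)
}

#' Difference wave: correct rejections minus hits
#'
#' Isolates inhibition-related activity by subtracting the Hit grand
#' average from the CR grand average; antisymmetric under swapping inputs.
#'
#' @param cr_avg,hit_avg channels x time matrices of matching shape.
#' @return channels x time difference matrix.
#' @export
difference_wave <- function(cr_avg, hit_avg) {
  if (!all(dim(cr_avg) == dim(hit_avg)))
    stopf("CR and Hit averages must have matching shapes")
  cr_avg - hit_avg
}

#' Topographic segment means
#'
#' Per-channel time-means over consecutive bins (default ten 50 ms segments
#' from 100 to 600 ms), the quantities mapped in difference topographies.
#'
#' @param wave channels x time matrix.
#' @param time time axis in ms.
#' @param span overall span in ms.
#' @param bin bin width in ms.
#' @return channels x bins matrix; column names give the bin edges.
#' @export
topo_segments <- function(wave, time, span = c(100, 600), bin = 50) {
  edges <- seq(span[1], span[2], by = bin)
  n_bin <- length(edges) - 1L
  out <- matrix(0, nrow = nrow(wave), ncol = n_bin,
                dimnames = list(rownames(wave),
                                sprintf("%g-%g", edges[-length(edges)],
                                        edges[-1])))
  for (b in seq_len(n_bin)) {
    sel <- time >= edges[b] & time < edges[b + 1L]
    out[, b] <- rowMeans(wave[, sel, drop = FALSE])
  }
  out
}
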