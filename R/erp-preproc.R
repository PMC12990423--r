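#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering: a 2nd-order
#' high-pass at `low` Hz cascaded with a 4th-order low-pass at `high` Hz,
#' each applied with `signal::filtfilt` so the pass band keeps zero phase
#' shift and DC is rejected. Defaults are the study band, 0.25-40 Hz.
#'
#' @param rec [new_recording()].
#' @param low high-pass edge in Hz.
#' @param high low-pass edge in Hz.
#' @return filtered recording.
#' @export
bandpass <- function(rec, low = 0.25, high = 40) {
  if (low <= 0 || high <= low) stopf("need 0 < low < high")
  if (rec$rate <= 2 * high)
    stopf("rate %g too low for a %g Hz low-pass", rec$rate, high)
  hp <- signal::butter(2, low / (rec$rate / 2), type = "high")
  lp <- signal::butter(4, high / (rec$rate / 2), type = "low")
  out <- rec
  ## remove the channel mean first: the high-pass settles much faster and a
  ## constant input maps to exactly zero
  for (i in seq_len(nrow(rec$samples))) {
    x <- rec$samples[i, ] - mean(rec$samples[i, ])
    x <- signal::filtfilt(hp, x)
    out$samples[i, ] <- signal::filtfilt(lp, x)
  }
  out
}

#' Re-reference to the channel average
#'
#' Subtracts the per-sample mean across channels, so every column of the
#' voltage matrix has zero mean afterwards. Idempotent.
#'
#' @param rec [new_recording()] with at least 2 channels.
#' @return re-referenced recording.
#' @export
average_reference <- function(rec) {
  if (nrow(rec$samples) < 2L)
    stopf("average reference needs at least 2 channels")
  rec$samples <- sweep(rec$samples, 2, colMeans(rec$samples))
  rec
}

## Legendre polynomials P_1..P_L evaluated at x (vector); rows = degree
legendre_upto <- function(L, x) {
  P <- matrix(0, nrow = L, ncol = length(x))
  P[1, ] <- x
  if (L >= 2) P[2, ] <- (3 * x^2 - 1) / 2
  if (L >= 3) for (n in 2:(L - 1))
    P[n + 1, ] <- ((2 * n + 1) * x * P[n, ] - n * P[n - 1, ]) / (n + 1)
  P
}

## Perrin-style spherical-spline kernel g(cos angle) of order m, degree <= L
spline_g <- function(cosang, m = 4, L = 7) {
  n <- seq_len(L)
  coef <- (2 * n + 1) / (n^m * (n + 1)^m)
  P <- legendre_upto(L, cosang)
  as.numeric(coef %*% P) / (4 * pi)
}

## interpolate bad channels from good ones by spherical splines
spline_interpolate <- function(samples, pos, bad, m = 4, L = 7, reg = 1e-5) {
  good <- setdiff(seq_len(nrow(samples)), bad)
  Pg <- pos[good, , drop = FALSE]
  G <- spline_g(pmin(1, pmax(-1, tcrossprod(Pg))), m, L)
  A <- rbind(cbind(G + diag(reg, length(good)), 1), c(rep(1, length(good)), 0))
  Gb <- spline_g(pmin(1, pmax(-1, pos[bad, , drop = FALSE] %*% t(Pg))), m, L)
  Gb <- matrix(Gb, nrow = length(bad))
  rhs <- rbind(samples[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)                       # spline weights + constant
  samples[bad, ] <- Gb %*% sol[seq_along(good), , drop = FALSE] +
    matrix(sol[length(good) + 1L, ], nrow = length(bad),
           ncol = ncol(samples), byrow = TRUE)
  samples
}

#' Detect and spherically interpolate bad channels
#'
#' Channels whose log-variance robust z-score (median/MAD across channels)
#' exceeds `z_thresh`, or that are flat, are replaced by Perrin-style
#' spherical-spline interpolation (order m = 4, Legendre series up to
#' degree 7, regularization 1e-5) from the remaining channels. Errors if
#' more than a quarter of the channels are bad.
#'
#' @param rec [new_recording()].
#' @param layout electrode layout covering all channels.
#' @param z_thresh robust z threshold on log-variance.
#' @return list with the repaired `recording` and the `bad` channel labels.
#' @export
detect_and_interpolate_bad <- function(rec, layout = electrode_layout(),
                                       z_thresh = 3.5) {
  if (!all(rec$channel_labels %in% layout$label))
    stopf("layout does not cover channels: %s",
          paste(setdiff(rec$channel_labels, layout$label), collapse = ", "))
  v <- apply(rec$samples, 1, stats::var)
  flat <- v < 1e-12
  lv <- log(pmax(v, 1e-12))
  z <- (lv - stats::median(lv)) / max(stats::mad(lv), 1e-12)
  bad <- which(abs(z) > z_thresh | flat)
  if (length(bad) > 0.25 * nrow(rec$samples))
    stopf("%d of %d channels bad: recording fails the quality floor",
          length(bad), nrow(rec$samples))
  if (length(bad)) {
    pos <- layout_matrix(layout)[rec$channel_labels, , drop = FALSE]
    rec$samples <- spline_interpolate(rec$samples, pos, bad)
  }
  list(recording = rec, bad = rec$channel_labels[bad])
}

#' Epoch a recording around stimulus events
#'
#' Cuts stimulus-locked epochs spanning samples `onset - 51` to
#' `onset + 409` inclusive — 461 samples at 512 Hz, the -100..800 ms study
#' window — and subtracts each channel's mean over the baseline
#' (-100..0 ms) unless disabled. Events too close to the recording bounds
#' are dropped with a warning.
#'
#' @param rec [new_recording()].
#' @param events data.frame with 0-based `sample` indices (defaults to the
#'   recording's stimulus events, codes 1/2) and optional metadata columns
#'   carried into the epoch table.
#' @param window epoch window in ms relative to onset.
#' @param baseline baseline window in ms, or NULL to skip correction.
#' @return object of class `mobi_epochs`: list with `data` (trials x
#'   channels x time array), `time` (ms axis), `rate`, `channels`, and
#'   `trials` (metadata data.frame).
#' @export
epoch <- function(rec, events = NULL, window = c(-100, 800),
                  baseline = c(-100, 0)) {
  if (is.null(events)) {
    events <- rec$events[rec$events$code %in% c(EVENT_GO, EVENT_NOGO), ,
                         drop = FALSE]
  }
  pre <- round(-window[1] / 1000 * rec$rate)          # 51 at 512 Hz
  post <- round(window[2] / 1000 * rec$rate) - 1L     # 409 at 512 Hz
  len <- pre + post + 1L
  time <- (seq_len(len) - 1L - pre) / rec$rate * 1000
  ok <- events$sample - pre >= 0 & events$sample + post < n_samples(rec)
  if (any(!ok))
    warnf("dropping %d event(s) too close to recording bounds", sum(!ok))
  events <- events[ok, , drop = FALSE]
  n_ch <- nrow(rec$samples)
  data <- array(0, dim = c(nrow(events), n_ch, len))
  for (k in seq_len(nrow(events))) {
    span <- (events$sample[k] - pre + 1L):(events$sample[k] + post + 1L)
    seg <- rec$samples[, span, drop = FALSE]
    if (!is.null(baseline)) {
      bl <- time >= baseline[1] & time <= baseline[2]
      seg <- seg - rowMeans(seg[, bl, drop = FALSE])
    }
    data[k, , ] <- seg
  }
  structure(list(data = data, time = time, rate = rec$rate,
                 channels = rec$channel_labels,
                 trials = as.data.frame(events)),
            class = "mobi_epochs")
}

#' @export
print.mobi_epochs <- function(x, ...) {
  cat(sprintf("<mobi_epochs> %d trials x %d channels x %d samples (%.0f..%.0f ms)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$time), max(x$time)))
  invisible(x)
}
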