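#' ERP component specification
#'
#' A Gaussian-in-time, spatially smooth scalp component injected at each
#' stimulus onset: `amplitude * exp(-(t - latency)^2 / (2 sd^2))` scaled per
#' channel by `exp(-angular_distance^2 / (2 spread^2))` on the unit sphere
#' around the center electrode, and optionally rescaled per response
#' outcome (e.g. a larger P3 for correct rejections than for hits).
#'
#' @param name one of "P2", "N2", "P3".
#' @param peak_latency peak time in ms post-stimulus.
#' @param peak_amplitude signed peak amplitude in microvolts (N2 must be
#'   negative, P2/P3 positive).
#' @param temporal_sd Gaussian temporal width in ms.
#' @param center electrode label of the spatial center.
#' @param spread angular spatial spread in radians.
#' @param scale named numeric of per-outcome amplitude multipliers
#'   (names among Hit, Miss, FA, CR); outcomes not named scale by 1.
#' @return list of class `erp_component`.
#' @export
erp_component <- function(name = c("P2", "N2", "P3"), peak_latency,
                          peak_amplitude, temporal_sd = 30,
                          center = c(P2 = "FCz", N2 = "FCz", P3 = "CPz")[[name[1]]],
                          spread = 0.7, scale = c(Hit = 1, CR = 1)) {
  name <- match.arg(name)
  if (name == "N2" && peak_amplitude >= 0) stopf("N2 amplitude must be < 0")
  if (name != "N2" && peak_amplitude <= 0) stopf("%s amplitude must be > 0", name)
  structure(list(name = name, peak_latency = peak_latency,
                 peak_amplitude = peak_amplitude, temporal_sd = temporal_sd,
                 center = center, spread = spread, scale = scale),
            class = "erp_component")
}

## 1/f-shaped noise: white spectrum reweighted by f^(-slope/2), zero DC,
## rescaled to the requested RMS. Returns an n-vector.
pink_noise <- function(n, rms, slope = 1) {
  if (rms <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))             # avoid 0; symmetric magnitudes
  f <- pmin(f, n - f + 1)
  shape <- f^(-slope / 2)
  shape[1] <- 0                          # remove DC
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

trial_outcomes <- function(stream, responses) {
  pressed <- responses$pressed
  ifelse(stream$stim == "Go",
         ifelse(pressed, "Hit", "Miss"),
         ifelse(pressed, "FA", "CR"))
}

#' Simulate a stimulus-locked EEG recording
#'
#' Builds a continuous 64-channel recording at `rate` Hz covering the trial
#' stream. Each trial adds every component's spatio-temporal Gaussian bump,
#' scaled by the trial's outcome; the background is 1/f-shaped noise of the
#' given RMS per channel. Stimulus onsets (codes 1 = Go, 2 = NoGo) and
#' button presses (code 100) are written into the event table.
#'
#' @param stream trial stream from [generate_trial_stream()].
#' @param responses responses from [simulate_behavior()], or NULL for a
#'   no-response (no-task) block.
#' @param components list of [erp_component()] specs.
#' @param noise_rms background noise RMS in microvolts.
#' @param rate sampling rate in Hz (study: 512).
#' @param layout electrode layout data.frame from [electrode_layout()].
#' @param seed integer seed.
#' @param pad_ms silence appended after the last trial (covers the epoch).
#' @param epoch_window epoch coverage the components must fit inside (ms).
#' @return [new_recording()] with events.
#' @export
simulate_eeg <- function(stream, responses = NULL, components = list(),
                         noise_rms = 10, rate = 512,
                         layout = electrode_layout(), seed = 1,
                         pad_ms = 1000, epoch_window = c(-100, 800)) {
  for (comp in components) {
    if (comp$peak_latency < epoch_window[1] || comp$peak_latency > epoch_window[2])
      stopf("component %s latency %g ms is outside epoch coverage [%g, %g]",
            comp$name, comp$peak_latency, epoch_window[1], epoch_window[2])
  }
  n_ch <- nrow(layout)
  dur_ms <- max(stream$onset) + pad_ms
  n <- ceiling(dur_ms / 1000 * rate)
  t_ms <- (seq_len(n) - 1L) / rate * 1000

  outcome <- if (is.null(responses)) rep("none", nrow(stream))
             else trial_outcomes(stream, responses)

  data <- matrix(0, nrow = n_ch, ncol = n)
  if (noise_rms > 0) {
    with_seed(derive_seed(seed, "eeg_noise"), {
      for (i in seq_len(n_ch)) data[i, ] <- pink_noise(n, noise_rms)
    })
  }

  for (comp in components) {
    w <- exp(-angular_dist(layout, comp$center)^2 / (2 * comp$spread^2))
    bump_total <- numeric(n)
    ## temporal support of the bump: +/- 5 sd around each trial's peak
    for (k in seq_len(nrow(stream))) {
      sc <- comp$scale[outcome[k]]
      sc <- if (is.null(sc) || is.na(sc)) 1 else unname(sc)
      mu <- stream$onset[k] + comp$peak_latency
      i0 <- max(1L, floor((mu - 5 * comp$temporal_sd) / 1000 * rate))
      i1 <- min(n, ceiling((mu + 5 * comp$temporal_sd) / 1000 * rate))
      idx <- i0:i1
      bump_total[idx] <- bump_total[idx] +
        sc * exp(-(t_ms[idx] - mu)^2 / (2 * comp$temporal_sd^2))
    }
    data <- data + comp$peak_amplitude * outer(as.numeric(w), bump_total)
  }

  ev <- data.frame(
    sample = as.integer(round(stream$onset / 1000 * rate)),
    code = ifelse(stream$stim == "Go", EVENT_GO, EVENT_NOGO))
  if (!is.null(responses)) {
    pt <- responses$press_time[!is.na(responses$press_time)]
    ev <- rbind(ev, data.frame(sample = as.integer(round(pt / 1000 * rate)),
                               code = EVENT_PRESS))
  }
  ev <- ev[order(ev$sample), ]
  ev <- ev[ev$sample >= 0 & ev$sample < n, ]
  new_recording(data, rate = rate, channel_labels = layout$label, events = ev)
}
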