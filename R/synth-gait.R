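#' Treadmill gait parameters
#'
#' Means and coefficients of variation (CV%, SD/mean x 100) controlling the
#' synthetic gait generator. `stride_length_mean` is the anterior-posterior
#' heel-lift-to-next-heel-strike distance, realized as the posterior drift
#' at belt speed during stance, so `stride_length_mean / belt_speed` must be
#' comfortably shorter than the stride time.
#'
#' @param belt_speed treadmill belt speed in mm/s.
#' @param stride_time_mean,stride_time_cv stride duration, ms and CV%.
#' @param stride_length_mean,stride_length_cv AP lift-to-strike distance,
#'   mm and CV%.
#' @param step_width_mean,step_width_cv lateral heel separation at right
#'   heel strike, mm and CV%.
#' @return list of class `gait_params`.
#' @export
gait_params <- function(belt_speed = 845,
                        stride_time_mean = 1300, stride_time_cv = 3,
                        stride_length_mean = 660, stride_length_cv = 3,
                        step_width_mean = 200, step_width_cv = 9) {
  p <- list(belt_speed = belt_speed,
            stride_time_mean = stride_time_mean,
            stride_time_cv = stride_time_cv,
            stride_length_mean = stride_length_mean,
            stride_length_cv = stride_length_cv,
            step_width_mean = step_width_mean,
            step_width_cv = step_width_cv)
  if (any(unlist(p[c(1, 2, 4, 6)]) <= 0)) stopf("all means must be positive")
  if (any(unlist(p[c(3, 5, 7)]) < 0)) stopf("CVs must be >= 0")
  structure(p, class = "gait_params")
}

## jittered positive draws at a given mean/cv; errors out when the jitter is
## wide enough to produce non-positive values
jitter_pos <- function(n, mean, cv, what) {
  x <- stats::rnorm(n, mean, mean * cv / 100)
  if (any(x <= 0))
    stopf("%s CV %.1f%% produced non-positive values; reduce it", what, cv)
  x
}

## one foot's AP (z) trace: stance = linear posterior drift at belt speed
## from the strike position z0, swing = raised-cosine anterior return.
foot_z_trace <- function(t_ms, strikes, lengths, belt_speed, z0 = 0) {
  z <- rep(z0, length(t_ms))
  n_str <- length(strikes)
  stance <- lengths / belt_speed * 1000          # ms
  ## lead-in: partial swing rising into the first strike
  pre <- t_ms < strikes[1]
  if (any(pre)) {
    u <- (t_ms[pre] - t_ms[1]) / max(strikes[1] - t_ms[1], 1)
    z[pre] <- z0 - lengths[1] + lengths[1] * (1 - cos(pi * u)) / 2
  }
  for (k in seq_len(n_str)) {
    t0 <- strikes[k]
    t1 <- if (k < n_str) strikes[k + 1] else max(t_ms) + 1
    s_end <- min(t0 + stance[k], t1)
    in_stance <- t_ms >= t0 & t_ms < s_end
    z[in_stance] <- z0 - belt_speed * (t_ms[in_stance] - t0) / 1000
    if (k < n_str) {
      in_swing <- t_ms >= s_end & t_ms < t1
      if (any(in_swing)) {
        u <- (t_ms[in_swing] - s_end) / (t1 - s_end)
        z[in_swing] <- z0 - lengths[k] + lengths[k] * (1 - cos(pi * u)) / 2
      }
    } else {
      tail <- t_ms >= s_end
      z[tail] <- z0 - lengths[k]                 # rest at the lift position
    }
  }
  z
}

#' Simulate heel-marker trajectories on a treadmill
#'
#' Generates left/right heel traces at `rate` Hz whose gait events follow
#' the configured stride-time/length and step-width distributions: heel
#' strikes are the most anterior (z) excursions, heel lifts the most
#' posterior within each stride, feet are half a stride out of phase, and
#' the lateral (x) traces are laid out so the heel separation at each right
#' heel strike equals that strike's drawn step width. Ground-truth event
#' times and per-stride parameters are returned alongside the stream.
#'
#' @param params [gait_params()].
#' @param duration_s trace duration in seconds (must cover >= 5 strides).
#' @param rate sampling rate in Hz (study: 100).
#' @param seed integer seed.
#' @return list with `stream` ([new_marker_stream()]) and `truth` (list of
#'   per-foot strike/lift times in ms, per-stride times/lengths, and
#'   per-right-strike step widths).
#' @export
simulate_gait_markers <- function(params = gait_params(), duration_s,
                                  rate = 100, seed = 1) {
  stopifnot(inherits(params, "gait_params"))
  dur_ms <- duration_s * 1000
  if (dur_ms < 5 * params$stride_time_mean)
    stopf("duration must cover at least 5 strides")
  n_str <- ceiling(dur_ms / params$stride_time_mean) + 2L
  with_seed(derive_seed(seed, "gait"), {
    mk_foot <- function(first_strike) {
      times <- jitter_pos(n_str, params$stride_time_mean,
                          params$stride_time_cv, "stride time")
      lens <- jitter_pos(n_str, params$stride_length_mean,
                         params$stride_length_cv, "stride length")
      stance_ms <- lens / params$belt_speed * 1000
      if (any(stance_ms >= 0.95 * times))
        stopf("stride_length/belt_speed implies stance >= stride time")
      strikes <- first_strike + c(0, cumsum(times[-n_str]))
      keep <- strikes <= dur_ms - 100            # keep strikes clear of the edge
      list(strikes = strikes[keep], times = times[seq_len(sum(keep))],
           lengths = lens[seq_len(sum(keep))])
    }
    right <- mk_foot(600)
    left <- mk_foot(600 + params$stride_time_mean / 2)

    t_ms <- (seq_len(round(duration_s * rate)) - 1L) / rate * 1000
    z_r <- foot_z_trace(t_ms, right$strikes, right$lengths, params$belt_speed)
    z_l <- foot_z_trace(t_ms, left$strikes, left$lengths, params$belt_speed)

    widths <- jitter_pos(length(right$strikes), params$step_width_mean,
                         params$step_width_cv, "step width")
    w_t <- stats::approx(right$strikes, widths, xout = t_ms, rule = 2)$y
    x_r <- w_t / 2
    x_l <- -w_t / 2

    stream <- new_marker_stream(list(
      left_heel = cbind(x = x_l, y = rep(0, length(t_ms)), z = z_l),
      right_heel = cbind(x = x_r, y = rep(0, length(t_ms)), z = z_r)),
      rate = rate)

    truth <- list(
      right_strikes = right$strikes,
      left_strikes = left$strikes,
      right_lifts = right$strikes + right$lengths / params$belt_speed * 1000,
      left_lifts = left$strikes + left$lengths / params$belt_speed * 1000,
      stride_times = right$times[-length(right$times)],
      stride_lengths = right$lengths,
      step_widths = widths)
    list(stream = stream, truth = truth)
  })
}
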