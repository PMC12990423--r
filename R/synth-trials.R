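#' Behavioral response parameters
#'
#' @param hit_rate probability of pressing on a Go trial, in (0, 1].
#' @param fa_rate probability of pressing on a NoGo trial, in [0, 1).
#' @param rt_mean mean press latency (ms); latencies are log-normal.
#' @param rt_sd latency standard deviation (ms).
#' @return parameter list of class `behavior_params`.
#' @export
behavior_params <- function(hit_rate = 0.92, fa_rate = 0.17,
                            rt_mean = 400, rt_sd = 80) {
  if (hit_rate <= 0 || hit_rate > 1) stopf("hit_rate must be in (0, 1]")
  if (fa_rate < 0 || fa_rate >= 1) stopf("fa_rate must be in [0, 1)")
  if (hit_rate <= fa_rate)
    warnf("hit_rate <= fa_rate: d-prime fixtures will be at or below chance")
  if (rt_mean <= 0 || rt_sd <= 0) stopf("rt_mean and rt_sd must be positive")
  structure(list(hit_rate = hit_rate, fa_rate = fa_rate,
                 rt_mean = rt_mean, rt_sd = rt_sd),
            class = "behavior_params")
}

#' Generate a Go/NoGo trial stream
#'
#' Emulates one task block: `n_trials` stimuli of `stim_dur` ms separated by
#' uniform inter-stimulus intervals from `isi_range`. Under the default
#' exact-proportion sampler the NoGo trials are a random permutation of a
#' fixed multiset, so a 180-trial block at `p_nogo = 0.2` contains exactly
#' 36 NoGo trials; with `exact_proportion = FALSE` trial types are i.i.d.
#' Bernoulli.
#'
#' @param n_trials number of trials (study block: 180).
#' @param p_nogo NoGo proportion in [0, 1) (study: 0.2).
#' @param isi_range ISI bounds in ms (study: 200-400).
#' @param stim_dur stimulus duration in ms (study: 400).
#' @param seed integer seed.
#' @param exact_proportion use the exact-count sampler (default TRUE).
#' @param start_ms onset of the first stimulus (ms into the recording).
#' @return data.frame with columns `trial`, `onset` (ms), `stim`
#'   ("Go"/"NoGo"), `isi` (ms).
#' @export
generate_trial_stream <- function(n_trials, p_nogo = 0.2,
                                  isi_range = c(200, 400), stim_dur = 400,
                                  seed = 1, exact_proportion = TRUE,
                                  start_ms = 1000) {
  if (p_nogo < 0 || p_nogo >= 1) stopf("p_nogo must be in [0, 1)")
  if (n_trials < 1) stopf("n_trials must be >= 1")
  with_seed(seed, {
    if (exact_proportion) {
      n_nogo <- round(n_trials * p_nogo)
      stim <- sample(rep(c("NoGo", "Go"), c(n_nogo, n_trials - n_nogo)))
    } else {
      stim <- ifelse(stats::runif(n_trials) < p_nogo, "NoGo", "Go")
    }
    isi <- stats::runif(n_trials, isi_range[1], isi_range[2])
    onset <- start_ms + c(0, cumsum(stim_dur + isi[-n_trials]))
    data.frame(trial = seq_len(n_trials), onset = onset, stim = stim,
               isi = isi)
  })
}

#' Simulate button presses for a trial stream
#'
#' Go trials are pressed with probability `hit_rate` and NoGo trials with
#' probability `fa_rate`; press latencies are log-normal with the configured
#' mean/SD, clipped to 100-800 ms post-onset.
#'
#' @param stream trial stream from [generate_trial_stream()].
#' @param params [behavior_params()].
#' @param seed integer seed.
#' @return data.frame with columns `trial`, `pressed`, `press_time`
#'   (absolute ms, NA when not pressed), `latency` (ms post-onset).
#' @export
simulate_behavior <- function(stream, params = behavior_params(), seed = 1) {
  stopifnot(inherits(params, "behavior_params"))
  n <- nrow(stream)
  with_seed(seed, {
    p <- ifelse(stream$stim == "Go", params$hit_rate, params$fa_rate)
    pressed <- stats::runif(n) < p
    sdlog <- sqrt(log(1 + (params$rt_sd / params$rt_mean)^2))
    meanlog <- log(params$rt_mean) - sdlog^2 / 2
    lat <- stats::rlnorm(n, meanlog, sdlog)
    lat <- pmin(pmax(lat, 100), 800)
    lat[!pressed] <- NA_real_
    data.frame(trial = stream$trial, pressed = pressed,
               press_time = stream$onset + lat, latency = lat)
  })
}
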