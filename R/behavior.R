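#' Classify Go/NoGo trials into Hit / Miss / FA / CR
#'
#' A press falling inside `valid_window` ms after a Go onset makes that
#' trial a Hit (the first such press counts); a Go trial without a valid
#' press is a Miss; a NoGo trial with a valid press is a False Alarm, and
#' without one a Correct Rejection. Presses earlier than the window start
#' are anticipatory: they are flagged invalid and attributed to no trial.
#' Each press is assigned to the most recent onset.
#'
#' @param stream trial stream (data.frame with `trial`, `onset`, `stim`,
#'   optionally `condition`).
#' @param responses either a numeric vector of absolute press times (ms) or
#'   a data.frame from [simulate_behavior()] (its non-NA `press_time`s are
#'   used).
#' @param valid_window response-validity window in ms post-onset.
#' @return data.frame of trial records: `trial`, `onset`, `stim`,
#'   `response_latency` (ms, NA if none), `outcome`; attribute
#'   `n_invalid_presses` counts anticipatory presses.
#' @export
classify_trials <- function(stream, responses, valid_window = c(100, 800)) {
  presses <- if (is.data.frame(responses)) {
    responses$press_time[!is.na(responses$press_time)]
  } else as.numeric(responses[!is.na(responses)])
  presses <- sort(presses)
  if (is.unsorted(stream$onset, strictly = TRUE))
    stopf("trial onsets must be strictly increasing")
  gaps <- diff(stream$onset)
  if (length(gaps) && any(gaps <= 0))
    stopf("malformed stream: overlapping trials")

  n <- nrow(stream)
  latency <- rep(NA_real_, n)
  n_invalid <- 0L
  for (p in presses) {
    k <- findInterval(p, stream$onset)   # most recent onset at or before p
    if (k < 1L) { n_invalid <- n_invalid + 1L; next }
    lat <- p - stream$onset[k]
    if (lat < valid_window[1]) { n_invalid <- n_invalid + 1L; next }
    if (lat > valid_window[2]) next       # late press: attributed to no trial
    if (is.na(latency[k])) latency[k] <- lat    # first valid press wins
  }
  outcome <- ifelse(stream$stim == "Go",
                    ifelse(is.na(latency), "Miss", "Hit"),
                    ifelse(is.na(latency), "CR", "FA"))
  out <- data.frame(trial = stream$trial, onset = stream$onset,
                    stim = stream$stim, response_latency = latency,
                    outcome = outcome)
  if (!is.null(stream$condition)) out$condition <- stream$condition
  attr(out, "n_invalid_presses") <- n_invalid
  out
}

adjust_rate <- function(count, n, correction) {
  switch(correction,
         loglinear = (count + 0.5) / (n + 1),
         clip = {
           r <- count / n
           pmin(pmax(r, 1 / (2 * n)), 1 - 1 / (2 * n))
         },
         none = count / n,
         stopf("unknown correction '%s'", correction))
}

#' Signal-detection sensitivity d-prime
#'
#' d' = qnorm(hit_rate) - qnorm(fa_rate), positive for above-chance
#' performance. Extreme rates (0 or 1) are adjusted before the probit by
#' the chosen correction: `loglinear` replaces each rate by
#' (count + 0.5) / (n + 1), `clip` bounds rates to [1/(2n), 1 - 1/(2n)],
#' and `none` leaves them untouched (erroring on infinite values).
#'
#' @param hit_rate,fa_rate observed proportions in [0, 1].
#' @param n_go,n_nogo trial counts behind the rates.
#' @param correction "loglinear" (default), "clip", or "none".
#' @return d-prime in z-units.
#' @export
dprime <- function(hit_rate, fa_rate, n_go, n_nogo,
                   correction = c("loglinear", "clip", "none")) {
  correction <- match.arg(correction)
  if (any(c(hit_rate, fa_rate) < 0) || any(c(hit_rate, fa_rate) > 1))
    stopf("rates must be in [0, 1]")
  if (n_go <= 0 || n_nogo <= 0) stopf("trial counts must be positive")
  h <- adjust_rate(hit_rate * n_go, n_go, correction)
  f <- adjust_rate(fa_rate * n_nogo, n_nogo, correction)
  d <- stats::qnorm(h) - stats::qnorm(f)
  if (!is.finite(d))
    stopf("d-prime is infinite at rate 0 or 1; use a correction")
  d
}

#' Per-subject, per-condition behavioral summary
#'
#' One row per subject x task-inclusive condition, pooling all of the
#' condition's blocks: trial counts, hit and false-alarm rates, d-prime,
#' and mean/SD response latency over Hits only. Cells lacking Go or NoGo
#' trials are returned with NA measures and `incomplete = TRUE`, with a
#' warning, so they can be excluded downstream.
#'
#' @param trials data.frame of classified trial records carrying `subject`
#'   and `condition` columns (e.g. rbind-ed outputs of [classify_trials()]).
#' @param correction extreme-rate correction passed to [dprime()].
#' @return data.frame with columns subject, condition, n_go, n_nogo, n_hit,
#'   n_fa, hit_rate, fa_rate, dprime, rt_mean, rt_sd, incomplete.
#' @export
summarize_behavior <- function(trials, correction = "loglinear") {
  stopifnot(all(c("subject", "condition", "stim", "outcome") %in% names(trials)))
  cells <- unique(trials[, c("subject", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$subject == cells$subject[i] &
                  trials$condition == cells$condition[i], ]
    n_go <- sum(sub$stim == "Go")
    n_nogo <- sum(sub$stim == "NoGo")
    n_hit <- sum(sub$outcome == "Hit")
    n_fa <- sum(sub$outcome == "FA")
    rt <- sub$response_latency[sub$outcome == "Hit"]
    if (n_go == 0L || n_nogo == 0L) {
      warnf("subject %s condition %s lacks Go or NoGo trials; flagged",
            cells$subject[i], cells$condition[i])
      return(data.frame(subject = cells$subject[i],
                        condition = cells$condition[i],
                        n_go = n_go, n_nogo = n_nogo, n_hit = n_hit,
                        n_fa = n_fa, hit_rate = NA_real_, fa_rate = NA_real_,
                        dprime = NA_real_, rt_mean = NA_real_,
                        rt_sd = NA_real_, incomplete = TRUE))
    }
    data.frame(subject = cells$subject[i], condition = cells$condition[i],
               n_go = n_go, n_nogo = n_nogo, n_hit = n_hit, n_fa = n_fa,
               hit_rate = n_hit / n_go, fa_rate = n_fa / n_nogo,
               dprime = dprime(n_hit / n_go, n_fa / n_nogo, n_go, n_nogo,
                               correction),
               rt_mean = if (length(rt)) mean(rt) else NA_real_,
               rt_sd = if (length(rt) > 1) stats::sd(rt) else NA_real_,
               incomplete = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$subject, out$condition), ]
}
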