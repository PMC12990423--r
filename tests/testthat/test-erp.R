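test_that("band-pass filter rejects DC, attenuates 60 Hz, passes 10 Hz", {
  rec <- new_recording(matrix(10, nrow = 2, ncol = 5120), 512)
  bf <- bandpass(rec)
  expect_lt(max(abs(bf$samples[, 512:4608])), 0.1)

  t <- (0:10239) / 512
  rec2 <- new_recording(rbind(sin(2 * pi * 60 * t), sin(2 * pi * 10 * t)),
                        512)
  b2 <- bandpass(rec2)
  mid <- 2000:8000
  a60 <- max(abs(b2$samples[1, mid]))
  expect_lt(20 * log10(a60), -20)              # >= 20 dB attenuation
  a10 <- max(abs(b2$samples[2, mid]))
  expect_lt(abs(a10 - 1), 0.05)                # amplitude within 5%
  ## zero-phase: delay < 1 ms, measured by projection onto quadratures
  y <- b2$samples[2, mid]; s <- sin(2 * pi * 10 * t[mid]); c0 <- cos(2 * pi * 10 * t[mid])
  phase <- atan2(sum(y * c0), sum(y * s))
  delay_ms <- abs(phase) / (2 * pi * 10) * 1000
  expect_lt(delay_ms, 1)

  expect_error(bandpass(rec, low = 5, high = 2), "low < high")
  expect_error(bandpass(new_recording(matrix(0, 1, 100), 60)), "rate")
})

test_that("average reference zeroes column means and is idempotent", {
  set.seed(3)
  rec <- new_recording(matrix(rnorm(8 * 100), nrow = 8), 512)
  ar <- average_reference(rec)
  expect_lt(max(abs(colMeans(ar$samples))), 1e-9)
  ar2 <- average_reference(ar)
  expect_equal(ar2$samples, ar$samples, tolerance = 1e-12)
  expect_error(average_reference(new_recording(matrix(1, 1, 10), 512)),
               "2 channels")
})

test_that("bad channels are flagged by variance ranking and spline-repaired", {
  lay <- electrode_layout()
  set.seed(4)
  rec <- new_recording(matrix(rnorm(64 * 1000), nrow = 64), 512, lay$label)
  out <- detect_and_interpolate_bad(rec, lay)
  expect_equal(out$bad, character(0))

  rec2 <- rec
  rec2$samples[10, ] <- rec2$samples[10, ] * 100
  out2 <- detect_and_interpolate_bad(rec2, lay)
  expect_equal(out2$bad, lay$label[10])

  ## repaired channel variance back near its neighbors
  expect_lt(var(out2$recording$samples[10, ]), 4)

  rec3 <- rec
  rec3$samples[1:20, ] <- 0
  expect_error(detect_and_interpolate_bad(rec3, lay), "quality floor")
})

test_that("spherical-spline interpolation reconstructs smooth topographies", {
  lay <- electrode_layout()
  P <- mobigng:::layout_matrix(lay)
  dip <- c(0.3, 0.8, 0.5); dip <- dip / sqrt(sum(dip^2))
  topo <- as.numeric(P %*% dip) * 10
  for (lab in c("Cz", "F3", "P8", "Oz")) {
    i <- which(lay$label == lab)
    M <- matrix(topo, ncol = 1)
    est <- mobigng:::spline_interpolate(M, P, i)[i, 1]
    expect_lt(abs(est - topo[i]) / abs(topo[i]), 0.10)
  }
})

test_that("epoching uses the fixed 461-sample convention with baseline zeroing", {
  set.seed(5)
  rec <- new_recording(matrix(rnorm(3 * 2000), nrow = 3), 512,
                       c("a", "b", "c"),
                       events = data.frame(sample = 1000L, code = 1L))
  ep <- epoch(rec, baseline = NULL)
  expect_equal(dim(ep$data), c(1L, 3L, 461L))
  ## epoch covers samples 949..1409 (0-based): identity with the raw data
  expect_equal(ep$data[1, , ], unname(rec$samples[, 950:1410]))
  expect_equal(range(ep$time), c(-51, 409) / 512 * 1000)

  epb <- epoch(rec)
  bl <- epb$time >= -100 & epb$time <= 0
  expect_lt(max(abs(rowMeans(epb$data[1, , bl]))), 1e-9)

  rec$events <- data.frame(sample = 1990L, code = 1L)
  expect_warning(ep2 <- epoch(rec), "dropping")
  expect_equal(dim(ep2$data)[1], 0L)
})

test_that("grand averaging is subject-first with unweighted group means", {
  time <- seq(-100, 800, length.out = 11)
  mk <- function(v, subj, n) {
    w <- matrix(v, nrow = 2, ncol = 11)
    rownames(w) <- c("a", "b")
    d <- data.frame(subject = subj, group = "g", condition = "S-NF-T",
                    response_type = "Hit", n_trials = n)
    d$wave <- list(w)
    d
  }
  avgs <- rbind(mk(1, "s1", 100), mk(3, "s2", 2))
  attr(avgs, "time") <- time
  ga <- grand_average(avgs, c("group", "condition", "response_type"))
  ## unweighted over subjects: (1 + 3)/2, not trial-weighted
  expect_equal(unique(as.numeric(ga$wave[[1]])), 2)
  expect_equal(ga$n_subjects, 2L)
  expect_equal(ga$n_trials, 102L)

  ## +v / -v symmetry
  avgs2 <- rbind(mk(2, "s1", 10), mk(-2, "s2", 10))
  ga2 <- grand_average(avgs2, "condition")
  expect_equal(max(abs(ga2$wave[[1]])), 0)
})

test_that("average_epochs equals any trial when trials are identical", {
  w <- matrix(rnorm(3 * 21), nrow = 3)
  data <- array(0, dim = c(4, 3, 21))
  for (k in 1:4) data[k, , ] <- w
  ep <- structure(list(data = data, time = seq(-100, 800, length.out = 21),
                       rate = 512, channels = c("x", "y", "z"),
                       trials = data.frame(response_type = rep("Hit", 4))),
                  class = "mobi_epochs")
  av <- average_epochs(ep, "response_type")
  expect_equal(unname(av$wave[[1]]), w)
  expect_equal(av$n_trials, 4L)
})

test_that("two-pass windows re-center on each group's grand-average peak", {
  time <- seq(-99.609375, 798.828125, by = 1000 / 512)
  lay <- small_layout()
  mk_wave <- function(p2_lat, p3_lat) {
    w <- 4 * outer(exp(-angular_dist(lay, "FCz")^2 / 0.98),
                   exp(-(time - p2_lat)^2 / (2 * 25^2))) +
      -3 * outer(exp(-angular_dist(lay, "FCz")^2 / 0.98),
                 exp(-(time - p2_lat - 80)^2 / (2 * 25^2))) +
      6 * outer(exp(-angular_dist(lay, "CPz")^2 / 0.98),
                exp(-(time - p3_lat)^2 / (2 * 50^2)))
    rownames(w) <- lay$label
    w
  }
  gw <- list(TD = mk_wave(244, 405), ASD = mk_wave(250, 405))
  win <- two_pass_peak_windows(gw, time)
  td_p2 <- win[win$group == "TD" & win$component == "P2", ]
  expect_lt(abs(td_p2$low - 219), 2)
  expect_lt(abs(td_p2$high - 269), 2)
  p3 <- win[win$group == "ASD" & win$component == "P3", ]
  expect_lt(abs(p3$low - 355), 2)
  expect_lt(abs(p3$high - 455), 2)

  flat <- list(TD = matrix(0, nrow = nrow(lay), ncol = length(time),
                           dimnames = list(lay$label, NULL)))
  expect_error(two_pass_peak_windows(flat, time), "no identifiable peak")
})

test_that("find_peak returns signed extrema with edge flags and tie rule", {
  time <- seq(0, 500, by = 2)
  x <- 5 * exp(-(time - 240)^2 / (2 * 20^2))
  pk <- find_peak(x, time, window = c(200, 280), polarity = 1)
  expect_equal(pk$amplitude, 5, tolerance = 1e-6)
  expect_equal(pk$latency, 240)
  expect_false(pk$edge)

  xn <- -4 * exp(-(time - 320)^2 / (2 * 20^2))
  pkn <- find_peak(xn, time, window = c(280, 380), polarity = -1)
  expect_equal(pkn$amplitude, -4, tolerance = 1e-6)
  expect_equal(pkn$latency, 320)

  ramp <- time / 100
  pkr <- find_peak(ramp, time, window = c(100, 300), polarity = 1)
  expect_true(pkr$edge)
  expect_equal(pkr$latency, 300)

  ## tie breaks to the earliest sample
  xt <- rep(0, length(time)); xt[time >= 100 & time <= 120] <- 1
  pkt <- find_peak(xt, time, window = c(0, 500), polarity = 1)
  expect_equal(pkt$latency, 100)
})

test_that("difference waves are antisymmetric and topo segments bin correctly", {
  cr <- matrix(rnorm(4 * 50), nrow = 4)
  hit <- matrix(rnorm(4 * 50), nrow = 4)
  expect_equal(difference_wave(cr, cr), matrix(0, 4, 50))
  expect_equal(difference_wave(cr, hit), -difference_wave(hit, cr))
  expect_error(difference_wave(cr, hit[, 1:10]), "matching")

  time <- seq(-100, 798, length.out = 461)
  wave <- matrix(2, nrow = 3, ncol = 461,
                 dimnames = list(c("a", "b", "c"), NULL))
  seg <- topo_segments(wave, time)
  expect_equal(dim(seg), c(3L, 10L))
  expect_true(all(seg == 2))
  expect_equal(colnames(seg)[1], "100-150")
})

test_that("the averaging pipeline is linear in input voltage", {
  set.seed(8)
  stream <- generate_trial_stream(12, 0.2, seed = 8)
  rec <- simulate_eeg(stream, NULL, list(erp_component("P3", 400, 5, 60)),
                      noise_rms = 4, layout = small_layout(), seed = 9)
  rec3 <- rec; rec3$samples <- 3 * rec3$samples
  ep1 <- epoch(rec); ep3 <- epoch(rec3)
  av1 <- apply(ep1$data, c(2, 3), mean)
  av3 <- apply(ep3$data, c(2, 3), mean)
  expect_equal(av3, 3 * av1, tolerance = 1e-12)
  expect_equal(difference_wave(av3, 3 * av1),
               matrix(0, nrow(av1), ncol(av1)), ignore_attr = TRUE)
})

test_that("injected peaks are recovered across seeded noisy runs", {
  ## noise RMS chosen so the 200-trial average carries the residual noise of
  ## a group grand average (~0.12 uV); see the methods vignette
  lay <- small_layout()
  n_trials <- 200; noise <- 1.6
  se <- noise / sqrt(n_trials)
  lat_err <- amp_err <- numeric(20)
  for (i in 1:20) {
    stream <- generate_trial_stream(n_trials, 0, seed = 100 + i)
    rec <- simulate_eeg(stream, NULL, list(erp_component("P3", 420, 5, 50)),
                        noise_rms = noise, layout = lay, seed = 200 + i)
    rec <- bandpass(rec)
    ep <- epoch(rec)
    av <- apply(ep$data, c(2, 3), mean); rownames(av) <- ep$channels
    pk <- find_peak(av, ep$time, "CPz", c(350, 500), 1)
    lat_err[i] <- abs(pk$latency - 420)
    amp_err[i] <- abs(pk$amplitude - 5)
  }
  expect_gte(mean(lat_err <= 4), 0.9)
  expect_gte(mean(amp_err <= 2 * se), 0.9)
})
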