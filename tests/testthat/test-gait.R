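test_that("heel-strike detector matches ground truth and the brute-force oracle", {
  p0 <- gait_params(stride_time_cv = 0, stride_length_cv = 0,
                    step_width_cv = 0)
  sim <- simulate_gait_markers(p0, 15, seed = 1)
  z <- sim$stream$markers$right_heel[, "z"]
  st <- detect_heel_strikes(z, 100, smooth = FALSE)
  truth <- sim$truth$right_strikes
  expect_equal(length(st), length(truth))
  expect_true(all(abs(st - truth) <= 10))       # one 100 Hz sample

  ## with 2 mm white noise, strikes stay within 20 ms of truth and agree
  ## with an exhaustive local-extrema oracle on the smoothed trace
  set.seed(2)
  zn <- z + rnorm(length(z), sd = 2)
  stn <- detect_heel_strikes(zn, 100, smooth = TRUE, smooth_ms = 50)
  expect_equal(length(stn), length(truth))
  expect_true(all(abs(stn - truth) <= 20))
  sm <- mobigng:::smooth_ma(zn, 5)
  oracle <- brute_force_peaks(sm, min_dist = 60, min_prom = 20)
  expect_equal(round(stn / 10) + 1, oracle)

  expect_error(detect_heel_strikes(rep(0, 2000), 100), "insufficient")
  expect_error(detect_heel_strikes(z[1:50], 100), "too short")
})

test_that("detector equals the brute-force oracle on random rough traces", {
  set.seed(33)
  for (rep in 1:5) {
    x <- cumsum(rnorm(3000)) + 30 * sin(2 * pi * (1:3000) / 120)
    mine <- mobigng:::find_peaks(x, min_dist = 80, min_prominence = 15)
    oracle <- brute_force_peaks(x, min_dist = 80, min_prom = 15)
    expect_equal(mine, oracle)
  }
})

test_that("heel lifts are the per-stride minima with earliest-tie rule", {
  ## sawtooth: linear drop then linear rise, cycle 100 samples
  cyc <- c(seq(100, 0, length.out = 51)[-51], seq(0, 100, length.out = 50))
  z <- rep(cyc, 5)
  strikes <- (which(z == 100) - 1) / 100 * 1000
  strikes <- strikes[c(TRUE, diff(strikes) > 10)]
  lifts <- detect_heel_lifts(z, strikes, 100)
  expect_equal(length(lifts), length(strikes) - 1)
  expect_true(all(z[round(lifts / 10) + 1] == 0))

  ## flat-bottomed trough: earliest sample of the tie
  z2 <- c(5, 3, 1, 1, 1, 3, 5)
  l2 <- detect_heel_lifts(z2, c(0, 60), 100)
  expect_equal(l2, 20)
})

test_that("stride metrics compute literal time and length definitions", {
  z <- seq(0, 1, length.out = 300)
  sm <- stride_metrics(z, strikes = c(0, 1300, 2600), lifts = c(600, 1900),
                       rate = 100)
  expect_equal(sm$stride_time, c(1300, 1300))

  ## lift at z = -300 mm, next strike at z = +350 mm -> 650 mm
  zt <- rep(0, 500); zt[101] <- -300; zt[201] <- 350; zt[401] <- 350
  sm2 <- stride_metrics(zt, strikes = c(0, 2000, 4000), lifts = c(1000, 3000),
                        rate = 100)
  expect_equal(sm2$stride_length[1], 650)

  ## negative computed length is excluded with a warning
  zt2 <- rep(0, 500); zt2[101] <- 300; zt2[201] <- -50
  expect_warning(
    sm3 <- stride_metrics(zt2, strikes = c(0, 2000, 4000),
                          lifts = c(1000, 3000), rate = 100),
    "negative")
  expect_equal(nrow(sm3), 1L)
})

test_that("step widths are absolute lateral distances at right strikes", {
  xl <- rep(-100, 1000); xr <- rep(100, 1000)
  w <- step_widths(xl, xr, c(0, 1300, 2600), 100)
  expect_equal(w, rep(200, 3))
  expect_equal(step_widths(xr, xl, c(0), 100), 200)  # absolute value
  expect_error(step_widths(xl, xr, 99999, 100), "coverage")
})

test_that("variability metrics are recovered within stated tolerances", {
  sim <- simulate_gait_markers(
    gait_params(stride_time_cv = 3, stride_length_cv = 3, step_width_cv = 8),
    270, seed = 9)
  ev <- gait_events(sim$stream, default_config())
  expect_gt(nrow(ev$strides), 190)
  tr <- sim$truth
  expect_lt(abs(mean(ev$strides$stride_time) - mean(tr$stride_times)) /
              mean(tr$stride_times), 0.02)
  expect_lt(abs(cv_percent(ev$strides$stride_time) - 3), 0.6)
  expect_lt(abs(cv_percent(ev$strides$stride_length) - 3), 0.6)
  expect_lt(abs(cv_percent(ev$widths) - 8), 1.6)
  expect_lt(abs(mean(ev$widths) - 200) / 200, 0.02)
})

test_that("block summaries use sample-SD CV% and unweighted condition means", {
  mk_ev <- function(st, sl, sw) {
    structure(list(strides = data.frame(stride_time = st, stride_length = sl),
                   widths = sw), class = "gait_events")
  }
  pb <- data.frame(subject = c("s1", "s1"), condition = c("W-NF-T", "W-NF-T"),
                   block = 1:2)
  pb$events <- list(mk_ev(c(1200, 1300, 1400), rep(650, 3), rep(200, 3)),
                    mk_ev(c(1200, 1300, 1400), rep(650, 3), rep(200, 3)))
  gs <- summarize_gait(pb)
  expect_equal(gs$blocks$stride_time_mean, c(1300, 1300))
  expect_equal(gs$blocks$stride_time_cv, rep(100 * 100 / 1300, 2),
               tolerance = 1e-12)
  expect_equal(gs$blocks$stride_length_cv, c(0, 0))
  expect_true(all(gs$blocks$flagged_short))
  ## two identical blocks: condition mean equals the block value
  expect_equal(gs$conditions$stride_time_cv, gs$blocks$stride_time_cv[1])
})

test_that("CV% is invariant under positive rescaling", {
  set.seed(5)
  x <- rlnorm(50, 7, 0.05)
  for (c in c(0.1, 3, 1000))
    expect_equal(cv_percent(c * x), cv_percent(x), tolerance = 1e-12)
})
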