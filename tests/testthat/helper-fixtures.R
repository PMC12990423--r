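# shared fixtures built in code; nothing here touches the network or disk
# outside tempdir()

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# a small electrode subset that keeps the component-center channels
small_layout <- function() {
  electrode_layout(c("Fz", "FCz", "Cz", "CPz", "Pz", "C3", "C4"))
}

# deterministic multi-channel recording with known content
sine_recording <- function(n_ch = 4, n = 2048, rate = 512, freq = 10,
                           amp = 1) {
  t <- (seq_len(n) - 1) / rate
  samples <- t(vapply(seq_len(n_ch),
                      function(i) amp * sin(2 * pi * freq * t + i),
                      numeric(n)))
  new_recording(samples, rate, paste0("ch", seq_len(n_ch)))
}

# subject-level average waveforms for the cluster suite: a P3-like effect
# (CR > Hit) injected for selected groups, plus white noise
synthetic_subject_avgs <- function(n_per_group = 5, effect_groups = "TD",
                                   effect_uv = 3, noise_sd = 0.5,
                                   conditions = task_conditions(),
                                   seed = 1) {
  lay <- small_layout()
  time <- seq(-100, 800, length.out = 231)
  bump <- exp(-(time - 420)^2 / (2 * 60^2))
  w_spatial <- exp(-angular_dist(lay, "CPz")^2 / (2 * 0.7^2))
  set.seed(seed)
  rows <- list()
  for (g in c("TD", "ASD")) {
    for (s in paste0(g, seq_len(n_per_group))) {
      for (cond in conditions) {
        for (rt in c("Hit", "CR")) {
          base <- matrix(rnorm(length(w_spatial) * length(time), sd = noise_sd),
                         nrow = length(w_spatial))
          if (rt == "CR" && g %in% effect_groups)
            base <- base + effect_uv * outer(as.numeric(w_spatial), bump)
          rownames(base) <- lay$label
          rows[[length(rows) + 1L]] <- data.frame(
            subject = s, group = g, condition = cond, response_type = rt,
            n_trials = 30L)
          rows[[length(rows)]]$wave <- list(base)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "time") <- time
  out
}

# long-format balanced/unbalanced mixed design with null or injected effects
random_mixed_design <- function(n1, n2, k1, k2 = NULL, sd = 1,
                                effect = 0) {
  subs <- c(paste0("A", seq_len(n1)), paste0("B", seq_len(n2)))
  grp <- rep(c("g1", "g2"), c(n1, n2))
  w1 <- paste0("c", seq_len(k1))
  if (is.null(k2)) {
    d <- expand.grid(subject = subs, w1 = w1, stringsAsFactors = FALSE)
    within <- "w1"
  } else {
    d <- expand.grid(subject = subs, w1 = w1,
                     w2 = paste0("r", seq_len(k2)), stringsAsFactors = FALSE)
    within <- c("w1", "w2")
  }
  d$group <- grp[match(d$subject, subs)]
  d$value <- rnorm(nrow(d), sd = sd) +
    effect * as.numeric(factor(d$w1))
  list(data = d, within = within)
}

# independent car-based Type III mixed ANOVA oracle (multivariate lm with
# an idesign); returns NULL when car is unavailable
car_oracle <- function(d, within) {
  if (!requireNamespace("car", quietly = TRUE)) return(NULL)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  k1 <- length(unique(d$w1))
  if (length(within) == 2L) {
    k2 <- length(unique(d$w2))
    cells <- expand.grid(w2 = sort(unique(d$w2)), w1 = sort(unique(d$w1)),
                         stringsAsFactors = FALSE)[, 2:1]
  } else {
    cells <- data.frame(w1 = sort(unique(d$w1)), stringsAsFactors = FALSE)
  }
  us <- unique(d$subject)
  Y <- sapply(seq_len(nrow(cells)), function(i) {
    sel <- d$w1 == cells$w1[i]
    if (length(within) == 2L) sel <- sel & d$w2 == cells$w2[i]
    sub <- d[sel, ]
    sub$value[match(us, sub$subject)]
  })
  g <- factor(d$group[match(us, d$subject)])
  idata <- as.data.frame(lapply(cells, factor))
  idesign <- if (length(within) == 2L) ~ w1 * w2 else ~ w1
  s <- suppressWarnings(summary(
    car::Anova(stats::lm(Y ~ g), idata = idata, idesign = idesign, type = 3),
    multivariate = FALSE))
  s
}

# brute-force local-extrema scan honoring min distance and prominence;
# independent oracle for the gait peak detector
brute_force_peaks <- function(x, min_dist, min_prom) {
  n <- length(x)
  is_max <- logical(n)
  for (i in 2:(n - 1)) {
    j <- i - 1
    while (j >= 1 && x[j] == x[i]) j <- j - 1
    k <- i + 1
    while (k <= n && x[k] == x[i]) k <- k + 1
    is_max[i] <- (j < 1 || x[j] < x[i]) && (k > n || x[k] < x[i]) &&
      (i == 1 || x[i - 1] <= x[i])  # plateau: first sample only
  }
  # plateau handling: keep only first index of equal-value runs
  cand <- which(is_max)
  cand <- cand[c(TRUE, diff(cand) > 1 | x[cand[-1]] != x[cand[-length(cand)]])]
  prom <- vapply(cand, function(p) {
    hl <- which(x[1:p] > x[p])
    lo_l <- min(x[(if (length(hl)) max(hl) else 1):p])
    hr <- which(x[p:n] > x[p]) + p - 1
    lo_r <- min(x[p:(if (length(hr)) min(hr) else n)])
    x[p] - max(lo_l, lo_r)
  }, 0)
  cand <- cand[prom >= min_prom]
  ord <- cand[order(-x[cand], cand)]
  kept <- integer()
  for (p in ord)
    if (!length(kept) || all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
  sort(kept)
}
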