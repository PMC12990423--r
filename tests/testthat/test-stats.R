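test_that("pointwise t maps follow the textbook formulas and zero-variance rule", {
  arr <- function(m) array(m, dim = c(length(m), 1, 1))
  A <- arr(c(1, 2, 3, 4)); B <- arr(c(0, 1, 2, 5))
  cm <- pointwise_t_map(A, B, "paired")
  d <- c(1, 1, 1, -1)
  expect_equal(as.numeric(cm$t), mean(d) / (sd(d) / 2), tolerance = 1e-12)
  expect_equal(cm$df, 3)
  expect_equal(as.numeric(cm$p),
               2 * pt(-abs(mean(d) / (sd(d) / 2)), 3), tolerance = 1e-12)

  ## identical inputs: t = 0, p = 1 everywhere
  set.seed(1)
  X <- array(rnorm(5 * 2 * 7), dim = c(5, 2, 7))
  cm0 <- pointwise_t_map(X, X, "paired")
  expect_true(all(cm0$t == 0))
  expect_true(all(cm0$p == 1))

  ## constant nonzero difference: the zero-variance rule fires
  expect_warning(cmz <- pointwise_t_map(arr(1:3), arr(0:2), "paired"),
                 "zero variance")
  expect_equal(as.numeric(cmz$p), 1)

  ## two-sample equals the pooled-variance oracle
  set.seed(2)
  A2 <- array(rnorm(6), dim = c(6, 1, 1)); B2 <- array(rnorm(5), dim = c(5, 1, 1))
  cm2 <- pointwise_t_map(A2, B2, "two_sample")
  tt <- t.test(A2[, 1, 1], B2[, 1, 1], var.equal = TRUE)
  expect_equal(as.numeric(cm2$t), unname(tt$statistic), tolerance = 1e-12)
  expect_equal(cm2$df, 9)

  expect_error(pointwise_t_map(arr(1:2), arr(1:2), "paired"), "3 subjects")
})

test_that("run-length mask enforces the 10-consecutive-sample boundary", {
  p <- matrix(1, 2, 40)
  p[1, 5:13] <- 0.01    # 9 consecutive: all rejected
  p[2, 5:14] <- 0.01    # 10 consecutive: all kept
  m <- runlength_mask(p, 0.05, 10)
  expect_equal(sum(m[1, ]), 0L)
  expect_equal(sum(m[2, ]), 10L)
  expect_true(all(which(m[2, ]) == 5:14))
  ## runs do not span channels
  p2 <- matrix(0.01, 2, 6)
  expect_true(all(!runlength_mask(p2, 0.05, 10)))
  expect_error(runlength_mask(matrix(2, 1, 5)), "p-values")
})

test_that("run-length masking is monotone in alpha and min_run", {
  set.seed(7)
  for (i in 1:20) {
    p <- matrix(runif(6 * 50), 6, 50)^2
    m1 <- runlength_mask(p, 0.10, 8)
    expect_true(all(runlength_mask(p, 0.05, 8) <= m1))   # shrink alpha
    expect_true(all(runlength_mask(p, 0.10, 12) <= m1))  # grow min_run
  }
})

test_that("null simulations: the run criterion suppresses isolated points", {
  set.seed(11)
  n_sub <- 12; n_ch <- 8; n_t <- 150; reps <- 60
  any_cluster <- any_point <- 0; masked_frac <- 0
  for (r in 1:reps) {
    A <- array(rnorm(n_sub * n_ch * n_t), dim = c(n_sub, n_ch, n_t))
    B <- array(rnorm(n_sub * n_ch * n_t), dim = c(n_sub, n_ch, n_t))
    cm <- pointwise_t_map(A, B, "paired")
    any_cluster <- any_cluster + sum(apply(cm$mask, 1, any))
    any_point <- any_point + sum(apply(cm$p < 0.05, 1, any))
    masked_frac <- masked_frac + mean(cm$mask)
  }
  expect_lt(any_cluster, any_point)             # strictly fewer channels hit
  expect_lte(masked_frac / reps, 0.05)          # masked fraction <= alpha
})

test_that("the cluster suite localizes a group-specific inhibition effect", {
  avgs <- synthetic_subject_avgs(n_per_group = 6, effect_groups = "TD",
                                 effect_uv = 4, noise_sd = 0.5, seed = 3)
  time <- attr(avgs, "time")
  maps <- cluster_contrast_suite(avgs)
  expect_equal(length(maps), 9L)

  sel <- time >= 350 & time <= 500
  cpz <- "CPz"
  for (cond in task_conditions()) {
    m_td <- maps[[sprintf("TD_%s_hit_vs_cr", cond)]]
    expect_gt(sum(m_td$mask[cpz, sel]), 0)
    gd <- maps[[sprintf("group_diff_%s", cond)]]
    expect_gt(sum(gd$mask[cpz, sel]), 0)
  }

  ## zero-noise zero-effect: every map empty (flat zero-variance grids)
  avgs0 <- synthetic_subject_avgs(n_per_group = 4, effect_groups = character(),
                                  effect_uv = 0, noise_sd = 0, seed = 4)
  maps0 <- suppressWarnings(cluster_contrast_suite(avgs0))
  expect_true(all(vapply(maps0, function(m) sum(m$mask) == 0, TRUE)))
})

test_that("identical groups yield null-consistent between-group maps", {
  avgs <- synthetic_subject_avgs(n_per_group = 8,
                                 effect_groups = c("TD", "ASD"),
                                 effect_uv = 3, noise_sd = 1, seed = 6)
  maps <- cluster_contrast_suite(avgs)
  frac <- mean(vapply(task_conditions(), function(cond)
    mean(maps[[sprintf("group_diff_%s", cond)]]$mask), 0))
  expect_lte(frac, 0.05)
})

test_that("mixed ANOVA equals aov stratum sums of squares on balanced data", {
  set.seed(21)
  r <- random_mixed_design(5, 5, 3, 2)
  at <- mixed_rm_anova(r$data, within = r$within)
  a <- summary(aov(value ~ group * w1 * w2 + Error(subject / (w1 * w2)),
                   data = r$data))
  get_ss <- function(stratum, term) {
    tab <- a[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "Sum Sq"]
  }
  expect_equal(at$SS[at$effect == "group"], get_ss("Error: subject", "group"),
               tolerance = 1e-10)
  expect_equal(at$SS[at$effect == "w1"], get_ss("Error: subject:w1", "w1"),
               tolerance = 1e-10)
  expect_equal(at$SS[at$effect == "group:w1:w2"],
               get_ss("Error: subject:w1:w2", "group:w1:w2"),
               tolerance = 1e-10)
})

test_that("mixed ANOVA matches the car Type III oracle with GG correction", {
  skip_if_not_installed("car")
  set.seed(22)
  configs <- list(c(5, 5, 3, 2), c(6, 4, 3, 2), c(4, 4, 2, 3), c(7, 5, 3, 0))
  for (cfgv in configs) {
    k2 <- if (cfgv[4] == 0) NULL else cfgv[4]
    r <- random_mixed_design(cfgv[1], cfgv[2], cfgv[3], k2, effect = 0.4)
    at <- mixed_rm_anova(r$data, within = r$within)
    s <- car_oracle(r$data, r$within)
    ut <- s$univariate.tests
    map <- c(group = "g", w1 = "w1", "group:w1" = "g:w1", w2 = "w2",
             "group:w2" = "g:w2", "w1:w2" = "w1:w2",
             "group:w1:w2" = "g:w1:w2")
    for (i in seq_len(nrow(at))) {
      j <- which(rownames(ut) == map[[at$effect[i]]])
      expect_equal(at$F[i], unname(ut[j, "F value"]), tolerance = 1e-8)
      expect_equal(at$p_uncorrected[i], unname(ut[j, "Pr(>F)"]),
                   tolerance = 1e-8)
    }
    pa <- s$pval.adjustments
    for (eff in rownames(pa)) {
      mine <- at[at$effect == names(map)[map == eff], ]
      expect_equal(mine$gg_epsilon, unname(pa[eff, "GG eps"]),
                   tolerance = 1e-8)
      expect_equal(mine$p_gg, unname(pa[eff, "Pr(>F[GG])"]),
                   tolerance = 1e-8)
    }
  }
})

test_that("ANOVA validates its design and reports errors usefully", {
  r <- random_mixed_design(4, 4, 3)
  d <- r$data[-1, ]   # knock out one cell
  expect_error(mixed_rm_anova(d, within = "w1"), "missing")
  d2 <- r$data; d2$group <- "g1"
  expect_error(mixed_rm_anova(d2, within = "w1"), "2 levels")
})

test_that("Greenhouse-Geisser epsilon hits its analytic anchors", {
  ## k = 2: always 1
  expect_equal(gg_epsilon(matrix(c(2, 0.3, 0.3, 1), 2)), 1)
  ## compound symmetry: exactly 1
  S_cs <- diag(4) * 2 + 0.7
  expect_equal(gg_epsilon(S_cs), 1, tolerance = 1e-6)
  ## maximally non-spherical rank-1 (double-centered) covariance, k = 3
  v <- c(1, 0, -1)
  expect_equal(gg_epsilon(tcrossprod(v)), 0.5, tolerance = 1e-12)
  expect_error(gg_epsilon(matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("partial eta squared and Cohen's d follow their definitions", {
  expect_equal(partial_eta_sq(10, 30), 0.25)
  expect_error(partial_eta_sq(-1, 3), ">= 0")

  expect_equal(cohens_d(5, 1, 10, 5, 1, 10)$value, 0)
  d1 <- cohens_d(2, 1.2, 12, 3, 0.8, 14)
  d2 <- cohens_d(3, 0.8, 14, 2, 1.2, 12)
  expect_equal(d1$value, -d2$value)              # antisymmetric
  ## equal SDs: pooled SD equals that SD regardless of ns
  expect_equal(cohens_d(2.599, 1.41, 18, 3.830, 1.41, 17)$value,
               (2.599 - 3.830) / 1.41, tolerance = 1e-12)
  ## paired kind: mean difference over SD of differences
  expect_equal(cohens_d(0.5, 0.25, 10, kind = "paired")$value, 2)
})

test_that("summary t-test and Bonferroni behave as published conventions", {
  r <- student_t_two_sample(1, 1, 10, 1, 1, 12)
  expect_equal(r$t, 0)
  expect_equal(r$df, 20)
  set.seed(9)
  x <- rnorm(8); y <- rnorm(9)
  tt <- t.test(x, y, var.equal = TRUE)
  mine <- student_t_two_sample(mean(x), sd(x), 8, mean(y), sd(y), 9)
  expect_equal(mine$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(mine$p, tt$p.value, tolerance = 1e-12)

  expect_equal(bonferroni(0.02, 3), 0.06)
  expect_equal(bonferroni(0.5, 3), 1)
  p <- runif(20)
  expect_true(all(bonferroni(p) >= p))
})

test_that("pairwise post-hocs produce matched and pooled contrasts", {
  set.seed(10)
  d <- expand.grid(subject = paste0("s", 1:8),
                   condition = c("S-NF-T", "W-NF-T", "W-F-T"),
                   stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d)) + (d$condition == "W-NF-T") * 1.5
  ph <- pairwise_posthoc(d, "value", "condition", paired = TRUE)
  expect_equal(nrow(ph), 3L)
  expect_true(all(ph$p_bonf >= ph$p))
  expect_equal(ph$df, rep(7, 3))
  ## between-subject version
  d$grp <- rep(c("a", "b"), 12)
  ph2 <- pairwise_posthoc(d[d$condition == "S-NF-T", ], "value", "grp",
                          paired = FALSE)
  expect_equal(ph2$df, 6)
})
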