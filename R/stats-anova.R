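## orthonormal polynomial-free contrasts for a k-level within factor
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), `/`)
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-violation correction factor for a k-level within-subject
#' factor, computed from the covariance matrix of the k repeated measures:
#' the covariance is double-centered and epsilon =
#' tr(S)^2 / ((k-1) tr(S^2)), clamped to its analytic range
#' [1/(k-1), 1]. Equals 1 exactly under compound symmetry and 1/(k-1) for
#' a maximally non-spherical rank-1 covariance.
#'
#' @param S symmetric positive semi-definite k x k covariance matrix.
#' @return epsilon.
#' @export
gg_epsilon <- function(S) {
  S <- as.matrix(S)
  k <- nrow(S)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
    stopf("covariance must be symmetric")
  if (k < 2L) return(1)
  Cn <- diag(k) - 1 / k
  Sc <- Cn %*% S %*% Cn
  num <- sum(diag(Sc))^2
  den <- (k - 1) * sum(Sc * Sc)
  if (den < 1e-30) return(1)
  min(1, max(1 / (k - 1), num / den))
}

## Greenhouse-Geisser epsilon from the covariance of orthonormal contrast
## variables (already centered in contrast space)
eps_contrast <- function(S) {
  q <- nrow(S)
  if (q < 2L) return(1)
  den <- q * sum(S * S)
  if (den < 1e-30) return(1)
  min(1, max(1 / q, sum(diag(S))^2 / den))
}

#' Partial eta squared
#'
#' Effect size SS_effect / (SS_effect + SS_error), in [0, 1].
#'
#' @param ss_effect,ss_error non-negative sums of squares.
#' @return partial eta squared.
#' @export
partial_eta_sq <- function(ss_effect, ss_error) {
  if (any(c(ss_effect, ss_error) < 0)) stopf("sums of squares must be >= 0")
  ss_effect / (ss_effect + ss_error)
}

#' Mixed repeated-measures ANOVA
#'
#' Univariate mixed-model ANOVA for a design with one between-subject
#' factor and one or two fully crossed within-subject factors, on balanced
#' (complete-cell) data; group sizes may differ. Sums of squares are
#' Type III, computed on orthonormal within-subject contrast variables.
#' Each within effect carries a Greenhouse-Geisser epsilon estimated from
#' the pooled covariance of its contrast variables, the epsilon-corrected
#' p-value, and partial eta squared; uncorrected p-values are always
#' reported alongside.
#'
#' @param data data.frame in long format.
#' @param dv name of the value column.
#' @param subject name of the subject-identifier column.
#' @param between name of the between-subject factor column (>= 2 levels).
#' @param within character vector of 1 or 2 within-subject factor columns,
#'   each with 2 or 3 levels.
#' @return data.frame (class `anova_table`) with one row per effect:
#'   effect, SS, df, MS, F, df_error, SS_error, p_uncorrected, gg_epsilon,
#'   p_gg, partial_eta_sq.
#' @export
mixed_rm_anova <- function(data, dv = "value", subject = "subject",
                           between = "group", within) {
  stopifnot(all(c(dv, subject, between, within) %in% names(data)))
  if (length(within) < 1L || length(within) > 2L)
    stopf("1 or 2 within factors supported")
  data[[subject]] <- as.character(data[[subject]])
  glev <- sort(unique(as.character(data[[between]])))
  if (length(glev) < 2L) stopf("between factor needs >= 2 levels")
  wlev <- lapply(within, function(w) sort(unique(as.character(data[[w]]))))
  ksz <- vapply(wlev, length, 0L)
  K <- prod(ksz)

  ## wide matrix Y: subjects x within cells, cells ordered with the last
  ## within factor fastest
  cells <- if (length(within) == 2L)
    expand.grid(w2 = wlev[[2]], w1 = wlev[[1]], stringsAsFactors = FALSE)[, 2:1]
  else data.frame(w1 = wlev[[1]], stringsAsFactors = FALSE)
  subs <- unique(data[[subject]])
  Y <- matrix(NA_real_, nrow = length(subs), ncol = K)
  grp <- character(length(subs))
  for (si in seq_along(subs)) {
    rows <- data[data[[subject]] == subs[si], ]
    grp[si] <- as.character(rows[[between]][1])
    for (ci in seq_len(K)) {
      sel <- rows[[within[1]]] == cells[ci, 1]
      if (length(within) == 2L) sel <- sel & rows[[within[2]]] == cells[ci, 2]
      v <- rows[[dv]][sel]
      if (length(v) != 1L || is.na(v))
        stopf("subject %s: missing or duplicated cell %s", subs[si],
              paste(unlist(cells[ci, ]), collapse = "/"))
      Y[si, ci] <- v
    }
  }
  ng <- table(factor(grp, levels = glev))
  N <- length(subs)
  G <- length(glev)
  if (any(ng < 2L)) stopf("each group needs >= 2 subjects")

  ## contrast matrices per effect
  ones <- function(k) matrix(1 / sqrt(k), nrow = k)
  Cs <- lapply(ksz, orthonormal_contrasts)
  effs <- list()
  if (length(within) == 1L) {
    effs[[within[1]]] <- Cs[[1]]
  } else {
    effs[[within[1]]] <- kronecker(Cs[[1]], ones(ksz[2]))
    effs[[within[2]]] <- kronecker(ones(ksz[1]), Cs[[2]])
    effs[[paste(within, collapse = ":")]] <- kronecker(Cs[[1]], Cs[[2]])
  }

  gi <- lapply(glev, function(g) which(grp == g))
  rows <- list()
  add_row <- function(effect, SS, df, SSe, dfe, eps = NA_real_) {
    Fv <- (SS / df) / (SSe / dfe)
    p <- stats::pf(Fv, df, dfe, lower.tail = FALSE)
    p_gg <- if (is.na(eps)) p else
      stats::pf(Fv, df * eps, dfe * eps, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(
      effect = effect, SS = SS, df = df, MS = SS / df, F = Fv,
      SS_error = SSe, df_error = dfe, p_uncorrected = p,
      gg_epsilon = eps, p_gg = p_gg,
      partial_eta_sq = partial_eta_sq(SS, SSe))
  }

  ## between stratum: subject means scaled to an orthonormal contrast
  u <- Y %*% ones(K)
  ubar <- vapply(gi, function(i) mean(u[i]), 0)
  uw <- sum(ng * ubar) / N
  SS_G <- sum(ng * (ubar - uw)^2)
  SS_SG <- sum(vapply(seq_along(gi),
                      function(j) sum((u[gi[[j]]] - ubar[j])^2), 0))
  add_row(between, SS_G, G - 1, SS_SG, N - G)

  ## within strata: one per within effect, shared by its group interaction
  for (en in names(effs)) {
    M <- effs[[en]]
    q <- ncol(M)
    Z <- Y %*% M
    zbar <- do.call(rbind, lapply(gi, function(i)
      colMeans(Z[i, , drop = FALSE])))
    zw <- colSums(zbar * as.numeric(ng)) / N
    zu <- colMeans(zbar)
    dev <- Z - zbar[match(grp, glev), , drop = FALSE]
    SSe <- sum(dev^2)
    dfe <- q * (N - G)
    eps <- eps_contrast(crossprod(dev) / (N - G))
    ## Type III: main = unweighted group-mean of contrasts equals zero
    SS_main <- sum(zu^2) * G^2 / sum(1 / as.numeric(ng))
    add_row(en, SS_main, q, SSe, dfe, eps)
    SS_int <- sum(as.numeric(ng) * rowSums(sweep(zbar, 2, zw)^2))
    add_row(paste(between, en, sep = ":"), SS_int, q * (G - 1), SSe, dfe, eps)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Pooled-SD Cohen's d and paired Cohen's d
#'
#' `pooled`: d = (m1 - m2) / s_p with
#' s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2), the effect size for
#' between-group contrasts. `paired`: d = mean difference / SD of the
#' differences (pass them as `m1`/`s1`).
#'
#' @param m1,s1,n1 first group's mean, SD, n (or the paired differences'
#'   mean and SD, with n the pair count).
#' @param m2,s2,n2 second group's mean, SD, n (ignored for paired).
#' @param kind "pooled" or "paired".
#' @return list of class `effect_size` with `kind`, `value`, `components`.
#' @export
cohens_d <- function(m1, s1, n1, m2 = NULL, s2 = NULL, n2 = NULL,
                     kind = c("pooled", "paired")) {
  kind <- match.arg(kind)
  if (kind == "pooled") {
    if (any(c(s1, s2) <= 0)) stopf("SDs must be positive")
    if (any(c(n1, n2) < 2)) stopf("ns must be >= 2")
    sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
    value <- (m1 - m2) / sp
  } else {
    if (s1 <= 0) stopf("SD of differences must be positive")
    value <- m1 / s1
  }
  structure(list(kind = paste0(kind, "_d"), value = value,
                 components = list(m1 = m1, s1 = s1, n1 = n1, m2 = m2,
                                   s2 = s2, n2 = n2)),
            class = "effect_size")
}

#' Two-sample Student t-test from summary statistics
#'
#' Pooled-variance t with df = n1 + n2 - 2, recomputable from printed
#' means/SDs/ns.
#'
#' @param m1,s1,n1,m2,s2,n2 group means, SDs, and sizes.
#' @return list with `t`, `df`, `p` (two-tailed).
#' @export
student_t_two_sample <- function(m1, s1, n1, m2, s2, n2) {
  if (any(c(s1, s2) <= 0)) stopf("SDs must be positive")
  if (any(c(n1, n2) < 2)) stopf("ns must be >= 2")
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Bonferroni adjustment
#'
#' p_adj = min(1, m p), with m defaulting to the number of p-values.
#'
#' @param p_list numeric vector of p-values.
#' @param m number of comparisons.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_list, m = length(p_list)) {
  if (m < 1) stopf("m must be >= 1")
  pmin(1, m * p_list)
}

#' Bonferroni-corrected pairwise post-hoc comparisons
#'
#' All pairwise contrasts of one factor's levels: paired t-tests on
#' within-subject factors (subject-matched differences), pooled-variance
#' two-sample t-tests on between-subject factors, each with means, SDs,
#' Cohen's d, and Bonferroni-adjusted p.
#'
#' @param data long data.frame.
#' @param dv value column name.
#' @param factor factor column name.
#' @param subject subject column name (used to pair within-subject data).
#' @param paired TRUE for a within-subject factor.
#' @return data.frame, one row per level pair.
#' @export
pairwise_posthoc <- function(data, dv = "value", factor, subject = "subject",
                             paired = TRUE) {
  levs <- sort(unique(as.character(data[[factor]])))
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- data[data[[factor]] == pr[1], ]
    b <- data[data[[factor]] == pr[2], ]
    if (paired) {
      m <- match(a[[subject]], b[[subject]])
      x <- a[[dv]]; y <- b[[dv]][m]
      d <- x - y
      tt <- stats::t.test(d)
      es <- cohens_d(mean(d), stats::sd(d), length(d), kind = "paired")
    } else {
      x <- a[[dv]]; y <- b[[dv]]
      tt <- stats::t.test(x, y, var.equal = TRUE)
      es <- cohens_d(mean(x), stats::sd(x), length(x),
                     mean(y), stats::sd(y), length(y))
    }
    data.frame(level_1 = pr[1], level_2 = pr[2],
               mean_1 = mean(x), sd_1 = stats::sd(x),
               mean_2 = mean(y, na.rm = TRUE), sd_2 = stats::sd(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, cohens_d = es$value)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- bonferroni(out$p, nrow(out))
  out
}
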