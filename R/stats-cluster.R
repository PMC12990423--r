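#' Pointwise t-test map over channels x time
#'
#' Applies a two-tailed t-test at every channel x time point of two
#' subjects x channels x time arrays: paired tests on within-subject
#' differences, or two-sample tests with pooled variance. Points with zero
#' variance get t = 0 and p = 1 (with a warning) so the grid shape stays
#' stable.
#'
#' @param A,B numeric arrays, subjects x channels x time. For a paired
#'   design the subject dimensions must match.
#' @param design "paired" or "two_sample".
#' @param alpha significance threshold stored on the map.
#' @param min_run run-length criterion stored on the map (samples).
#' @param contrast free-text descriptor.
#' @return object of class `cluster_map`: `t`, `p` (channels x time),
#'   `mask` (after the run-length criterion), `df`, `alpha`, `min_run`,
#'   `contrast`.
#' @export
pointwise_t_map <- function(A, B, design = c("paired", "two_sample"),
                            alpha = 0.05, min_run = 10, contrast = "") {
  design <- match.arg(design)
  dA <- dim(A); dB <- dim(B)
  if (length(dA) != 3L || length(dB) != 3L || any(dA[2:3] != dB[2:3]))
    stopf("A and B must be subjects x channels x time with matching grids")
  if (min(dA[1], dB[1]) < 3L) stopf("need at least 3 subjects per cell")
  flat <- function(X) matrix(X, nrow = dim(X)[1])   # subjects x (ch*time)
  if (design == "paired") {
    if (dA[1] != dB[1]) stopf("paired design needs equal subject counts")
    D <- flat(A) - flat(B)
    n <- nrow(D)
    m <- colMeans(D)
    s <- sqrt(colSums(sweep(D, 2, m)^2) / (n - 1))
    df <- n - 1
    se <- s / sqrt(n)
  } else {
    Xa <- flat(A); Xb <- flat(B)
    na <- nrow(Xa); nb <- nrow(Xb)
    ma <- colMeans(Xa); mb <- colMeans(Xb)
    va <- colSums(sweep(Xa, 2, ma)^2)
    vb <- colSums(sweep(Xb, 2, mb)^2)
    sp2 <- (va + vb) / (na + nb - 2)
    m <- ma - mb
    df <- na + nb - 2
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  }
  zero <- se < 1e-14
  if (any(zero & abs(m) > 1e-14))
    warnf("%d grid point(s) with zero variance set to p = 1", sum(zero))
  tval <- ifelse(zero, 0, m / ifelse(zero, 1, se))
  pval <- ifelse(zero, 1, 2 * stats::pt(-abs(tval), df))
  tmat <- matrix(tval, nrow = dA[2])
  pmat <- matrix(pval, nrow = dA[2])
  dimnames(tmat) <- dimnames(pmat) <- dimnames(A)[2:3]
  structure(list(t = tmat, p = pmat,
                 mask = runlength_mask(pmat, alpha, min_run),
                 df = df, alpha = alpha, min_run = min_run,
                 contrast = contrast),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> %s: %d x %d grid, df = %g, alpha = %g, min_run = %d, %d masked points\n",
              x$contrast, nrow(x$t), ncol(x$t), x$df, x$alpha, x$min_run,
              sum(x$mask)))
  invisible(x)
}

#' Consecutive-sample (run-length) significance mask
#'
#' Keeps, per channel, only maximal runs of at least `min_run` consecutive
#' time points with p below alpha; all other points are masked out. Runs
#' never span channels. This is the consecutive-sample criterion used to
#' control isolated spuriously significant points in pointwise maps.
#'
#' @param p_values channels x time matrix of p-values (a vector is treated
#'   as one channel).
#' @param alpha pointwise significance threshold.
#' @param min_run minimum run length in samples (study value: 10).
#' @return logical matrix of the same shape.
#' @export
runlength_mask <- function(p_values, alpha = 0.05, min_run = 10) {
  if (!is.matrix(p_values)) p_values <- matrix(p_values, nrow = 1L)
  if (any(p_values < 0 | p_values > 1)) stopf("p-values must be in [0, 1]")
  mask <- matrix(FALSE, nrow = nrow(p_values), ncol = ncol(p_values),
                 dimnames = dimnames(p_values))
  for (ch in seq_len(nrow(p_values))) {
    r <- rle(p_values[ch, ] < alpha)
    keep <- r$values & r$lengths >= min_run
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(keep)) mask[ch, starts[j]:ends[j]] <- TRUE
  }
  mask
}

#' The study's nine cluster contrasts
#'
#' Builds, from subject-level average waveforms, the six within-group
#' Hit-vs-CR paired maps (2 groups x 3 task conditions) and the three
#' between-group two-sample maps on per-subject CR - Hit difference waves
#' (one per task condition). Cells missing either response type for a
#' subject drop that subject; a contrast left with too few subjects is
#' skipped with a message.
#'
#' @param subject_avgs data.frame of subject-level averages with columns
#'   `subject`, `group`, `condition`, `response_type` and list-column
#'   `wave` (channels x time), as built by [average_epochs()] per subject
#'   and rbind-ed.
#' @param alpha,min_run cluster criterion parameters.
#' @return named list of `cluster_map` objects.
#' @export
cluster_contrast_suite <- function(subject_avgs, alpha = 0.05, min_run = 10) {
  conds <- intersect(task_conditions(), unique(subject_avgs$condition))
  groups <- unique(subject_avgs$group)
  maps <- list()
  stack <- function(waves) {
    arr <- array(0, dim = c(length(waves), dim(waves[[1]])))
    for (i in seq_along(waves)) arr[i, , ] <- waves[[i]]
    dimnames(arr)[2:3] <- dimnames(waves[[1]])
    arr
  }
  ## per subject x condition: hit and cr waves (NULL when absent)
  get_wave <- function(subj, cond, rt) {
    i <- which(subject_avgs$subject == subj & subject_avgs$condition == cond &
               subject_avgs$response_type == rt)
    if (length(i) == 1L) subject_avgs$wave[[i]] else NULL
  }
  for (cond in conds) {
    diffs <- list()
    for (g in groups) {
      subs <- unique(subject_avgs$subject[subject_avgs$group == g])
      hits <- list(); crs <- list()
      for (s in subs) {
        h <- get_wave(s, cond, "Hit"); cr <- get_wave(s, cond, "CR")
        if (!is.null(h) && !is.null(cr)) {
          hits[[length(hits) + 1L]] <- h
          crs[[length(crs) + 1L]] <- cr
        }
      }
      nm <- sprintf("%s_%s_hit_vs_cr", g, cond)
      if (length(hits) < 3L) {
        message(sprintf("skipping %s: only %d complete subject(s)", nm,
                        length(hits)))
      } else {
        maps[[nm]] <- pointwise_t_map(stack(crs), stack(hits), "paired",
                                      alpha, min_run,
                                      contrast = sprintf("%s %s CR - Hit",
                                                         g, cond))
        diffs[[g]] <- stack(Map(function(cr, h) cr - h, crs, hits))
      }
    }
    nm <- sprintf("group_diff_%s", cond)
    if (length(diffs) == 2L) {
      maps[[nm]] <- pointwise_t_map(diffs[[1]], diffs[[2]], "two_sample",
                                    alpha, min_run,
                                    contrast = sprintf(
                                      "(CR - Hit) %s vs %s, %s",
                                      groups[1], groups[2], cond))
    } else {
      message(sprintf("skipping %s: missing a group", nm))
    }
  }
  maps
}
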