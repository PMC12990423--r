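`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Coefficient of variation in percent
#'
#' CV% = 100 * SD / mean, with the sample (n-1) standard deviation, the
#' convention used for all gait-variability metrics in this package.
#'
#' @param x numeric vector (at least two values).
#' @return CV in percent.
#' @export
cv_percent <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  100 * stats::sd(x) / mean(x)
}

#' Convert miles per hour to meters per second
#'
#' Treadmill belt speeds are commonly set in mph; analyses report m/s.
#' 1 mile = 1609.344 m exactly.
#'
#' @param mph speed in miles per hour.
#' @return speed in meters per second.
#' @export
mph_to_mps <- function(mph) mph * 1609.344 / 3600

## deterministic sub-seed derivation: keeps every stream independent under a
## single user seed while staying inside 32-bit integer range
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483399) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
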