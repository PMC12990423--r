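#' Continuous EEG recording
#'
#' Container for a multichannel EEG recording: a channels x time voltage
#' matrix in microvolts, the sampling rate, ordered 10-20 channel labels, and
#' an event table. Event latencies are stored as 0-based sample indices and
#' converted to milliseconds only at reporting, so no rounding drift
#' accumulates across stages.
#'
#' @param samples numeric matrix, channels x time, in microvolts. Row names,
#'   if present, are taken as channel labels.
#' @param rate sampling rate in samples/s (512 for study-conforming data).
#' @param channel_labels character vector of unique channel names.
#' @param events data.frame with columns `sample` (0-based index) and `code`
#'   (integer trigger code); may have extra columns (e.g. `condition`).
#' @return object of class `mobi_recording`.
#' @export
new_recording <- function(samples, rate, channel_labels = rownames(samples),
                          events = data.frame(sample = integer(), code = integer())) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stopf("rate must be a single positive number, got %s", format(rate))
  if (anyDuplicated(channel_labels))
    stopf("channel labels must be unique")
  if (length(channel_labels) != nrow(samples))
    stopf("%d labels for %d channels", length(channel_labels), nrow(samples))
  if (nrow(events) > 0L &&
      (any(events$sample < 0L) || any(events$sample >= ncol(samples))))
    stopf("event sample indices must lie in [0, %d)", ncol(samples))
  rownames(samples) <- channel_labels
  structure(list(samples = samples, rate = rate,
                 channel_labels = channel_labels, events = events),
            class = "mobi_recording")
}

#' @export
print.mobi_recording <- function(x, ...) {
  cat(sprintf("<mobi_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate, nrow(x$events)))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$samples)

#' Motion-capture marker stream
#'
#' Named set of 3-D marker trajectories on a uniform time grid. Axis
#' convention is fixed: x = mediolateral (positive right), y = vertical,
#' z = anterior-posterior (positive anterior, i.e. the direction opposing
#' treadmill belt travel). Positions are millimeters.
#'
#' @param markers named list of n x 3 numeric matrices (columns x, y, z),
#'   all the same length. Gait analysis requires `left_heel` and
#'   `right_heel`.
#' @param rate sampling rate in samples/s (study value 100).
#' @return object of class `mobi_markers`.
#' @export
new_marker_stream <- function(markers, rate = 100) {
  if (rate <= 0) stopf("rate must be positive")
  if (is.null(names(markers)) || any(!nzchar(names(markers))))
    stopf("markers must be a named list")
  lens <- vapply(markers, nrow, integer(1))
  if (length(unique(lens)) > 1L)
    stopf("all marker traces must have equal length")
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    colnames(m) <- c("x", "y", "z")
    m
  })
  structure(list(markers = markers, rate = rate), class = "mobi_markers")
}

#' @export
print.mobi_markers <- function(x, ...) {
  n <- if (length(x$markers)) nrow(x$markers[[1]]) else 0L
  cat(sprintf("<mobi_markers> %d markers (%s) x %d samples @ %g Hz\n",
              length(x$markers), paste(names(x$markers), collapse = ", "),
              n, x$rate))
  invisible(x)
}

require_heel_markers <- function(ms) {
  need <- c("left_heel", "right_heel")
  miss <- setdiff(need, names(ms$markers))
  if (length(miss))
    stopf("missing heel markers: %s", paste(miss, collapse = ", "))
  invisible(ms)
}

## the five study conditions: motor-sensory-cognitive
STUDY_CONDITIONS <- c("S-NF-T", "W-NF-NT", "W-F-NT", "W-NF-T", "W-F-T")

#' Experimental condition label
#'
#' Encodes the motor (standing/walking), sensory (optic flow or not) and
#' cognitive (task or not) load of a block. Only the five combinations used
#' in the study design are accepted by default; the standing-with-flow-task
#' combination (S-F-T) is rejected unless `permissive = TRUE`.
#'
#' @param motor "standing" or "walking".
#' @param sensory "no_flow" or "flow".
#' @param cognitive "task" or "no_task".
#' @param permissive allow combinations outside the five study conditions.
#' @return condition code string such as "W-NF-T".
#' @export
condition_label <- function(motor = c("standing", "walking"),
                            sensory = c("no_flow", "flow"),
                            cognitive = c("task", "no_task"),
                            permissive = FALSE) {
  motor <- match.arg(motor)
  sensory <- match.arg(sensory)
  cognitive <- match.arg(cognitive)
  code <- paste(c(standing = "S", walking = "W")[motor],
                c(no_flow = "NF", flow = "F")[sensory],
                c(task = "T", no_task = "NT")[cognitive], sep = "-")
  if (!permissive && !code %in% STUDY_CONDITIONS)
    stopf("condition %s is not one of the five study conditions (%s)",
          code, paste(STUDY_CONDITIONS, collapse = ", "))
  code
}

#' Parse a condition code into its factors
#'
#' @param code condition string like "W-NF-T".
#' @return list with `motor`, `sensory`, `cognitive`.
#' @export
parse_condition <- function(code) {
  parts <- strsplit(code, "-", fixed = TRUE)[[1]]
  if (length(parts) != 3L) stopf("malformed condition code: %s", code)
  list(motor = c(S = "standing", W = "walking")[[parts[1]]],
       sensory = c(NF = "no_flow", F = "flow")[[parts[2]]],
       cognitive = c(T = "task", NT = "no_task")[[parts[3]]])
}

task_conditions <- function() c("S-NF-T", "W-NF-T", "W-F-T")
walking_conditions <- function() c("W-NF-NT", "W-F-NT", "W-NF-T", "W-F-T")
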