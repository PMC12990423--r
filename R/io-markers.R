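#' Read a marker-trajectory CSV
#'
#' Expects long-format columns `time` (seconds), `marker`, `x`, `y`, `z`
#' with the canonical axis convention (x mediolateral positive-right,
#' y vertical, z anterior-posterior positive-anterior). A header comment of
#' the form `# axes: x=<col>, y=<col>, z=<col>` declares that a canonical
#' axis is stored in a different file column and is remapped on read, e.g.
#' `# axes: x=z, y=x, z=y`. Timestamps must be uniform; traces are then
#' (linearly) resampled onto a uniform 100 Hz grid.
#'
#' @param path CSV file.
#' @param rate target grid rate in Hz.
#' @return [new_marker_stream()] object.
#' @export
read_markers <- function(path, rate = 100) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  axis_map <- c(x = "x", y = "y", z = "z")
  if (grepl("^#", first)) {
    m <- regmatches(first, gregexpr("[xyz] *= *[xyz]", first))[[1]]
    for (pair in m) {
      kv <- strsplit(gsub(" ", "", pair), "=")[[1]]
      axis_map[kv[1]] <- kv[2]
    }
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time", "marker", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("marker CSV lacks columns: %s",
                          paste(miss, collapse = ", "))
  out <- list()
  for (nm in unique(df$marker)) {
    sub <- df[df$marker == nm, ]
    sub <- sub[order(sub$time), ]
    dt <- diff(sub$time)
    if (length(dt) < 1L) stopf("marker %s has fewer than 2 samples", nm)
    if (max(dt) - min(dt) > 1e-6)
      stopf("non-uniform timestamps for marker %s; cannot resample", nm)
    t0 <- sub$time[1]
    t_end <- sub$time[nrow(sub)]
    grid <- seq(t0, t_end, by = 1 / rate)
    tr <- sapply(c("x", "y", "z"), function(ax)
      stats::approx(sub$time, sub[[axis_map[[ax]]]], xout = grid)$y)
    out[[nm]] <- tr
  }
  ms <- new_marker_stream(out, rate = rate)
  require_heel_markers(ms)
  ms
}

#' Write a marker stream as CSV
#'
#' Long format (`time, marker, x, y, z`) with full double precision, so a
#' write-read cycle reproduces positions to well under 1e-9 mm.
#'
#' @param ms [new_marker_stream()] object.
#' @param path output file.
#' @export
write_markers <- function(ms, path) {
  rows <- lapply(names(ms$markers), function(nm) {
    m <- ms$markers[[nm]]
    data.frame(time = (seq_len(nrow(m)) - 1L) / ms$rate, marker = nm,
               x = m[, 1], y = m[, 2], z = m[, 3])
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time,marker,x,y,z", con)
  writeLines(sprintf("%.12g,%s,%.17g,%.17g,%.17g",
                     df$time, df$marker, df$x, df$y, df$z), con)
  invisible(path)
}

#' Read / write a trial-event table
#'
#' Tab-separated with columns `onset_sample` (0-based), `code`, `condition`.
#' Trigger codes are this package's own documented convention: 1 = Go
#' stimulus onset, 2 = NoGo stimulus onset, 100 = button press.
#'
#' @param path TSV file.
#' @return data.frame with the three columns.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_sample", "code", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("events TSV lacks columns: %s",
                          paste(miss, collapse = ", "))
  df
}

#' @rdname read_events
#' @param events data.frame with columns onset_sample, code, condition.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

EVENT_GO <- 1L
EVENT_NOGO <- 2L
EVENT_PRESS <- 100L
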