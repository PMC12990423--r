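## EDF / BDF container support.
##
## EDF stores 16-bit and BDF (the BioSemi variant) 24-bit little-endian
## samples in fixed-size records behind an ASCII header; voltages are mapped
## linearly between the per-channel physical and digital ranges. Events are
## carried on a BioSemi-style "Status" channel: the trigger code is held at
## the onset sample(s), zero elsewhere, and decoded on read by rising-edge
## detection. Round-trips are exact up to the quantization step of the
## written physical range (2^-24 of it for BDF).

EDF_DIG <- c(-32768, 32767)
BDF_DIG <- c(-8388608, 8388607)

## format a number into at most `width` chars, plain notation preferred
fmt_num <- function(x, width) {
  s <- format(x, scientific = FALSE, trim = TRUE, digits = 15)
  for (d in c(6, 4, 3)) {
    if (nchar(s) <= width) return(s)
    s <- trimws(formatC(x, format = "g", digits = d))
  }
  if (nchar(s) > width) stopf("cannot format %g into %d chars", x, width)
  s
}

fmt_field <- function(x, width) {
  s <- if (is.numeric(x)) {
    s0 <- format(x, scientific = FALSE, trim = TRUE, digits = 15)
    if (nchar(s0) > width) s0 <- formatC(x, width = width, format = "g")
    s0
  } else as.character(x)
  if (nchar(s) > width) stopf("header field '%s' exceeds %d chars", s, width)
  formatC(s, width = -width)  # left-justified, space padded
}

read_ascii <- function(con, n) {
  raw <- readBin(con, "raw", n)
  if (length(raw) < n) stopf("malformed EDF/BDF: truncated header")
  trimws(rawToChar(raw))
}

#' Read an EDF or BDF recording
#'
#' Data channels are returned in microvolts (the physical dimension recorded
#' in the file is preserved as written); a channel labeled `Status` (or
#' `EDF Annotations`) is decoded into the event table by rising-edge
#' detection and excluded from the voltage matrix. If no event channel is
#' present a warning is raised and the event table is empty.
#'
#' @param path file path.
#' @param format "auto" (default, sniffed from the first header byte),
#'   "edf", or "bdf".
#' @return [new_recording()] object.
#' @export
read_eeg <- function(path, format = c("auto", "edf", "bdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))

  magic <- readBin(con, "raw", 8)
  if (length(magic) < 8) stopf("malformed EDF/BDF: file too short")
  is_bdf <- magic[1] == as.raw(255)
  if (format == "edf" && is_bdf) stopf("file is BDF but format='edf' requested")
  if (format == "bdf" && !is_bdf) stopf("file is EDF but format='bdf' requested")

  read_ascii(con, 80); read_ascii(con, 80)      # patient / recording id
  read_ascii(con, 8); read_ascii(con, 8)        # date / time
  header_bytes <- as.integer(read_ascii(con, 8))
  read_ascii(con, 44)                           # reserved
  n_records <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  if (is.na(ns) || ns < 1) stopf("malformed EDF/BDF: bad signal count")

  labels <- vapply(seq_len(ns), function(i) read_ascii(con, 16), "")
  for (i in seq_len(ns)) read_ascii(con, 80)    # transducer
  for (i in seq_len(ns)) read_ascii(con, 8)     # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  for (i in seq_len(ns)) read_ascii(con, 80)    # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(read_ascii(con, 8)), 0L)
  for (i in seq_len(ns)) read_ascii(con, 32)    # reserved

  if (any(is.na(c(pmin, pmax, dmin, dmax, spr))) || is.na(n_records) ||
      is.na(rec_dur) || rec_dur <= 0)
    stopf("malformed EDF/BDF: unparseable header fields")
  if (length(unique(spr)) != 1L)
    stopf("mixed per-signal sampling rates are not supported")
  expected_header <- 256L * (1L + ns)
  if (!is.na(header_bytes) && header_bytes != expected_header)
    stopf("malformed EDF/BDF: header size mismatch")

  bps <- if (is_bdf) 3L else 2L
  spr1 <- spr[1]
  rate <- spr1 / rec_dur
  ## the record duration's 8-char field limits precision; snap near-integer
  ## rates back to the integer
  if (abs(rate - round(rate)) < 0.01 * max(1, rate / 512)) rate <- round(rate)
  total <- as.numeric(n_records) * ns * spr1 * bps
  raw <- readBin(con, "raw", total)
  if (length(raw) < total) stopf("malformed EDF/BDF: truncated data section")

  ## decode all samples at once, then reshape record-wise
  if (is_bdf) {
    b <- matrix(as.integer(raw), nrow = 3L)
    v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
  } else {
    b <- matrix(as.integer(raw), nrow = 2L)
    v <- b[1, ] + 256L * b[2, ]
    v <- ifelse(v >= 32768, v - 65536, v)
  }
  ## v is ordered: record-major, then signal, then sample-within-record
  arr <- array(v, dim = c(spr1, ns, n_records))
  data <- matrix(0, nrow = ns, ncol = spr1 * n_records)
  for (i in seq_len(ns))
    data[i, ] <- as.numeric(arr[, i, ])

  ## digital -> physical
  scale <- (pmax - pmin) / (dmax - dmin)
  data <- data * scale + (pmin - dmin * scale)

  status_i <- which(tolower(labels) %in% c("status", "edf annotations"))
  if (length(status_i)) {
    sv <- round(data[status_i[1], ])
    prev <- c(0, sv[-length(sv)])
    ## an event starts wherever the code turns nonzero or changes value
    onset <- which(sv != 0 & (prev == 0 | prev != sv))
    events <- data.frame(sample = onset - 1L, code = as.integer(sv[onset]))
    keep <- setdiff(seq_len(ns), status_i)
  } else {
    warnf("no event (Status) channel in %s; returning empty events", path)
    events <- data.frame(sample = integer(), code = integer())
    keep <- seq_len(ns)
  }
  new_recording(data[keep, , drop = FALSE], rate = rate,
                channel_labels = labels[keep], events = events)
}

#' Write a recording as EDF or BDF
#'
#' Events are encoded on an appended `Status` channel (code value held for
#' one sample at onset). The physical range of each channel is fitted to its
#' data, so voltages round-trip to within one quantization step of that
#' range (1/2^24 of it for BDF, 1/2^16 for EDF); integer-valued microvolt
#' data within +/-2^22 round-trip exactly under BDF.
#'
#' @param rec [new_recording()] object.
#' @param path output file.
#' @param format "bdf" (default, 24-bit) or "edf" (16-bit).
#' @return the path, invisibly.
#' @export
write_eeg <- function(rec, path, format = c("bdf", "edf")) {
  format <- match.arg(format)
  is_bdf <- format == "bdf"
  dig <- if (is_bdf) BDF_DIG else EDF_DIG
  n <- n_samples(rec)
  rate <- rec$rate
  ## 1-s records when the length allows, otherwise one big record
  if (n %% rate == 0 && rate == round(rate)) {
    spr <- as.integer(rate); n_rec <- n %/% spr; rec_dur <- 1
  } else {
    spr <- n; n_rec <- 1L; rec_dur <- n / rate
  }

  ## each event occupies one Status sample; if two events collide on a
  ## sample, the later one shifts to the next free sample so no trigger is
  ## lost (the reader treats any code change as a new event)
  status <- numeric(n)
  if (nrow(rec$events) > 0) {
    for (k in seq_len(nrow(rec$events))) {
      s <- rec$events$sample[k] + 1L
      while (s <= n && status[s] != 0) s <- s + 1L
      if (s <= n) status[s] <- rec$events$code[k]
    }
  }
  data <- rbind(rec$samples, Status = status)
  labels <- c(rec$channel_labels, "Status")
  ns <- nrow(data)

  ## physical range per channel. Ranges are formatted into their 8-char
  ## header fields first and the parsed-back values drive the scaling, so
  ## written data and header agree exactly; the range is symmetric
  ## (pmin string = "-" + pmax string, 7 chars each). The Status channel
  ## uses the identity physical = digital mapping so codes are exact.
  pmax_str <- vapply(apply(data[-ns, , drop = FALSE], 1,
                           function(x) max(abs(x), 1)) * (1 + 1e-5),
                     fmt_num, "", width = 7)
  pmax_str <- c(pmax_str, fmt_num(dig[2], 8))
  pmin_str <- c(paste0("-", pmax_str[-ns]), fmt_num(dig[1], 8))
  pmax <- as.numeric(pmax_str)
  pmin <- as.numeric(pmin_str)

  con <- file(path, "wb")
  on.exit(close(con))
  if (is_bdf) {
    writeBin(as.raw(255), con)
    writeBin(charToRaw(fmt_field("BIOSEMI", 7)), con)
  } else {
    writeBin(charToRaw(fmt_field("0", 8)), con)
  }
  writeBin(charToRaw(fmt_field("synthetic", 80)), con)
  writeBin(charToRaw(fmt_field("mobigng", 80)), con)
  writeBin(charToRaw(fmt_field("01.01.00", 8)), con)
  writeBin(charToRaw(fmt_field("00.00.00", 8)), con)
  writeBin(charToRaw(fmt_field(256L * (1L + ns), 8)), con)
  writeBin(charToRaw(fmt_field(if (is_bdf) "24BIT" else "", 44)), con)
  writeBin(charToRaw(fmt_field(n_rec, 8)), con)
  writeBin(charToRaw(fmt_field(fmt_num(rec_dur, 8), 8)), con)
  writeBin(charToRaw(fmt_field(ns, 4)), con)
  put <- function(vals, width)
    for (v in vals) writeBin(charToRaw(fmt_field(v, width)), con)
  put(labels, 16)
  put(rep("", ns), 80)
  put(c(rep("uV", ns - 1L), ""), 8)
  put(pmin_str, 8)
  put(pmax_str, 8)
  put(rep(dig[1], ns), 8)
  put(rep(dig[2], ns), 8)
  put(rep("", ns), 80)
  put(rep(spr, ns), 8)
  put(rep("", ns), 32)

  scale <- (dig[2] - dig[1]) / (pmax - pmin)
  dmat <- round((data - pmin) * scale + dig[1])
  dmat <- pmin(pmax(dmat, dig[1]), dig[2])
  ## record-major interleaving: for each record, each signal's spr samples
  arr <- array(0, dim = c(spr, ns, n_rec))
  for (i in seq_len(ns))
    arr[, i, ] <- dmat[i, ]
  v <- as.numeric(arr)
  if (is_bdf) {
    v <- ifelse(v < 0, v + 16777216, v)
    bytes <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
  } else {
    v <- ifelse(v < 0, v + 65536, v)
    bytes <- rbind(v %% 256, (v %/% 256) %% 256)
  }
  writeBin(as.raw(bytes), con)
  invisible(path)
}
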