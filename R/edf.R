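# European Data Format (EDF) I/O for continuous recordings: 16-bit PCM data
# records, 1-second record duration, physical units in microvolts. Events
# travel separately as the TSV written by writeEvents().

.edfPad <- function(x, width) {
  x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' One-second data records; the final record is zero-padded. Each channel is
#' scaled to the 16-bit digital range from its own physical min/max.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param path output file path.
#' @param patient,recordingId free-text header fields.
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(recording, path, patient = "X X X X",
                     recordingId = "Startdate X X X X") {
  x <- recording@data
  fs <- recording@samplingRate
  if (fs != as.integer(fs)) stop("EDF export requires an integer sampling rate")
  ns <- nrow(x)
  nrec <- ceiling(ncol(x) / fs)
  pad <- nrec * fs - ncol(x)
  if (pad > 0) x <- cbind(x, matrix(0, ns, pad))
  physMin <- pmin(apply(x, 1, min), -1)
  physMax <- pmax(apply(x, 1, max), 1)
  # digitize per channel
  dmin <- -32768; dmax <- 32767
  dig <- matrix(0L, nrow(x), ncol(x))
  for (ch in seq_len(ns)) {
    g <- (dmax - dmin) / (physMax[ch] - physMin[ch])
    dig[ch, ] <- as.integer(round((x[ch, ] - physMin[ch]) * g + dmin))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8), .edfPad(patient, 80), .edfPad(recordingId, 80),
    .edfPad("01.01.00", 8), .edfPad("00.00.00", 8),
    .edfPad(as.character(256 * (1 + ns)), 8), .edfPad("", 44),
    .edfPad(as.character(nrec), 8), .edfPad("1", 8),
    .edfPad(as.character(ns), 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(recording@channels, .edfPad, "", width = 16),
    rep(.edfPad("", 80), ns),
    rep(.edfPad("uV", 8), ns),
    vapply(sprintf("%.6g", physMin), .edfPad, "", width = 8),
    vapply(sprintf("%.6g", physMax), .edfPad, "", width = 8),
    rep(.edfPad("-32768", 8), ns),
    rep(.edfPad("32767", 8), ns),
    rep(.edfPad("", 80), ns),
    rep(.edfPad(as.character(as.integer(fs)), 8), ns),
    rep(.edfPad("", 32), ns)
  )
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns))
      writeBin(dig[ch, cols], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Channel labels are normalized to upper case and reordered to the battery
#' montage; unknown extra channels are dropped with a warning, missing
#' montage channels are a hard error.
#'
#' @param path EDF file path.
#' @param montage required channel set (default \code{\link{batteryMontage}};
#'   NULL keeps the file's channels as-is).
#' @return An \linkS4class{EEGRecording} with an empty event table.
#' @export
readEDF <- function(path, montage = batteryMontage()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    out <- readChar(con, n, useBytes = TRUE)
    if (length(out) == 0 || nchar(out, type = "bytes") < n)
      stop("truncated EDF header")
    out
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(nrec) || is.na(ns) || ns < 1) stop("malformed EDF header")
  labels <- toupper(trimws(vapply(seq_len(ns), function(i) rd(16), "")))
  for (i in seq_len(ns)) rd(80)            # transducer
  units <- trimws(vapply(seq_len(ns), function(i) rd(8), ""))
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)            # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / recDur
  data <- matrix(0, ns, nrec * spr[1])
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      v <- readBin(con, "integer", spr[ch], size = 2, endian = "little",
                   signed = TRUE)
      if (length(v) < spr[ch]) stop("truncated EDF data record ", r)
      g <- (physMax[ch] - physMin[ch]) / (digMax[ch] - digMin[ch])
      data[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (v - digMin[ch]) * g + physMin[ch]
    }
  }
  if (!is.null(montage)) {
    missing <- setdiff(montage, labels)
    if (length(missing))
      stop("EDF file lacks montage channel(s): ",
           paste(missing, collapse = ", "))
    extra <- setdiff(labels, montage)
    if (length(extra))
      warning("dropping unknown channel(s): ", paste(extra, collapse = ", "))
    keep <- match(montage, labels)
    data <- data[keep, , drop = FALSE]
    labels <- montage
  }
  new("EEGRecording", data = data, channels = labels, samplingRate = fs,
      events = data.frame(sample = integer(0), onset_s = numeric(0),
                          word_id = integer(0), trial = integer(0),
                          block = integer(0), task = character(0)))
}

#' Attach an event table to a recording
#'
#' Maps event onsets (seconds) to sample indices at the recording's rate and
#' stores them on the recording; rows beyond the recording end are dropped
#' with a warning.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param events data.frame from \code{\link{readEvents}}.
#' @return The recording with events attached.
#' @export
attachEvents <- function(recording, events) {
  events$sample <- as.integer(floor(events$onset_s *
                                      recording@samplingRate))
  bad <- events$sample >= ncol(recording@data)
  if (any(bad)) {
    warning(sum(bad), " event(s) beyond the recording end; dropped")
    events <- events[!bad, ]
  }
  ev <- data.frame(sample = events$sample, onset_s = events$onset_s,
                   word_id = events$word_id, trial = events$trial_index,
                   block = events$block_index, task = events$task)
  if (!is.null(events$is_target)) ev$is_target <- events$is_target
  initialize(recording, events = ev)
}
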