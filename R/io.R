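#' Read / write a recording as delimited text
#'
#' The text dialect mirrors a review-station ASCII export: one column per
#' electrode with a header row of labels, samples in microvolts, and an
#' optional leading comment line `# fs: <Hz>` carrying the sampling rate
#' (written by [writeRecordingText()]; if absent, `fs` must be supplied).
#'
#' @param path file path.
#' @param fs sampling rate in Hz (required when the file has no `# fs:`
#'   comment).
#' @param age subject age in years.
#' @param sep field separator (default tab; `","` also common).
#' @return `readRecordingText` returns a [MonopolarRecording-class].
#' @export
readRecordingText <- function(path, fs = NULL, age = NA_real_, sep = "\t") {
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (grepl("^#", first)) {
    skip <- 1L
    m <- regmatches(first, regexec("fs[:=]\\s*([0-9.]+)", first))[[1L]]
    if (length(m) == 2L && is.null(fs)) fs <- as.numeric(m[2L])
  }
  if (is.null(fs)) stop("sampling rate not found in file; supply fs")
  tab <- read.table(path, header = TRUE, sep = sep, skip = skip,
                    check.names = FALSE)
  monopolarRecording(t(as.matrix(tab)), fs = fs, age = age)
}

#' @rdname readRecordingText
#' @param rec a [MonopolarRecording-class].
#' @export
writeRecordingText <- function(rec, path, sep = "\t") {
  stopifnot(is(rec, "MonopolarRecording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %g", samplingRate(rec)), con)
  write.table(t(samples(rec)), con, sep = sep, row.names = FALSE,
              col.names = TRUE, quote = FALSE)
  invisible(path)
}

.padAscii <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Read / write a recording as EDF
#'
#' A minimal European Data Format codec (16-bit samples, standard 256-byte
#' header blocks, 1 s data records). The writer stores each channel with its
#' own physical scaling; the reader keeps the 19 scalp electrodes and drops
#' any other signal (e.g. a dummy ECG channel), requiring a common sampling
#' rate across the kept channels. Records are truncated to whole seconds.
#'
#' @param path file path.
#' @param age subject age in years.
#' @return `readRecordingEDF` returns a [MonopolarRecording-class].
#' @export
readRecordingEDF <- function(path, age = NA_real_) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) trimws(rawToChar(readBin(con, "raw", nchars)))
  rd(8L)                                    # version
  rd(80L); rd(80L); rd(8L); rd(8L)          # patient, recording, date, time
  rd(8L)                                    # header bytes
  rd(44L)                                   # reserved
  nRec <- as.integer(rd(8L))
  recDur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  field <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- field(16L)
  field(80L); field(8L)                     # transducer, physical dimension
  physMin <- as.numeric(field(8L))
  physMax <- as.numeric(field(8L))
  digMin <- as.numeric(field(8L))
  digMax <- as.numeric(field(8L))
  field(80L)                                # prefiltering
  nSampRec <- as.integer(field(8L))
  field(32L)                                # reserved
  keep <- which(labels %in% electrodes1020())
  missing <- setdiff(electrodes1020(), labels[keep])
  if (length(missing))
    stop("EDF file lacks electrode(s): ", paste(missing, collapse = ", "))
  if (length(unique(nSampRec[keep])) != 1L)
    stop("EEG channels have heterogeneous sampling rates")
  fs <- nSampRec[keep][1L] / recDur
  scale <- (physMax - physMin) / (digMax - digMin)
  out <- matrix(NA_real_, length(keep), nRec * nSampRec[keep][1L],
                dimnames = list(labels[keep], NULL))
  for (r in seq_len(nRec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = nSampRec[s], size = 2L,
                     signed = TRUE, endian = "little")
      if (s %in% keep) {
        i <- match(s, keep)
        cols <- ((r - 1L) * nSampRec[s] + 1L):(r * nSampRec[s])
        out[i, cols] <- physMin[s] + (raw - digMin[s]) * scale[s]
      }
    }
  }
  monopolarRecording(out, fs = fs, age = age)
}

#' @rdname readRecordingEDF
#' @param rec a [MonopolarRecording-class].
#' @param ecg emit an additional synthetic 1 Hz "ECG" channel for format
#'   fidelity with clinical exports (no ECG analysis is supported).
#' @export
writeRecordingEDF <- function(rec, path, ecg = FALSE) {
  stopifnot(is(rec, "MonopolarRecording"))
  fs <- samplingRate(rec)
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer needs an integer sampling rate")
  x <- samples(rec)
  nRec <- floor(ncol(x) / fs)
  if (nRec < 1L) stop("recording shorter than one 1 s data record")
  if (ncol(x) %% fs != 0)
    x <- x[, seq_len(nRec * fs), drop = FALSE]
  if (ecg) {
    beat <- sin(2 * pi * seq_len(ncol(x)) / fs)^21 * 1000
    x <- rbind(x, ECG = beat)
  }
  ns <- nrow(x)
  # integer physical limits keep the 8-character header fields exact
  physMin <- floor(apply(x, 1L, min)) - 1
  physMax <- ceiling(apply(x, 1L, max)) + 1
  digMin <- rep(-32768, ns)
  digMax <- rep(32767, ns)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(paste0(.padAscii(x, width), collapse = ""),
                                     con, nchars = width * length(x),
                                     eos = NULL)
  wr("0", 8L)
  wr("X X X X", 80L)
  wr("Startdate X X X X", 80L)
  wr("01.01.00", 8L); wr("00.00.00", 8L)
  wr(as.character(256L * (ns + 1L)), 8L)
  wr("", 44L)
  wr(as.character(nRec), 8L)
  wr("1", 8L)
  wr(as.character(ns), 4L)
  wr(rownames(x), 16L)
  wr(rep("", ns), 80L)
  wr(rep("uV", ns), 8L)
  wr(as.character(physMin), 8L)
  wr(as.character(physMax), 8L)
  wr(as.character(digMin), 8L)
  wr(as.character(digMax), 8L)
  wr(rep("", ns), 80L)
  wr(rep(as.character(as.integer(fs)), ns), 8L)
  wr(rep("", ns), 32L)
  scale <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nRec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round(digMin[s] + (x[s, cols] - physMin[s]) * scale[s])
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a recording from EDF or delimited text by extension
#'
#' @param path file ending in `.edf` (any case), `.csv`, `.tsv` or `.txt`.
#' @param fs,age see the format-specific readers.
#' @return A [MonopolarRecording-class].
#' @export
readRecording <- function(path, fs = NULL, age = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    edf = readRecordingEDF(path, age = age),
    csv = readRecordingText(path, fs = fs, age = age, sep = ","),
    tsv = ,
    txt = readRecordingText(path, fs = fs, age = age, sep = "\t"),
    stop("unrecognized recording format: .", ext))
}
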