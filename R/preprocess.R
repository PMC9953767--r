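#' Construct a monopolar recording
#'
#' @param samples channels x time numeric matrix in microvolts, with the 19
#'   10-20 electrode labels as rownames (any order; stored in canonical
#'   order).
#' @param fs sampling rate in Hz.
#' @param age subject age in years (optional).
#' @return A [MonopolarRecording-class].
#' @examples
#' x <- matrix(rnorm(19 * 512), 19, 512, dimnames = list(electrodes1020(), NULL))
#' rec <- monopolarRecording(x, fs = 512, age = 30)
#' @export
monopolarRecording <- function(samples, fs, age = NA_real_) {
  if (!is.matrix(samples)) samples <- as.matrix(samples)
  lab <- rownames(samples)
  missing <- setdiff(electrodes1020(), lab)
  if (length(missing))
    stop("missing electrode(s): ", paste(missing, collapse = ", "))
  samples <- samples[electrodes1020(), , drop = FALSE]
  new("MonopolarRecording", samples = samples, fs = as.numeric(fs),
      subjectAge = as.numeric(age))
}

# zero-phase sixth-order Butterworth band-pass, realized as a cascade of a
# 6th-order high-pass and a 6th-order low-pass section (a single 12-pole
# band-pass transfer function is numerically unstable at 512 Hz for a
# 0.5 Hz lower edge)
.bandpassFiltfilt <- function(x, fs, band, order = 6L) {
  hp <- signal::butter(order, band[1L] / (fs / 2), type = "high")
  lp <- signal::butter(order, band[2L] / (fs / 2), type = "low")
  signal::filtfilt(lp, signal::filtfilt(hp, x))
}

#' Band-pass filter and downsample a recording
#'
#' Applies a zero-phase sixth-order Butterworth band-pass (default
#' 0.5-30 Hz) to every channel and decimates to the analysis rate (default
#' 128 Hz). The 30 Hz low-pass is the anti-alias guard for the 4:1
#' decimation.
#'
#' @param rec a [MonopolarRecording-class].
#' @param targetFs analysis sampling rate in Hz; must divide `fs` evenly.
#' @param band `c(low, high)` pass band in Hz.
#' @param order Butterworth order per edge (default 6).
#' @return A [MonopolarRecording-class] at `targetFs`.
#' @examples
#' rec <- monopolarRecording(
#'   matrix(sin(2 * pi * 10 * seq_len(2048) / 512), 19, 2048, byrow = TRUE,
#'          dimnames = list(electrodes1020(), NULL)), fs = 512)
#' out <- preprocessRecording(rec)
#' samplingRate(out)  # 128
#' @export
preprocessRecording <- function(rec, targetFs = 128, band = c(0.5, 30),
                                order = 6L) {
  stopifnot(is(rec, "MonopolarRecording"))
  fs <- samplingRate(rec)
  if (fs < 2 * band[2L])
    stop(sprintf("sampling rate %g Hz is below Nyquist for a %g Hz band edge",
                 fs, band[2L]))
  if (!all(is.finite(samples(rec))))
    stop("recording contains non-finite samples")
  factor <- fs / targetFs
  if (abs(factor - round(factor)) > 1e-9)
    stop(sprintf("targetFs %g Hz must divide the sampling rate %g Hz evenly",
                 targetFs, fs))
  factor <- as.integer(round(factor))
  x <- samples(rec)
  filtered <- t(apply(x, 1L, .bandpassFiltfilt, fs = fs, band = band,
                      order = order))
  keep <- seq(1L, ncol(filtered), by = factor)
  out <- filtered[, keep, drop = FALSE]
  rownames(out) <- rownames(x)
  monopolarRecording(out, fs = targetFs, age = subjectAge(rec))
}

#' Concatenate artifact-free chunks
#'
#' Joins visually selected artifact-free segments of one recording into a
#' single record for analysis. All chunks must share electrode labels and
#' sampling rate. A warning is issued when the total duration falls below
#' 120 s, the lower end of the epoch lengths for which the normative values
#' were established.
#'
#' @param chunks list of [MonopolarRecording-class] objects.
#' @param minDuration warning threshold in seconds (default 120).
#' @return A single [MonopolarRecording-class].
#' @export
concatenateChunks <- function(chunks, minDuration = 120) {
  if (!length(chunks)) stop("no chunks supplied")
  stopifnot(all(vapply(chunks, is, TRUE, "MonopolarRecording")))
  fs <- unique(vapply(chunks, samplingRate, 0))
  if (length(fs) != 1L)
    stop("chunks have mismatched sampling rates: ", paste(fs, collapse = ", "))
  labs <- lapply(chunks, channelLabels)
  if (!all(vapply(labs, identical, TRUE, labs[[1L]])))
    stop("chunks have mismatched channel labels")
  ages <- vapply(chunks, subjectAge, 0)
  joined <- do.call(cbind, lapply(chunks, samples))
  total <- ncol(joined) / fs
  if (total < minDuration)
    warning(sprintf("concatenated record is only %.1f s (< %g s)", total,
                    minDuration))
  monopolarRecording(joined, fs = fs, age = ages[1L])
}

#' Reconstruct the double-banana bipolar montage
#'
#' Derives the 18 differential channels of the longitudinal bipolar montage:
#' each bipolar trace is the anterior-electrode samples minus the
#' posterior-electrode samples. Any signal common to all electrodes (i.e.
#' the reference) cancels exactly.
#'
#' @param rec a [MonopolarRecording-class].
#' @return A [BipolarRecording-class] with channels in [bananaChannels()]
#'   order.
#' @export
doubleBanana <- function(rec) {
  stopifnot(is(rec, "MonopolarRecording"))
  x <- samples(rec)
  pairs <- bananaPairs()
  missing <- setdiff(unique(c(pairs)), rownames(x))
  if (length(missing))
    stop("missing electrode(s) for montage: ", paste(missing, collapse = ", "))
  out <- x[pairs[, 1L], , drop = FALSE] - x[pairs[, 2L], , drop = FALSE]
  rownames(out) <- bananaChannels()
  new("BipolarRecording", samples = out, fs = samplingRate(rec),
      subjectAge = subjectAge(rec))
}
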