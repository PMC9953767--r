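#' Divide a record into overlapping analysis windows
#'
#' Cuts the bipolar record into moving windows (default 1 s with 10%
#' overlap, i.e. a 0.9 s step). Window starts are placed at
#' `floor(i * step * fs)` so the window count equals
#' `floor((T - windowLen) / step) + 1` for a record of `T` seconds even when
#' the step is a non-integer number of samples.
#'
#' @param rec a [BipolarRecording-class] (or [MonopolarRecording-class]).
#' @param windowLen window length in seconds.
#' @param overlap fractional overlap of consecutive windows in [0, 1).
#' @return A [WindowSet-class].
#' @examples
#' # a 10 s record yields floor((10 - 1) / 0.9) + 1 = 11 windows
#' @export
makeWindows <- function(rec, windowLen = 1, overlap = 0.1) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  x <- samples(rec)
  nSamp <- ncol(x)
  wlen <- as.integer(round(windowLen * fs))
  if (nSamp < wlen)
    stop(sprintf("record (%.3f s) is shorter than one window (%g s)",
                 nSamp / fs, windowLen))
  step <- windowLen * (1 - overlap) * fs     # samples, possibly fractional
  nWin <- floor((nSamp - wlen) / step) + 1
  starts <- floor((seq_len(nWin) - 1) * step) + 1L
  win <- array(NA_real_, dim = c(nWin, nrow(x), wlen),
               dimnames = list(NULL, rownames(x), NULL))
  for (i in seq_len(nWin))
    win[i, , ] <- x[, starts[i]:(starts[i] + wlen - 1L), drop = FALSE]
  new("WindowSet", windows = win, starts = as.numeric(starts), fs = fs,
      windowLen = windowLen, overlap = overlap)
}

# complex windowed FFT shared by the power- and cross-spectral estimators;
# returns list(X = array win x chan x freq (one-sided), freqs, U = taper
# power sum, scale factors)
.windowedFFT <- function(ws, taper = c("hann", "rect"), padFactor = 2L) {
  taper <- match.arg(taper)
  d <- dim(ws@windows)
  nWin <- d[1L]; nChan <- d[2L]; wlen <- d[3L]
  w <- switch(taper,
    hann = 0.5 * (1 - cos(2 * pi * (0:(wlen - 1)) / wlen)),  # periodic Hann
    rect = rep(1, wlen))
  nfft <- wlen * padFactor
  nFreq <- nfft %/% 2L + 1L
  # channels*windows as columns of one big matrix for a single mvfft call
  flat <- matrix(0, nrow = nfft, ncol = nWin * nChan)
  idx <- 0L
  for (ch in seq_len(nChan)) for (i in seq_len(nWin)) {
    idx <- idx + 1L
    flat[seq_len(wlen), idx] <- ws@windows[i, ch, ] * w
  }
  X <- mvfft(flat)[seq_len(nFreq), , drop = FALSE]
  freqs <- (seq_len(nFreq) - 1L) * ws@fs / nfft
  list(X = X, freqs = freqs, nWin = nWin, nChan = nChan, nfft = nfft,
       U = sum(w^2), fs = ws@fs,
       labels = dimnames(ws@windows)[[2L]])
}

#' Per-window power spectrum
#'
#' Computes the one-sided power spectral density of every window and channel
#' via the FFT, `S = |X|^2 / (fs * U)` with `U` the taper power sum (so the
#' spectral area reproduces the time-domain mean square: Parseval's
#' relation, exact for the rectangular taper). Windows are Hann-tapered by
#' default and zero-padded (default x2) so that 1 s windows at 128 Hz give a
#' 0.5 Hz frequency grid.
#'
#' @param ws a [WindowSet-class].
#' @param taper `"hann"` (power-normalized) or `"rect"`.
#' @param padFactor zero-padding factor (integer >= 1).
#' @return A [WindowedSpectrum-class] in microvolts squared per Hz.
#' @export
powerSpectrum <- function(ws, taper = c("hann", "rect"), padFactor = 2L) {
  stopifnot(is(ws, "WindowSet"))
  if (!all(is.finite(ws@windows)))
    stop("windows contain non-finite samples")
  taper <- match.arg(taper)
  ft <- .windowedFFT(ws, taper, padFactor)
  P <- Mod(ft$X)^2 / (ft$fs * ft$U)
  onesided <- rep(2, length(ft$freqs))
  onesided[1L] <- 1
  if (ft$nfft %% 2L == 0L) onesided[length(onesided)] <- 1
  P <- P * onesided
  S <- array(NA_real_, dim = c(ft$nWin, ft$nChan, length(ft$freqs)),
             dimnames = list(NULL, ft$labels, NULL))
  idx <- 0L
  for (ch in seq_len(ft$nChan)) for (i in seq_len(ft$nWin)) {
    idx <- idx + 1L
    S[i, ch, ] <- P[, idx]
  }
  new("WindowedSpectrum", S = S, freqs = ft$freqs, fs = ft$fs, taper = taper)
}

# band-membership of frequency bins: each bin goes to the band whose
# interval (lower, upper] contains it; the lowest band additionally claims
# its own lower edge, so shared edges are counted exactly once
.bandBins <- function(freqs, bands = eegBands()) {
  lows <- vapply(bands, `[`, 0, 1L)
  lo0 <- min(lows)
  lapply(bands, function(b) {
    inBand <- freqs > b[1L] & freqs <= b[2L]
    if (b[1L] <= lo0) inBand <- inBand | abs(freqs - b[1L]) < 1e-9
    which(inBand)
  })
}

#' Band power areas
#'
#' Integrates the power spectrum over the classical EEG bands
#' (`A_j = sum(S * dk)` over the band's bins) for every window and channel,
#' then averages over windows. Bins on a shared band edge are assigned to
#' the lower band only, so the four bands partition the 0.5-30 Hz area
#' exactly.
#'
#' @param spec a [WindowedSpectrum-class].
#' @param bands named list of band edges (Hz), default [eegBands()].
#' @param perWindow if `TRUE`, return the window x channel x band array
#'   instead of the window average.
#' @return channel x band matrix of areas in microvolts squared (or the
#'   per-window array).
#' @export
bandAreas <- function(spec, bands = eegBands(), perWindow = FALSE) {
  stopifnot(is(spec, "WindowedSpectrum"))
  freqs <- spec@freqs
  edges <- sort(unique(unlist(bands)))
  if (min(edges) < min(freqs) - 1e-9 || max(edges) > max(freqs) + 1e-9)
    stop("band edges fall outside the spectral frequency grid")
  dk <- freqStep(spec)
  bins <- .bandBins(freqs, bands)
  d <- dim(spec@S)
  A <- array(NA_real_, dim = c(d[1L], d[2L], length(bands)),
             dimnames = list(NULL, dimnames(spec@S)[[2L]], names(bands)))
  for (j in seq_along(bands))
    A[, , j] <- apply(spec@S[, , bins[[j]], drop = FALSE], c(1L, 2L), sum) * dk
  if (perWindow) return(A)
  apply(A, c(2L, 3L), mean)
}

#' Log-transform band areas
#'
#' Raw spectral powers vary over orders of magnitude between subjects, so
#' band areas are compared on a decimal log scale (logPS = log10 area).
#'
#' @param areas numeric matrix/vector of band areas, all > 0.
#' @param base logarithm base (default 10).
#' @return Same shape as `areas`, log-transformed.
#' @export
logTransform <- function(areas, base = 10) {
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop("band areas must be positive and finite for the log transform")
  log(areas, base = base)
}

#' Shannon spectral entropy
#'
#' Normalizes the power spectrum over the analysis support (default
#' 0.5-30 Hz, 60 bins at 0.5 Hz spacing) to a probability distribution
#' `p_k = S_k / sum(S_k)` and computes `SSE = -sum(p_k log2 p_k)` in bits.
#' A flat spectrum attains the maximum `log2(nBins)`; a single spectral
#' line gives 0. By default the entropy is computed per window and averaged;
#' `order = "mean-spectrum"` instead takes the entropy of the window-averaged
#' spectrum.
#'
#' @param spec a [WindowedSpectrum-class].
#' @param support `c(low, high)` frequency support in Hz.
#' @param order `"per-window"` (average of per-window entropies) or
#'   `"mean-spectrum"`.
#' @return Named numeric vector of entropies (bits) per channel, with the
#'   bin count as attribute `nBins`.
#' @export
spectralEntropy <- function(spec, support = c(0.5, 30),
                            order = c("per-window", "mean-spectrum")) {
  stopifnot(is(spec, "WindowedSpectrum"))
  order <- match.arg(order)
  bins <- which(spec@freqs >= support[1L] - 1e-9 &
                spec@freqs <= support[2L] + 1e-9)
  if (!length(bins)) stop("entropy support outside the frequency grid")
  sub <- spec@S[, , bins, drop = FALSE]
  ent <- function(s) {
    tot <- sum(s)
    if (tot <= 0) stop("all-zero spectrum: entropy undefined")
    p <- s / tot
    -sum(ifelse(p > 0, p * log2(p), 0))
  }
  vals <- if (order == "per-window") {
    perWin <- apply(sub, c(1L, 2L), ent)
    colMeans(perWin)
  } else {
    meanS <- apply(sub, c(2L, 3L), mean)
    apply(meanS, 1L, ent)
  }
  names(vals) <- dimnames(spec@S)[[2L]]
  attr(vals, "nBins") <- length(bins)
  vals
}
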