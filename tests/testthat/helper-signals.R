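# fixture builders: all synthetic, constructed in code

# monopolar recording with every electrode carrying the same signal-maker
makeRecording <- function(fun, duration = 10, fs = 512, age = NA_real_) {
  t <- seq_len(round(duration * fs)) / fs
  x <- t(vapply(seq_along(electrodes1020()), function(i) fun(t, i),
                numeric(length(t))))
  rownames(x) <- electrodes1020()
  monopolarRecording(x, fs = fs, age = age)
}

sineRecording <- function(freq, amp = 1, duration = 10, fs = 512)
  makeRecording(function(t, i) amp * sin(2 * pi * freq * t),
                duration = duration, fs = fs)

noiseRecording <- function(duration = 10, fs = 512, sd = 1, seed = 1) {
  set.seed(seed)
  makeRecording(function(t, i) rnorm(length(t), sd = sd),
                duration = duration, fs = fs)
}

# bipolar recording built directly from a channel x time matrix of the 18
# double-banana channels (bypasses derivation; for estimator tests)
directBipolar <- function(x, fs = 128) {
  stopifnot(nrow(x) == 18L)
  rownames(x) <- bananaChannels()
  new("BipolarRecording", samples = x, fs = fs, subjectAge = NA_real_)
}

# bipolar record where every channel is an independent N(0,1) noise stream
noiseBipolar <- function(duration = 10, fs = 128, seed = 1) {
  set.seed(seed)
  directBipolar(matrix(rnorm(18 * round(duration * fs)), nrow = 18), fs = fs)
}

# single-channel windowed spectrum from a hand-built spectral shape
flatSpectrum <- function(values, freqs = seq(0, 64, by = 0.5), nwin = 3L) {
  S <- array(rep(values, each = nwin), dim = c(nwin, 1L, length(freqs)),
             dimnames = list(NULL, "P3-O1", NULL))
  new("WindowedSpectrum", S = S, freqs = freqs, fs = 128, taper = "hann")
}
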