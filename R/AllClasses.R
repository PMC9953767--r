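#' @importFrom stats approx coef cor fft fitted lm median mvfft pt quantile
#'   rnorm runif sd setNames t.test var wilcox.test confint predict
#' @importFrom utils head modifyList read.table write.csv write.table
NULL

setClass("EEGRecording",
  representation("VIRTUAL",
    samples = "matrix",     # channels x time, microvolts
    fs = "numeric",         # sampling rate, Hz
    subjectAge = "numeric"))

#' MonopolarRecording: 19-channel referential scalp EEG
#'
#' Container for a referential (monopolar) recording with the 19 classical
#' 10-20 electrodes. Samples are a channels x time matrix in microvolts with
#' electrode labels as rownames; all 19 electrodes must be present exactly
#' once and every sample finite.
#'
#' @slot samples channels x time numeric matrix (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot subjectAge subject age in years (`NA` if unknown).
#' @export
setClass("MonopolarRecording", contains = "EEGRecording")

setValidity("MonopolarRecording", function(object) {
  lab <- rownames(object@samples)
  want <- electrodes1020()
  if (is.null(lab) || !setequal(lab, want) || anyDuplicated(lab))
    return("samples must carry each of the 19 10-20 electrode labels exactly once")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 60)
    return("fs must be a single value above 60 Hz (Nyquist for the 30 Hz band)")
  if (!all(is.finite(object@samples)))
    return("samples contain non-finite values")
  if (length(object@subjectAge) != 1L)
    return("subjectAge must be a single number (NA allowed)")
  TRUE
})

#' BipolarRecording: double-banana differential montage
#'
#' The 18 differential channels of the longitudinal bipolar montage, each the
#' elementwise difference of its two parent electrodes, in the fixed order
#' given by [bananaChannels()].
#'
#' @slot samples channels x time numeric matrix (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot subjectAge subject age in years (`NA` if unknown).
#' @export
setClass("BipolarRecording", contains = "EEGRecording")

setValidity("BipolarRecording", function(object) {
  if (!identical(rownames(object@samples), bananaChannels()))
    return("samples must have exactly the 18 double-banana channels, in montage order")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("fs must be a single positive value")
  if (!all(is.finite(object@samples)))
    return("samples contain non-finite values")
  TRUE
})

#' WindowSet: overlapping analysis windows of a bipolar record
#'
#' @slot windows array window x channel x sample (microvolts).
#' @slot starts first sample index (1-based) of each window.
#' @slot fs sampling rate in Hz.
#' @slot windowLen window length in seconds.
#' @slot overlap fractional overlap between consecutive windows.
#' @export
setClass("WindowSet",
  representation(windows = "array", starts = "numeric", fs = "numeric",
                 windowLen = "numeric", overlap = "numeric"))

setValidity("WindowSet", function(object) {
  if (length(dim(object@windows)) != 3L)
    return("windows must be a 3-d array (window x channel x sample)")
  if (dim(object@windows)[1L] != length(object@starts))
    return("starts must match the number of windows")
  if (object@overlap < 0 || object@overlap >= 1)
    return("overlap must lie in [0, 1)")
  TRUE
})

#' WindowedSpectrum: per-window one-sided power spectra
#'
#' Power spectral density estimates S(window, channel, frequency) in
#' microvolts squared per Hz on an equispaced frequency grid.
#'
#' @slot S array window x channel x frequency, all values >= 0.
#' @slot freqs frequency grid in Hz, strictly increasing, constant spacing.
#' @slot fs sampling rate of the underlying record, Hz.
#' @slot taper taper applied per window (`"hann"` or `"rect"`).
#' @export
setClass("WindowedSpectrum",
  representation(S = "array", freqs = "numeric", fs = "numeric",
                 taper = "character"))

setValidity("WindowedSpectrum", function(object) {
  if (length(dim(object@S)) != 3L)
    return("S must be a 3-d array (window x channel x frequency)")
  if (dim(object@S)[3L] != length(object@freqs))
    return("frequency axis of S must match freqs")
  if (any(object@S < 0))
    return("power spectral values must be non-negative")
  df <- diff(object@freqs)
  if (length(df) && (any(df <= 0) || diff(range(df)) > 1e-9))
    return("freqs must be strictly increasing with constant spacing")
  TRUE
})

#' CoherenceSpectrum: magnitude-squared coherence by channel pair
#'
#' @slot coh pair x frequency matrix of magnitude-squared coherence in [0, 1].
#' @slot pairs two-column character matrix of channel names.
#' @slot freqs frequency grid in Hz.
#' @slot nWindows number of windows averaged in the cross-spectra.
#' @export
setClass("CoherenceSpectrum",
  representation(coh = "matrix", pairs = "matrix", freqs = "numeric",
                 nWindows = "numeric"))

setValidity("CoherenceSpectrum", function(object) {
  if (nrow(object@coh) != nrow(object@pairs))
    return("one coherence row per channel pair required")
  if (ncol(object@coh) != length(object@freqs))
    return("frequency axis of coh must match freqs")
  if (any(object@coh < -1e-9 | object@coh > 1 + 1e-9))
    return("coherence must lie within [0, 1]")
  TRUE
})

#' NormativeEquation: age regression for a qEEG feature
#'
#' Either a polynomial in age (degree <= 3, coefficients in increasing power
#' order) or an offset plus decaying exponential
#' `a + b * exp(-c * age)` with coefficients `c(a, b, c)`.
#'
#' @slot feature name of the regressed feature.
#' @slot kind `"polynomial"` or `"exp_decay"`.
#' @slot coefficients numeric coefficients (see above).
#' @slot r correlation coefficient of the fit.
#' @slot n number of subjects behind the fit.
#' @slot ageRange validity range in years, `c(min, max)`.
#' @export
setClass("NormativeEquation",
  representation(feature = "character", kind = "character",
                 coefficients = "numeric", r = "numeric", n = "numeric",
                 ageRange = "numeric"))

setValidity("NormativeEquation", function(object) {
  if (!object@kind %in% c("polynomial", "exp_decay"))
    return(sprintf("unknown equation kind '%s'", object@kind))
  if (object@kind == "polynomial" && length(object@coefficients) > 4L)
    return("polynomial degree must be at most 3")
  if (object@kind == "exp_decay" && length(object@coefficients) != 3L)
    return("exp_decay needs coefficients c(offset, scale, rate)")
  if (length(object@r) == 1L && !is.na(object@r) && abs(object@r) > 1)
    return("fit correlation r must lie in [-1, 1]")
  if (length(object@ageRange) != 2L || object@ageRange[1L] > object@ageRange[2L])
    return("ageRange must be c(min, max)")
  TRUE
})

#' SubjectFeatures: the per-subject qEEG feature set
#'
#' Regional log band powers, spectral entropy, band coherence, and posterior
#' dominant rhythm measures for one subject, as produced by
#' [subjectFeatures()].
#'
#' @slot age subject age in years.
#' @slot logPS region x band matrix of log10 band power areas.
#' @slot sse named numeric, Shannon spectral entropy (bits) per region.
#' @slot coh region x band matrix of grouped band coherence.
#' @slot pdrFreq named numeric `c(left, right)`, posterior dominant rhythm, Hz.
#' @slot pdrAmp named numeric `c(left, right)`, RMS amplitude, microvolts.
#' @export
setClass("SubjectFeatures",
  representation(age = "numeric", logPS = "matrix", sse = "numeric",
                 coh = "matrix", pdrFreq = "numeric", pdrAmp = "numeric"))

setValidity("SubjectFeatures", function(object) {
  regions <- names(lobeGrouping("all"))
  if (!setequal(rownames(object@logPS), regions))
    return("logPS must cover all eight regions")
  if (!all(is.finite(object@logPS)) || !all(is.finite(object@sse)) ||
      !all(is.finite(object@coh)))
    return("feature values must be finite")
  TRUE
})
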