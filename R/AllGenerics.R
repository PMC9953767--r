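#' Accessors for EEG containers
#'
#' `samples()` returns the channels x time sample matrix, `samplingRate()`
#' the sampling rate in Hz, `channelLabels()` the channel names,
#' `subjectAge()` the subject's age in years, and `duration()` the record
#' length in seconds.
#'
#' @param object an EEG container object.
#' @return See description.
#' @name eeg-accessors
NULL

#' @rdname eeg-accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname eeg-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname eeg-accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))

#' @rdname eeg-accessors
#' @export
setGeneric("subjectAge", function(object) standardGeneric("subjectAge"))

#' @rdname eeg-accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))

#' @rdname eeg-accessors
#' @export
setMethod("samples", "EEGRecording", function(object) object@samples)

#' @rdname eeg-accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@fs)

#' @rdname eeg-accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(object) rownames(object@samples))

#' @rdname eeg-accessors
#' @export
setMethod("subjectAge", "EEGRecording", function(object) object@subjectAge)

#' @rdname eeg-accessors
#' @export
setMethod("duration", "EEGRecording",
  function(object) ncol(object@samples) / object@fs)

#' @rdname eeg-accessors
#' @export
setMethod("samplingRate", "WindowSet", function(object) object@fs)

#' @rdname eeg-accessors
#' @export
setMethod("channelLabels", "WindowSet", function(object) dimnames(object@windows)[[2L]])

#' Number of analysis windows
#' @param object a [WindowSet-class] or [WindowedSpectrum-class].
#' @return Integer window count.
#' @export
setGeneric("nWindows", function(object) standardGeneric("nWindows"))

#' @rdname nWindows
#' @export
setMethod("nWindows", "WindowSet", function(object) dim(object@windows)[1L])

#' @rdname nWindows
#' @export
setMethod("nWindows", "WindowedSpectrum", function(object) dim(object@S)[1L])

#' Frequency grid accessors
#'
#' `freqGrid()` returns the frequency axis in Hz; `freqStep()` its constant
#' spacing (the spectral precision, 0.5 Hz under the default configuration).
#'
#' @param object a [WindowedSpectrum-class] or [CoherenceSpectrum-class].
#' @return Numeric vector (grid) or single number (spacing).
#' @name freq-accessors
NULL

#' @rdname freq-accessors
#' @export
setGeneric("freqGrid", function(object) standardGeneric("freqGrid"))

#' @rdname freq-accessors
#' @export
setGeneric("freqStep", function(object) standardGeneric("freqStep"))

#' @rdname freq-accessors
#' @export
setMethod("freqGrid", "WindowedSpectrum", function(object) object@freqs)

#' @rdname freq-accessors
#' @export
setMethod("freqGrid", "CoherenceSpectrum", function(object) object@freqs)

#' @rdname freq-accessors
#' @export
setMethod("freqStep", "WindowedSpectrum",
  function(object) object@freqs[2L] - object@freqs[1L])

#' @rdname freq-accessors
#' @export
setMethod("freqStep", "CoherenceSpectrum",
  function(object) object@freqs[2L] - object@freqs[1L])

setMethod("show", "MonopolarRecording", function(object) {
  cat(sprintf("MonopolarRecording: %d channels, %.1f s at %g Hz, age %s\n",
              nrow(object@samples), duration(object), object@fs,
              ifelse(is.na(object@subjectAge), "unknown",
                     format(object@subjectAge))))
})

setMethod("show", "BipolarRecording", function(object) {
  cat(sprintf("BipolarRecording (double banana): %d channels, %.1f s at %g Hz\n",
              nrow(object@samples), duration(object), object@fs))
})

setMethod("show", "WindowSet", function(object) {
  d <- dim(object@windows)
  cat(sprintf("WindowSet: %d windows of %g s (%d samples), overlap %g%%, %d channels\n",
              d[1L], object@windowLen, d[3L], 100 * object@overlap, d[2L]))
})

setMethod("show", "WindowedSpectrum", function(object) {
  cat(sprintf(
    "WindowedSpectrum: %d windows x %d channels, %g-%g Hz at %g Hz steps (%s taper)\n",
    dim(object@S)[1L], dim(object@S)[2L], min(object@freqs), max(object@freqs),
    freqStep(object), object@taper))
})

setMethod("show", "CoherenceSpectrum", function(object) {
  cat(sprintf("CoherenceSpectrum: %d channel pairs, %d frequencies, %d windows averaged\n",
              nrow(object@pairs), length(object@freqs), object@nWindows))
})

setMethod("show", "NormativeEquation", function(object) {
  co <- object@coefficients
  eqn <- if (object@kind == "polynomial") {
    terms <- sprintf("%+g*years^%d", co[-1L], seq_along(co[-1L]))
    paste(c(format(co[1L]), if (length(co) > 1L) terms), collapse = " ")
  } else {
    sprintf("%g + %g*exp(-%g*years)", co[1L], co[2L], co[3L])
  }
  cat(sprintf("NormativeEquation [%s] %s = %s  (r = %s, n = %s, ages %g-%g)\n",
              object@kind, object@feature, eqn,
              format(object@r), format(object@n),
              object@ageRange[1L], object@ageRange[2L]))
})

setMethod("show", "SubjectFeatures", function(object) {
  cat(sprintf("SubjectFeatures: age %g; PDR %g/%g Hz (L/R), %g/%g uV RMS\n",
              object@age, object@pdrFreq[["left"]], object@pdrFreq[["right"]],
              round(object@pdrAmp[["left"]], 2), round(object@pdrAmp[["right"]], 2)))
  cat("logPS (region x band):\n")
  print(round(object@logPS, 3))
})
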