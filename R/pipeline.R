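#' Analysis pipeline configuration
#'
#' Collects every tunable of the pipeline with the defaults under which the
#' bundled normative values were derived: 0.5-30 Hz sixth-order Butterworth
#' band-pass, downsampling to 128 Hz, 1 s windows with 10% overlap, Hann
#' taper with x2 zero padding (0.5 Hz grid), decimal log transform, age-group
#' boundaries 20/50, and the nine-slot hemisphere policy.
#'
#' @param targetFs analysis sampling rate (Hz).
#' @param filterBand `c(low, high)` band-pass edges (Hz).
#' @param filterOrder Butterworth order per edge.
#' @param windowLen window length (s).
#' @param overlap fractional window overlap.
#' @param taper `"hann"` or `"rect"`.
#' @param padFactor zero-padding factor of the FFT.
#' @param bands named list of band edges (Hz).
#' @param sseSupport entropy support `c(low, high)` (Hz).
#' @param sseOrder `"per-window"` or `"mean-spectrum"`.
#' @param logBase base of the power log transform.
#' @param alphaRange PDR search band (Hz).
#' @param pdrAmpBand `NULL` for broadband RMS amplitude, or a band such as
#'   `c(8, 13)`.
#' @param hemispherePolicy `"slots"` or `"unique"` (see [groupCoherence()]).
#' @param ageBreaks age-group boundaries (years).
#' @param seed integer seed recorded with outputs.
#' @return A list of class `"qeegConfig"`.
#' @export
qeegConfig <- function(targetFs = 128, filterBand = c(0.5, 30),
                       filterOrder = 6L, windowLen = 1, overlap = 0.1,
                       taper = c("hann", "rect"), padFactor = 2L,
                       bands = eegBands(), sseSupport = c(0.5, 30),
                       sseOrder = c("per-window", "mean-spectrum"),
                       logBase = 10, alphaRange = c(8, 13),
                       pdrAmpBand = NULL,
                       hemispherePolicy = c("slots", "unique"),
                       ageBreaks = c(20, 50), seed = 1L) {
  cfg <- list(targetFs = targetFs, filterBand = filterBand,
              filterOrder = as.integer(filterOrder), windowLen = windowLen,
              overlap = overlap, taper = match.arg(taper),
              padFactor = as.integer(padFactor), bands = bands,
              sseSupport = sseSupport, sseOrder = match.arg(sseOrder),
              logBase = logBase, alphaRange = alphaRange,
              pdrAmpBand = pdrAmpBand,
              hemispherePolicy = match.arg(hemispherePolicy),
              ageBreaks = ageBreaks, seed = as.integer(seed))
  stopifnot(cfg$targetFs > 2 * cfg$filterBand[2L],
            cfg$windowLen > 0, cfg$overlap >= 0, cfg$overlap < 1,
            length(cfg$bands) >= 1L, cfg$logBase > 0,
            length(cfg$ageBreaks) == 2L, diff(cfg$ageBreaks) > 0)
  class(cfg) <- "qeegConfig"
  cfg
}

#' Write / read a pipeline configuration
#'
#' Serialized as YAML so every output directory carries the exact
#' parameters (and seed) needed to regenerate it.
#'
#' @param config a `"qeegConfig"` list.
#' @param path file path.
#' @return `readQeegConfig` returns the configuration.
#' @export
writeQeegConfig <- function(config, path) {
  stopifnot(inherits(config, "qeegConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeQeegConfig
#' @export
readQeegConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$taper <- raw$taper %||% "hann"
  raw$pdrAmpBand <- if (length(raw$pdrAmpBand)) unlist(raw$pdrAmpBand) else NULL
  do.call(qeegConfig, modifyList(
    raw, list(filterBand = unlist(raw$filterBand),
              bands = lapply(raw$bands, unlist),
              sseSupport = unlist(raw$sseSupport),
              alphaRange = unlist(raw$alphaRange),
              ageBreaks = unlist(raw$ageBreaks))))
}

# channel pairs needed for the regional coherence averages
.neededPairs <- function(hemispherePolicy = "slots") {
  regions <- lobeGrouping("all")
  keys <- unique(unlist(lapply(names(regions), function(r) {
    dedupe <- if (startsWith(r, "H_")) hemispherePolicy else "slots"
    .regionPairKeys(regions[[r]], dedupe)
  })))
  do.call(rbind, strsplit(keys, "|", fixed = TRUE))
}

#' Extract the full qEEG feature set of one subject
#'
#' Runs the complete analysis chain on a recording: band-pass filtering and
#' downsampling, double-banana montage reconstruction, windowing, power
#' spectra, band areas with decimal log transform, Shannon spectral entropy,
#' pairwise band coherence, regional averaging, and the posterior dominant
#' rhythm frequency and RMS amplitude.
#'
#' @param rec a [MonopolarRecording-class] (preprocessed internally) or an
#'   already-preprocessed [BipolarRecording-class].
#' @param age subject age in years; defaults to the recording's age.
#' @param config a [qeegConfig()] list.
#' @return A [SubjectFeatures-class].
#' @export
subjectFeatures <- function(rec, age = NULL, config = qeegConfig()) {
  stopifnot(inherits(config, "qeegConfig"))
  if (is.null(age)) age <- subjectAge(rec)
  if (is(rec, "MonopolarRecording")) {
    pre <- preprocessRecording(rec, targetFs = config$targetFs,
                               band = config$filterBand,
                               order = config$filterOrder)
    bip <- doubleBanana(pre)
  } else if (is(rec, "BipolarRecording")) {
    bip <- rec
  } else stop("rec must be a MonopolarRecording or BipolarRecording")

  ws <- makeWindows(bip, windowLen = config$windowLen,
                    overlap = config$overlap)
  spec <- powerSpectrum(ws, taper = config$taper,
                        padFactor = config$padFactor)

  areas <- bandAreas(spec, bands = config$bands)          # channel x band
  logPS <- groupFeatures(logTransform(areas, base = config$logBase),
                         "all", config$hemispherePolicy)
  sse <- groupFeatures(
    spectralEntropy(spec, support = config$sseSupport, order = config$sseOrder),
    "all", config$hemispherePolicy)

  cs <- coherenceSpectrum(ws, pairs = .neededPairs(config$hemispherePolicy),
                          taper = config$taper, padFactor = config$padFactor)
  coh <- groupCoherence(bandCoherence(cs, bands = config$bands), "all",
                        config$hemispherePolicy)

  pdrFreq <- c(left = pdrFrequency(spec, "P3-O1", config$alphaRange),
               right = pdrFrequency(spec, "P4-O2", config$alphaRange))
  pdrAmp <- c(left = rmsAmplitude(bip, "P3-O1", band = config$pdrAmpBand),
              right = rmsAmplitude(bip, "P4-O2", band = config$pdrAmpBand))

  new("SubjectFeatures", age = as.numeric(age), logPS = logPS, sse = sse,
      coh = coh, pdrFreq = pdrFreq, pdrAmp = pdrAmp)
}

#' Flatten subject features to a named vector / cohort table
#'
#' `featureVector()` flattens one [SubjectFeatures-class] into a named
#' numeric vector (`logPS.F_left.delta`, `sse.PO_right`,
#' `coh.T_left.alpha`, `pdr.freq.left`, `pdr.amp.right`, ...);
#' `featureTable()` stacks a cohort into a data.frame with an `age` column.
#'
#' @param features a [SubjectFeatures-class].
#' @param cohort list of [SubjectFeatures-class].
#' @return Named numeric vector / data.frame.
#' @export
featureVector <- function(features) {
  stopifnot(is(features, "SubjectFeatures"))
  flat <- function(m, prefix) {
    v <- as.vector(t(m))
    names(v) <- paste(prefix, rep(rownames(m), each = ncol(m)),
                      rep(colnames(m), nrow(m)), sep = ".")
    v
  }
  c(flat(features@logPS, "logPS"),
    setNames(features@sse, paste0("sse.", names(features@sse))),
    flat(features@coh, "coh"),
    setNames(features@pdrFreq, paste0("pdr.freq.", names(features@pdrFreq))),
    setNames(features@pdrAmp, paste0("pdr.amp.", names(features@pdrAmp))))
}

#' @rdname featureVector
#' @export
featureTable <- function(cohort) {
  stopifnot(length(cohort) >= 1L,
            all(vapply(cohort, is, TRUE, "SubjectFeatures")))
  rows <- lapply(cohort, featureVector)
  tab <- as.data.frame(do.call(rbind, rows))
  data.frame(subject = seq_along(cohort),
             age = vapply(cohort, function(f) f@age, 0), tab,
             check.names = FALSE)
}
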