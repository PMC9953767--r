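# per-lobe shared-source gain profiles. Each lobe's source is injected at
# two lobe-exclusive parent electrodes with opposite signs — the unique
# montage-graph solution in which every in-lobe bipolar channel picks up
# its lobe's source (gains 2, -1, 1 along the chain) while no channel of a
# neighbouring lobe receives it at all; injecting at junction electrodes
# (C3, F7, T5, O1) instead would push, e.g., posterior alpha into the
# frontal channel F3-C3 at full posterior amplitude, which is incompatible
# with the frontal band-power targets. The double-membership channel T5-O1
# legitimately carries both the parieto-occipital and the temporal source.
.GEN_SHARED <- list(
  F_left   = c(Fp1 = 1, F3 = -1),
  PO_left  = c(P3 = -1, O1 = 1),
  T_left   = c(T3 = -1, T5 = 1),
  F_right  = c(Fp2 = 1, F4 = -1),
  PO_right = c(P4 = -1, O2 = 1),
  T_right  = c(T4 = -1, T6 = 1))

# lobes whose bipolar channels an electrode parents; junction electrodes
# belong to two lobes and receive the geometric mean of their lobes'
# source amplitudes (the spatial amplitude gradient that keeps, e.g.,
# posterior alpha from flooding cross-boundary channels)
.GEN_MEMBERSHIP <- list(
  Fp1 = "F_left", F3 = "F_left", C3 = c("F_left", "PO_left"),
  P3 = "PO_left", O1 = c("PO_left", "T_left"), F7 = c("F_left", "T_left"),
  T3 = "T_left", T5 = c("T_left", "PO_left"),
  Fp2 = "F_right", F4 = "F_right", C4 = c("F_right", "PO_right"),
  P4 = "PO_right", O2 = c("PO_right", "T_right"), F8 = c("F_right", "T_right"),
  T4 = "T_right", T6 = c("T_right", "PO_right"),
  Fz = character(), Cz = character(), Pz = character())

.LOBE_REGIONS <- c("F_left", "PO_left", "T_left",
                   "F_right", "PO_right", "T_right")

# unit-variance band-limited Gaussian noise (zero-phase Butterworth edges,
# same filter family as the analysis band-pass). Steep order-8 edges keep
# the source's power inside its band; the delta band keeps order 6 because
# higher orders are numerically degraded at cut-offs this far below the
# sampling rate.
.bandNoise <- function(n, fs, band,
                       order = if (band[1L] < 4) 6L else 8L) {
  x <- .bandpassFiltfilt(rnorm(n), fs, band, order = order)
  x / sd(x)
}

# source bands are inset from the nominal band edges: the 1 s analysis
# windows smear spectral power by about +/-1 Hz (the Hann main-lobe
# half-width at 1 s windows), so noise generated right up to a band edge
# would be partly attributed to the neighbouring band. Beta is additionally
# kept below 24 Hz because the zero-phase sixth-order 30 Hz analysis
# low-pass already attenuates 24-30 Hz content materially (power gain
# |H|^4 < 0.9), which would make any power placed there unrecoverable.
.GENERATOR_BANDS <- list(delta = c(1.5, 3), theta = c(5, 7),
                         alpha = c(10, 12), beta = c(14.5, 24))

#' Specification of one synthetic rsEEG subject
#'
#' Parameter set consumed by [generateSubject()]. Defaults are
#' age-parameterized from the bundled normative references: regional band
#' power targets are `10^logPS` of the subject age group's group means,
#' within-lobe shared-source fractions come from the age group's band
#' coherences, and the posterior dominant rhythm frequency and amplitude
#' follow the bundled age regressions.
#'
#' @param age subject age in years.
#' @param seed integer seed; the recording is bit-reproducible given the
#'   spec.
#' @param duration record length in seconds.
#' @param fs sampling rate in Hz.
#' @param bandPower 6 x 4 matrix (lobe regions x bands) of target bipolar
#'   band-power areas in microvolts squared, or `NULL` for age defaults.
#' @param sharedFraction 6 x 4 matrix in [0, 1] controlling within-lobe
#'   coherence, or `NULL` for age defaults.
#' @param pdrFreq posterior dominant rhythm frequency in Hz (8-13).
#' @param pdrAmp `c(left, right)` RMS amplitude of the posterior oscillator
#'   on the posterior bipolar channels, microvolts.
#' @param sourceBands named list of `c(low, high)` source-noise bands, one
#'   per EEG band; `NULL` for the package defaults (each inset from the
#'   nominal band edges, see the methods vignette). Controls spectral
#'   concentration without changing band-power targets.
#' @return List of class `"subjectSpec"`.
#' @export
subjectSpec <- function(age, seed = 1L, duration = 180, fs = 512,
                        bandPower = NULL, sharedFraction = NULL,
                        pdrFreq = NULL, pdrAmp = NULL, sourceBands = NULL) {
  grp <- as.character(suppressWarnings(assignAgeGroup(age)))
  bands <- names(eegBands())
  if (is.null(bandPower)) {
    tab <- logPSGroupMeans()
    tab <- tab[tab$age_group == grp, ]
    bandPower <- matrix(NA_real_, 6L, 4L,
                        dimnames = list(.LOBE_REGIONS, bands))
    for (r in .LOBE_REGIONS) {
      parts <- strsplit(r, "_")[[1L]]
      sel <- tab[tab$lobe == parts[1L] & tab$hemisphere == parts[2L], ]
      bandPower[r, sel$band] <- 10^sel$mean
    }
  }
  if (is.null(sharedFraction)) {
    tab <- coherenceGroupMeans()
    tab <- tab[tab$age_group == grp & tab$region != "H", ]
    sharedFraction <- matrix(NA_real_, 6L, 4L,
                             dimnames = list(.LOBE_REGIONS, bands))
    for (r in .LOBE_REGIONS) {
      parts <- strsplit(r, "_")[[1L]]
      sel <- tab[tab$region == parts[1L] & tab$hemisphere == parts[2L], ]
      sharedFraction[r, sel$band] <- sel$mean
    }
  }
  bundle <- normativeBundle()
  if (is.null(pdrFreq))
    pdrFreq <- min(13, max(8, evaluateNormative(bundle$pdr.freq.left, age,
                                                warn = FALSE)))
  if (is.null(pdrAmp))
    pdrAmp <- c(left = evaluateNormative(bundle$pdr.amp.left, age, warn = FALSE),
                right = evaluateNormative(bundle$pdr.amp.right, age, warn = FALSE))
  shape <- function(m, what) {
    m <- as.matrix(m)
    if (!identical(dim(m), c(6L, 4L)))
      stop(what, " must be a 6 x 4 (lobe region x band) matrix")
    if (!is.null(rownames(m)) && setequal(rownames(m), .LOBE_REGIONS))
      m <- m[.LOBE_REGIONS, , drop = FALSE]
    if (!is.null(colnames(m)) && setequal(colnames(m), bands))
      m <- m[, bands, drop = FALSE]
    dimnames(m) <- list(.LOBE_REGIONS, bands)
    m
  }
  bandPower <- shape(bandPower, "bandPower")
  sharedFraction <- shape(sharedFraction, "sharedFraction")
  if (any(bandPower < 0) || any(!is.finite(bandPower)) || all(bandPower == 0))
    stop("band power targets must be non-negative (and not all zero)")
  if (any(sharedFraction < 0 | sharedFraction > 1))
    stop("shared fractions must lie in [0, 1]")
  if (pdrFreq < 8 || pdrFreq > 13)
    stop("pdrFreq must lie within the alpha band (8-13 Hz)")
  if (is.null(sourceBands)) sourceBands <- .GENERATOR_BANDS
  stopifnot(identical(names(sourceBands), names(.GENERATOR_BANDS)))
  for (j in names(sourceBands)) {
    nominal <- eegBands()[[j]]
    b <- sourceBands[[j]]
    if (b[1L] >= b[2L] || b[1L] < nominal[1L] || b[2L] > nominal[2L])
      stop("source band for ", j, " must lie inside ",
           nominal[1L], "-", nominal[2L], " Hz")
  }
  structure(list(age = age, seed = as.integer(seed), duration = duration,
                 fs = fs, bandPower = bandPower,
                 sharedFraction = sharedFraction, pdrFreq = pdrFreq,
                 pdrAmp = pdrAmp, sourceBands = sourceBands),
            class = "subjectSpec")
}

#' Generate a synthetic eye-closed rsEEG recording
#'
#' Builds a 19-electrode monopolar recording in which every electrode is a
#' sum over the four EEG bands of `sqrt(1 - c) * private + sqrt(c) *
#' regional-shared` band-limited Gaussian noise (c the lobe's shared-source
#' fraction; each lobe's source enters at two lobe-exclusive electrodes
#' with opposite signs so it survives the bipolar derivation without
#' leaking into neighbouring lobes), plus a posterior narrowband oscillator
#' at the target posterior-dominant-rhythm frequency injected at O1/O2.
#' Junction electrodes take the geometric mean of their lobes' amplitudes
#' (a spatial amplitude gradient). Source amplitudes are calibrated
#' iteratively (up to 5 passes, the later ones against the full analysis
#' chain) so the measured band power of the derived bipolar lobe channels
#' matches the targets after derivation.
#'
#' @param spec a [subjectSpec()].
#' @param calibrate number of calibration passes (0 disables).
#' @return List with `recording` (a [MonopolarRecording-class]) and `truth`
#'   (ground-truth regional band areas in microvolts squared, including the
#'   oscillator's analytic contribution to the alpha band, plus the target
#'   PDR frequency/amplitude and shared fractions).
#' @export
generateSubject <- function(spec, calibrate = 5L) {
  stopifnot(inherits(spec, "subjectSpec"))
  set.seed(spec$seed)
  fs <- spec$fs
  n <- round(spec$duration * fs)
  bands <- eegBands()
  electrodes <- electrodes1020()
  nE <- length(electrodes)

  # unit-variance composite sources per band: U[e, ] = sqrt(1-c)*private +
  # sign(e)*sqrt(c)*shared(region(e)); midline electrodes are private-only
  srcBands <- spec$sourceBands %||% .GENERATOR_BANDS
  # which lobe's shared source (if any) each electrode carries
  carrier <- lapply(setNames(electrodes, electrodes), function(e)
    names(.GEN_SHARED)[vapply(.GEN_SHARED, function(g) e %in% names(g), TRUE)])
  U <- vector("list", length(bands))
  names(U) <- names(bands)
  for (j in names(bands)) {
    shared <- sapply(.LOBE_REGIONS,
                     function(r) .bandNoise(n, fs, srcBands[[j]]))
    Uj <- matrix(0, nE, n, dimnames = list(electrodes, NULL))
    for (e in electrodes) {
      member <- .GEN_MEMBERSHIP[[e]]
      priv <- .bandNoise(n, fs, srcBands[[j]])
      if (!length(member)) {               # midline: background only
        Uj[e, ] <- priv
        next
      }
      cbar <- mean(spec$sharedFraction[member, j])
      contrib <- 0
      r0 <- carrier[[e]]
      if (length(r0) == 1L)
        contrib <- .GEN_SHARED[[r0]][[e]] *
          sqrt(spec$sharedFraction[r0, j]) * shared[, r0]
      Uj[e, ] <- sqrt(1 - cbar) * priv + contrib
    }
    U[[j]] <- Uj
  }

  # initial source scales from the analytic variance of an in-lobe bipolar
  # difference (mean squared shared gain over a chain is 2, private part
  # contributes 2 as well); then calibrate on the realized post-derivation
  # band power of each lobe's three channels
  sigma <- sqrt(spec$bandPower / 2)
  sigmaMid <- colMeans(sigma[c("F_left", "F_right"), , drop = FALSE])

  pairs <- bananaPairs()
  lobes <- lobeGrouping("lobes")
  chanNames <- bananaChannels()
  elecSigma <- function(sg) {
    s <- matrix(NA_real_, nE, length(bands),
                dimnames = list(electrodes, names(bands)))
    for (e in electrodes) {
      member <- .GEN_MEMBERSHIP[[e]]
      s[e, ] <- if (!length(member)) sigmaMid
                else exp(colMeans(log(sg[member, , drop = FALSE])))
    }
    s
  }
  channelBandVar <- function(sg) {
    es <- elecSigma(sg)
    out <- matrix(NA_real_, length(chanNames), length(bands),
                  dimnames = list(chanNames, names(bands)))
    for (j in names(bands)) {
      comp <- es[pairs[, 1L], j] * U[[j]][pairs[, 1L], , drop = FALSE] -
              es[pairs[, 2L], j] * U[[j]][pairs[, 2L], , drop = FALSE]
      out[, j] <- apply(comp, 1L, var)
    }
    out
  }
  updateSigma <- function(sigma, realizedByLobe) {
    for (r in .LOBE_REGIONS) {
      realized <- realizedByLobe[r, ]
      ratio <- ifelse(realized > 0, spec$bandPower[r, ] / realized,
                      ifelse(spec$bandPower[r, ] == 0, 1, NA_real_))
      if (any(!is.finite(ratio)))
        stop("infeasible band power combination for region ", r)
      sigma[r, ] <- sigma[r, ] * sqrt(ratio)
    }
    sigma
  }
  buildV <- function(sg) {
    es <- elecSigma(sg)
    V <- matrix(0, nE, n, dimnames = list(electrodes, NULL))
    for (j in names(bands)) V <- V + es[, j] * U[[j]]
    V
  }
  lobeMeans <- function(m) t(vapply(lobes, function(ch)
    colMeans(m[ch, , drop = FALSE]), numeric(length(bands))))[.LOBE_REGIONS, ,
                                                              drop = FALSE]
  # measured band areas of the derived bipolar lobe channels through the
  # actual analysis chain (filtering, decimation, Hann-windowed spectra):
  # calibrating against the chain itself also compensates the estimator's
  # cross-band kernel leakage, which is not negligible where a neighbouring
  # band is an order of magnitude stronger
  measureLobeAreas <- function(sg) {
    rec <- monopolarRecording(buildV(sg), fs = fs, age = spec$age)
    bip <- doubleBanana(preprocessRecording(rec))
    A <- bandAreas(powerSpectrum(makeWindows(bip)))
    lobeMeans(A)
  }

  # two cheap passes on the component variances, then the remaining passes
  # against the full analysis chain
  nCheap <- min(2L, calibrate)
  for (it in seq_len(nCheap)) {
    sigma <- updateSigma(sigma, lobeMeans(channelBandVar(sigma)))
    sigmaMid <- colMeans(sigma[c("F_left", "F_right"), , drop = FALSE])
  }
  for (it in seq_len(max(0L, calibrate - nCheap))) {
    sigma <- updateSigma(sigma, measureLobeAreas(sigma))
    sigmaMid <- colMeans(sigma[c("F_left", "F_right"), , drop = FALSE])
  }

  V <- buildV(sigma)

  # posterior oscillator: injected at O1/O2 so the posterior bipolar
  # channels (P3-O1, T5-O1 / P4-O2, T6-O2) carry it at the target RMS
  tt <- seq_len(n) / fs
  oscL <- sqrt(2) * spec$pdrAmp[["left"]] *
    sin(2 * pi * spec$pdrFreq * tt + runif(1, 0, 2 * pi))
  oscR <- sqrt(2) * spec$pdrAmp[["right"]] *
    sin(2 * pi * spec$pdrFreq * tt + runif(1, 0, 2 * pi))
  V["O1", ] <- V["O1", ] + oscL
  V["O2", ] <- V["O2", ] + oscR

  rec <- monopolarRecording(V, fs = fs, age = spec$age)

  # ground truth: realized band power of every bipolar channel (variance of
  # its calibrated band components) plus the oscillator's analytic alpha
  # contribution on the channels that contain O1/O2; regional areas are the
  # arithmetic slot means of the channel areas
  chanArea <- channelBandVar(sigma)
  oscChans <- list(left = c("P3-O1", "T5-O1"), right = c("P4-O2", "T6-O2"))
  for (side in c("left", "right"))
    chanArea[oscChans[[side]], "alpha"] <-
      chanArea[oscChans[[side]], "alpha"] + spec$pdrAmp[[side]]^2
  regions <- lobeGrouping("all")
  truthArea <- t(vapply(regions,
                        function(ch) colMeans(chanArea[ch, , drop = FALSE]),
                        numeric(length(bands))))
  # lobe-level targets the calibration aimed at, plus the oscillator's
  # analytic contribution on the channels it reaches
  targetArea <- spec$bandPower
  for (side in c("left", "right")) for (r in .LOBE_REGIONS) {
    hits <- sum(lobes[[r]] %in% oscChans[[side]])
    targetArea[r, "alpha"] <- targetArea[r, "alpha"] +
      hits * spec$pdrAmp[[side]]^2 / length(lobes[[r]])
  }

  list(recording = rec,
       truth = list(age = spec$age, bandArea = truthArea,
                    channelBandArea = chanArea,
                    targetBandArea = targetArea,
                    pdrFreq = spec$pdrFreq, pdrAmp = spec$pdrAmp,
                    sharedFraction = spec$sharedFraction, spec = spec))
}

#' Draw per-subject (and per-session) specs for a synthetic cohort
#'
#' Subjects receive individual parameters scattered around the age-group
#' normative defaults: log10 band powers (independent per region and band,
#' plus a global amplitude gain common to all bands, reflecting the large
#' stable inter-individual amplitude differences of scalp EEG), shared
#' fractions, and PDR frequency/amplitude around the bundled age curves.
#' With `sessions = 2` each subject additionally receives small session-level
#' perturbations of the same parameters, emulating physiological state
#' changes between test and retest; noise seeds always differ per session.
#'
#' @param n number of subjects.
#' @param seed master seed; all subject/session seeds derive from it.
#' @param ages optional explicit ages; otherwise uniform over `ageRange`.
#' @param ageRange age sampling range in years.
#' @param duration,fs passed to [subjectSpec()].
#' @param sessions recordings per subject (1 or 2).
#' @param subjectSd between-subject SDs: `logPower` (dex, per region x
#'   band), `logGain` (dex, global), `shared`, `pdrFreq` (Hz),
#'   `logPdrAmp` (dex).
#' @param sessionSd within-subject between-session SDs, same elements.
#' @return List of subjects; each subject is a list of per-session
#'   [subjectSpec()]s with the subject's `age` attached.
#' @export
cohortSpecs <- function(n, seed = 1L, ages = NULL, ageRange = c(10, 74),
                        duration = 180, fs = 512, sessions = 1L,
                        subjectSd = list(logPower = 0.25, logGain = 0.2,
                                         shared = 0.05, pdrFreq = 0.5,
                                         logPdrAmp = 0.1, srcWidth = 0.25),
                        sessionSd = list(logPower = 0.05, logGain = 0.03,
                                         shared = 0.03, pdrFreq = 0.25,
                                         logPdrAmp = 0.02, srcWidth = 0.15)) {
  stopifnot(n >= 1L)
  set.seed(seed)
  if (is.null(ages)) ages <- runif(n, ageRange[1L], ageRange[2L])
  stopifnot(length(ages) == n)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, n * sessions),
                  nrow = n)
  bundle <- normativeBundle()
  clamp <- function(x, lo, hi) { x[x < lo] <- lo; x[x > hi] <- hi; x }
  lapply(seq_len(n), function(i) {
    base <- subjectSpec(ages[i], seed = seeds[i, 1L], duration = duration,
                        fs = fs)
    logP <- log10(base$bandPower) +
      matrix(rnorm(24, 0, subjectSd$logPower), 6, 4) +
      rnorm(1, 0, subjectSd$logGain)
    shared <- clamp(base$sharedFraction +
                      matrix(rnorm(24, 0, subjectSd$shared), 6, 4),
                    0.01, 0.95)
    pf <- clamp(base$pdrFreq + rnorm(1, 0, subjectSd$pdrFreq), 8, 13)
    pa <- base$pdrAmp * 10^rnorm(1, 0, subjectSd$logPdrAmp)
    # spectral concentration: per-subject (and per-session) width factors
    # for the theta/alpha/beta source bands; band-power targets unchanged,
    # entropy responds to the concentration
    widthSubj <- clamp(1 + rnorm(3, 0, subjectSd$srcWidth), 0.55, 1.35)
    srcBandsFor <- function(widths) {
      out <- .GENERATOR_BANDS
      for (k in seq_along(c("theta", "alpha", "beta"))) {
        j <- c("theta", "alpha", "beta")[k]
        b <- .GENERATOR_BANDS[[j]]
        centre <- mean(b); half <- diff(b) / 2 * widths[k]
        lim <- eegBands()[[j]]
        out[[j]] <- c(max(lim[1] + 0.25, centre - half),
                      min(lim[2] - 0.25, centre + half))
      }
      out
    }
    sess <- lapply(seq_len(sessions), function(s) {
      dLogP <- matrix(rnorm(24, 0, sessionSd$logPower), 6, 4) +
        rnorm(1, 0, sessionSd$logGain)
      widths <- if (sessions > 1L)
        clamp(widthSubj + rnorm(3, 0, sessionSd$srcWidth), 0.5, 1.4)
      else widthSubj
      spec <- subjectSpec(
        ages[i], seed = seeds[i, s], duration = duration, fs = fs,
        bandPower = 10^(logP + if (sessions > 1L) dLogP else 0),
        sharedFraction = clamp(shared + if (sessions > 1L)
          matrix(rnorm(24, 0, sessionSd$shared), 6, 4) else 0, 0.01, 0.95),
        pdrFreq = clamp(pf + if (sessions > 1L)
          rnorm(1, 0, sessionSd$pdrFreq) else 0, 8, 13),
        pdrAmp = pa * 10^(if (sessions > 1L)
          rnorm(1, 0, sessionSd$logPdrAmp) else 0),
        sourceBands = srcBandsFor(widths))
      spec
    })
    structure(sess, age = ages[i])
  })
}

#' Generate a synthetic cohort of recordings
#'
#' Calls [generateSubject()] for every subject spec drawn by
#' [cohortSpecs()] and collects the recordings with their ground truth.
#'
#' @inheritParams cohortSpecs
#' @param ... further arguments passed to [cohortSpecs()].
#' @return List with `subjects` (per subject: list(recording, truth), first
#'   session only), `ages`, and `truth` (data.frame of ground-truth features
#'   per subject).
#' @export
generateCohort <- function(n, seed = 1L, ..., duration = 180) {
  specs <- cohortSpecs(n, seed = seed, duration = duration, ...)
  subjects <- lapply(specs, function(s) generateSubject(s[[1L]]))
  truth <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    tr <- subjects[[i]]$truth
    data.frame(subject = i, age = tr$age, pdrFreq = tr$pdrFreq,
               pdrAmpLeft = tr$pdrAmp[["left"]],
               pdrAmpRight = tr$pdrAmp[["right"]])
  }))
  list(subjects = subjects, ages = vapply(specs, attr, 0, "age"),
       truth = truth)
}

#' Simulate a feature-level cohort from the normative equations
#'
#' Draws per-subject feature values directly from the bundled normative age
#' regressions plus Gaussian residual noise, without synthesizing raw EEG.
#' Used for regression-recovery studies (e.g. refitting the PDR cubic from
#' n = 200 simulated subjects with 0.5 Hz residuals).
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param ageRange age sampling range in years.
#' @param noiseSd named residual SDs by feature family: `pdr.freq` (Hz),
#'   `sse` (bits), `pdr.amp` (dex, lognormal).
#' @param bundle equation bundle (default shipped).
#' @return data.frame with `age` and one column per bundle equation.
#' @export
simulateFeatureCohort <- function(n, seed = 1L, ageRange = c(10, 74),
                                  noiseSd = c("pdr.freq" = 0.5, "sse" = 0.4,
                                              "pdr.amp" = 0.1),
                                  bundle = normativeBundle()) {
  set.seed(seed)
  age <- runif(n, ageRange[1L], ageRange[2L])
  out <- data.frame(age = age)
  for (f in names(bundle)) {
    mu <- evaluateNormative(bundle[[f]], age, warn = FALSE)
    fam <- if (startsWith(f, "pdr.freq")) "pdr.freq"
           else if (startsWith(f, "pdr.amp")) "pdr.amp" else "sse"
    out[[f]] <- if (fam == "pdr.amp") mu * 10^rnorm(n, 0, noiseSd[[fam]])
                else mu + rnorm(n, 0, noiseSd[[fam]])
  }
  out
}
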