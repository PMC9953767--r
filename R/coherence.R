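.pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Magnitude-squared coherence between channel pairs
#'
#' Estimates `Coh(w) = |<S_ij>|^2 / (<S_ii> <S_jj>)` where `S_ij` is the
#' cross-spectrum of the two channels and `<...>` averages over all analysis
#' windows; the cross-spectrum is averaged before the modulus is taken.
#' Auto- and cross-spectra come from the same tapered, zero-padded windowed
#' FFT as [powerSpectrum()], so all spectral estimators share one estimator
#' family. The estimate is bounded in [0, 1] and, for independent signals,
#' biased upward by about `1/nWindows`.
#'
#' @param ws a [WindowSet-class] with at least 2 windows (the coherence of a
#'   single window is identically 1).
#' @param pairs two-column character matrix of channel names, or `NULL` for
#'   all unordered pairs of distinct channels.
#' @param taper,padFactor passed to the shared windowed FFT (see
#'   [powerSpectrum()]).
#' @return A [CoherenceSpectrum-class].
#' @export
coherenceSpectrum <- function(ws, pairs = NULL, taper = c("hann", "rect"),
                              padFactor = 2L) {
  stopifnot(is(ws, "WindowSet"))
  taper <- match.arg(taper)
  if (dim(ws@windows)[1L] < 2L)
    stop("coherence needs at least 2 windows")
  ft <- .windowedFFT(ws, taper, padFactor)
  labels <- ft$labels
  if (is.null(pairs)) {
    pairs <- t(utils::combn(labels, 2L))
  } else {
    pairs <- as.matrix(pairs)
    unknown <- setdiff(unique(c(pairs)), labels)
    if (length(unknown))
      stop("unknown channel(s) in pairs: ", paste(unknown, collapse = ", "))
  }
  nFreq <- length(ft$freqs)
  # reshape FFT columns back into freq x window blocks per channel
  chanFFT <- lapply(seq_len(ft$nChan), function(ch) {
    cols <- ((ch - 1L) * ft$nWin + 1L):(ch * ft$nWin)
    ft$X[, cols, drop = FALSE]       # nFreq x nWin, complex
  })
  names(chanFFT) <- labels
  auto <- lapply(chanFFT, function(X) rowMeans(Mod(X)^2))
  coh <- matrix(NA_real_, nrow = nrow(pairs), ncol = nFreq)
  for (p in seq_len(nrow(pairs))) {
    Xi <- chanFFT[[pairs[p, 1L]]]
    Xj <- chanFFT[[pairs[p, 2L]]]
    cross <- rowMeans(Xi * Conj(Xj))
    denom <- auto[[pairs[p, 1L]]] * auto[[pairs[p, 2L]]]
    bad <- denom <= 0
    v <- Mod(cross)^2 / ifelse(bad, NA_real_, denom)
    if (any(bad)) {
      warning(sprintf("pair %s-%s: %d zero auto-spectrum bin(s) masked",
                      pairs[p, 1L], pairs[p, 2L], sum(bad)))
      v[bad] <- NA_real_
    }
    coh[p, ] <- pmin(pmax(v, 0), 1)
  }
  rownames(coh) <- .pairKey(pairs[, 1L], pairs[, 2L])
  new("CoherenceSpectrum", coh = coh, pairs = pairs, freqs = ft$freqs,
      nWindows = ft$nWin)
}

#' Band coherence
#'
#' Reduces the coherence spectrum to one value per band as the unweighted
#' mean of `Coh(w)` over the band's frequency bins, with shared band edges
#' assigned to the lower band (same rule as [bandAreas()]).
#'
#' @param cs a [CoherenceSpectrum-class].
#' @param bands named list of band edges (Hz), default [eegBands()].
#' @return pair x band numeric matrix in [0, 1]; rownames are
#'   `"chanA|chanB"` keys.
#' @export
bandCoherence <- function(cs, bands = eegBands()) {
  stopifnot(is(cs, "CoherenceSpectrum"))
  bins <- .bandBins(cs@freqs, bands)
  empty <- names(bands)[vapply(bins, length, 0L) == 0L]
  if (length(empty))
    stop("no frequency bins in band(s): ", paste(empty, collapse = ", "))
  out <- vapply(bins, function(ix)
    rowMeans(cs@coh[, ix, drop = FALSE], na.rm = TRUE),
    numeric(nrow(cs@coh)))
  out <- matrix(out, nrow = nrow(cs@coh),
                dimnames = list(rownames(cs@coh), names(bands)))
  out
}

# pair keys for one region: all unordered pairs of the region's channel
# slots, with pairs of a duplicated channel against itself dropped
.regionPairKeys <- function(channels, dedupe = c("slots", "unique")) {
  dedupe <- match.arg(dedupe)
  if (dedupe == "unique") channels <- unique(channels)
  idx <- utils::combn(seq_along(channels), 2L)
  a <- channels[idx[1L, ]]
  b <- channels[idx[2L, ]]
  keep <- a != b                      # self-pairs from duplicated slots
  .pairKey(a[keep], b[keep])
}

#' Group band coherence by lobe and hemisphere
#'
#' Averages pairwise band coherences over all channel pairs of each region:
#' 3 pairs per lobe (3 channels) and the hemisphere pairs formed from the
#' nine hemisphere slots (36 slot pairs, of which the self-pair of the
#' duplicated posterior channel is dropped). `hemispherePolicy = "unique"`
#' instead uses the 8 distinct hemisphere channels (28 pairs).
#'
#' @param bc pair x band matrix from [bandCoherence()].
#' @param grouping `"lobes"`, `"hemispheres"`, or `"all"`.
#' @param hemispherePolicy `"slots"` (default) or `"unique"`.
#' @return region x band numeric matrix.
#' @export
groupCoherence <- function(bc, grouping = c("all", "lobes", "hemispheres"),
                           hemispherePolicy = c("slots", "unique")) {
  grouping <- match.arg(grouping)
  hemispherePolicy <- match.arg(hemispherePolicy)
  regions <- lobeGrouping(grouping)
  out <- matrix(NA_real_, nrow = length(regions), ncol = ncol(bc),
                dimnames = list(names(regions), colnames(bc)))
  for (r in names(regions)) {
    dedupe <- if (startsWith(r, "H_")) hemispherePolicy else "slots"
    keys <- .regionPairKeys(regions[[r]], dedupe)
    missing <- setdiff(unique(keys), rownames(bc))
    if (length(missing))
      stop("coherence values missing for pair(s): ",
           paste(missing, collapse = ", "))
    out[r, ] <- colMeans(bc[keys, , drop = FALSE])
  }
  out
}

#' Pair count for a region of Nch channels
#'
#' `Npairs = Nch * (Nch - 1) / 2`: 3 pairs for a 3-channel lobe, 36 for a
#' 9-slot hemisphere.
#'
#' @param nch number of channels (slots) in the region.
#' @return Integer pair count.
#' @export
nPairs <- function(nch) as.integer(nch * (nch - 1) / 2)
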