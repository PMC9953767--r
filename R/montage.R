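#' @import methods
NULL

#' Standard 10-20 electrode labels (19 scalp positions)
#'
#' @return Character vector of the 19 classical 10-20 electrode names.
#' @export
electrodes1020 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz")
}

# fixed channel order of the longitudinal bipolar ("double banana") montage:
# left parasagittal, left temporal, right parasagittal, right temporal, midline
.DOUBLE_BANANA <- matrix(c(
  "Fp1", "F3",  "F3", "C3",  "C3", "P3",  "P3", "O1",
  "Fp1", "F7",  "F7", "T3",  "T3", "T5",  "T5", "O1",
  "Fp2", "F4",  "F4", "C4",  "C4", "P4",  "P4", "O2",
  "Fp2", "F8",  "F8", "T4",  "T4", "T6",  "T6", "O2",
  "Fz",  "Cz",  "Cz", "Pz"),
  ncol = 2, byrow = TRUE,
  dimnames = list(NULL, c("anterior", "posterior")))

#' Double-banana bipolar channel definitions
#'
#' The 18 differential channels of the longitudinal bipolar montage, in the
#' package's fixed order (left parasagittal chain, left temporal chain, right
#' homologues, then the two midline channels).
#'
#' @return Two-column character matrix (anterior, posterior electrode).
#' @export
bananaPairs <- function() .DOUBLE_BANANA

#' @rdname bananaPairs
#' @export
bananaChannels <- function() {
  paste(.DOUBLE_BANANA[, 1], .DOUBLE_BANANA[, 2], sep = "-")
}

# Lobe groupings: channel triplets used for regional averaging. The midline
# channels Fz-Cz and Cz-Pz belong to no lobe. T5-O1 (T6-O2) legitimately sits
# in both the parieto-occipital and the temporal triplet.
.LOBE_CHANNELS <- list(
  F_left   = c("Fp1-F3", "F3-C3", "Fp1-F7"),
  PO_left  = c("C3-P3", "P3-O1", "T5-O1"),
  T_left   = c("F7-T3", "T3-T5", "T5-O1"),
  F_right  = c("Fp2-F4", "F4-C4", "Fp2-F8"),
  PO_right = c("C4-P4", "P4-O2", "T6-O2"),
  T_right  = c("F8-T4", "T4-T6", "T6-O2"))

# Hemisphere "slots": nine channel positions per hemisphere with T5-O1
# (T6-O2) occupying two slots, one from the parieto-occipital and one from
# the temporal chain. The slot count (9) is what makes the pair count
# Nch(Nch-1)/2 = 36 for coherence averaging.
.HEMI_SLOTS <- list(
  H_left  = c(.LOBE_CHANNELS$F_left, .LOBE_CHANNELS$PO_left, .LOBE_CHANNELS$T_left),
  H_right = c(.LOBE_CHANNELS$F_right, .LOBE_CHANNELS$PO_right, .LOBE_CHANNELS$T_right))

#' Regional channel groupings
#'
#' Channel triplets for the frontal (F), parieto-occipital (PO) and temporal
#' (T) lobes of each hemisphere, and the nine-slot hemisphere groupings
#' (`H_left`, `H_right`) in which the posterior temporal-occipital channel
#' appears twice (once per chain).
#'
#' @param what `"lobes"`, `"hemispheres"`, or `"all"`.
#' @return Named list of character vectors of bipolar channel names.
#' @export
lobeGrouping <- function(what = c("all", "lobes", "hemispheres")) {
  what <- match.arg(what)
  switch(what,
    lobes = .LOBE_CHANNELS,
    hemispheres = .HEMI_SLOTS,
    all = c(.LOBE_CHANNELS, .HEMI_SLOTS))
}

# classical EEG band segmentation (Hz); delta's lower edge coincides with the
# analysis high-pass
.EEG_BANDS <- list(delta = c(0.5, 4), theta = c(4, 8),
                   alpha = c(8, 13), beta = c(13, 30))

#' Classical EEG frequency bands
#'
#' @return Named list of `c(lower, upper)` band edges in Hz: delta 0.5-4,
#'   theta 4-8, alpha 8-13, beta 13-30.
#' @export
eegBands <- function() .EEG_BANDS
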