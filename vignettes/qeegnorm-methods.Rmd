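---
title: "Methods: normative quantitative EEG in the double-banana montage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative quantitative EEG in the double-banana montage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegnorm)
```

This vignette documents the models, estimators and design decisions behind
the package: what is computed, under which assumptions, which parameters
matter, and what the synthetic-data generator does and does not emulate.

## The analysis chain

### Filtering and montage

Input is a 19-electrode referential recording in the 10–20 layout, in
microvolts. Preprocessing applies a zero-phase sixth-order Butterworth
band-pass between 0.5 and 30 Hz and decimates to the 128 Hz analysis rate.
Two numerical choices deserve note:

* The band-pass is realized as a **cascade** of a 6th-order high-pass
  (0.5 Hz) and a 6th-order low-pass (30 Hz). A single 12-pole band-pass
  transfer function is numerically unstable in double precision at a
  512 Hz sampling rate with a 0.5 Hz lower edge (pole moduli exceed 1
  after coefficient rounding); the cascade is stable and gives 6th-order
  roll-off at each edge.
* Filtering is **forward–backward** (`signal::filtfilt`), i.e. zero-phase,
  so the latency and shape of the posterior dominant rhythm are not
  distorted. The effective amplitude response is the squared Butterworth
  magnitude. One consequence users should know: spectral content between
  roughly 24 and 30 Hz is attenuated noticeably (power gain
  $|H|^4 \approx 0.88$ at 24 Hz, $0.25$ at 30 Hz), which biases the upper
  beta band low for any recording — a property of this standard clinical
  filter choice, not of the implementation.

The 30 Hz low-pass doubles as the anti-alias guard for the 4:1 decimation.
The double-banana derivation is exact elementwise subtraction of parent
electrodes; it is linear and invariant under re-referencing (any common
signal cancels), which the test suite asserts as algebraic properties.

Artifact handling follows clinical practice: artifact-free segments are
selected by the reader and concatenated (`concatenateChunks()`); the
package warns below 120 s of total data, the lower end of the epoch
lengths for which the normative values were established, and performs no
automatic artifact rejection.

### Windowing and spectra

The bipolar record is cut into 1 s moving windows with 10% overlap (step
0.9 s). At 128 Hz the step is 115.2 samples; window starts are placed at
`floor(i * 0.9 * fs)` so that the window count equals
`floor((T - 1)/0.9) + 1` exactly for every duration (a 180 s record gives
199 windows; rounding the step to whole samples would not).

Each window is Hann-tapered (power-normalized, so Parseval's relation
holds against the taper-weighted mean square; a rectangular taper is
available via `qeegConfig(taper = "rect")`, for which Parseval is exact
against the plain mean square) and zero-padded twofold, giving a one-sided
power spectral density in µV²/Hz on a **0.5 Hz grid** — the stated
precision of the frequency measurements, including the PDR. The taper is a
deliberate choice: the overlap-and-window scheme exists to control
spectral leakage, and a Hann window is the standard realization; the exact
taper is configurable because the original numerical conditions named
none.

Band areas integrate the PSD over the classical segmentation δ 0.5–4,
θ 4–8, α 8–13, β 13–30 Hz. Bins falling on a shared edge are assigned to
the **lower** band only, making the four bands an exact partition of the
0.5–30 Hz area (asserted to machine precision). The δ lower edge is 0.5 Hz
(matching the high-pass; configurable). Window areas are averaged before
the decimal log transform (logPS = log₁₀ A); base 10 is chosen because the
normative logPS magnitudes (≈ 0.6–2.2 for areas of 4–150 µV²) are only
consistent with decimal logs.

Spectral entropy normalizes the PSD to a probability distribution over the
60 bins of the 0.5–30 Hz support and reports
$SSE = -\sum_k p_k \log_2 p_k$ in bits, so a flat spectrum gives
$\log_2 60 \approx 5.91$ and a pure line gives 0. Restricting the support
to the filtered band is deliberate: bins outside the pass-band carry only
filter leakage. SSE is computed per window and averaged (default); the
entropy of the window-averaged spectrum is also implemented
(`sseOrder = "mean-spectrum"`) and is always ≥ the default by Jensen's
inequality, because averaging flattens the chi-squared fluctuations of
single-window spectra.

### Coherence

Magnitude-squared coherence uses the same tapered, padded windowed FFT as
the power spectra: $Coh(\omega) = |\langle S_{ij}\rangle_n|^2 /
(\langle S_{ii}\rangle_n \langle S_{jj}\rangle_n)$, with the
cross-spectrum averaged over windows **before** the modulus — the order
matters; taking moduli first would make every estimate 1. The estimate is
bounded in [0, 1] and biased upward by about $1/n_{windows}$ for
independent signals (≈ 0.005 at 199 windows), which the tests verify
against simulation. Band coherence is the unweighted mean of $Coh(\omega)$
over the band's bins (the band-integrated alternative is not implemented).

Two properties of bipolar coherence are worth flagging. Adjacent
double-banana channels share an electrode, so even fully independent
sources produce baseline coherence (~0.15–0.25) through the common
electrode's noise — a property of the montage itself. And regional
averages use all `Nch(Nch-1)/2` channel pairs: 3 per lobe and 36 slot
pairs per hemisphere, where the hemisphere's nine slots include the
posterior temporal-occipital channel twice (it closes both the
parasagittal and the temporal chain). The slot pair of that channel with
itself is excluded as a self-pair; a "unique-8" hemisphere (28 pairs) is
available via `hemispherePolicy = "unique"`.

### Posterior dominant rhythm

PDR frequency is the argmax of the window-averaged spectrum within
8–13 Hz on P3-O1 (left) and P4-O2 (right), reported on the 0.5 Hz grid;
exact ties resolve to the lower frequency (deterministic). Amplitude is
the RMS of the full broadband channel trace (the amplitude definition is
stated on the channel voltage with no further filtering); an alpha-band
RMS is available via `pdrAmpBand = c(8, 13)` since the original
measurement's filtering state is not documented.

## The normative layer

Age groups partition the age axis as [0, 20) → "<20", [20, 50] → "20–50",
(50, ∞) → ">50" (the closed 20–50 convention is the one the group sizes
7/25/5 are attached to). Structure orderings sort the four band means of a
region descending, reporting exact ties jointly ("beta/theta"). The
bundled reference tables carry one label column per age group ordered by
the left hemisphere; in two right-hemisphere cells (temporal <20,
parieto-occipital >50) the numeric cells order differently, and the
numeric cells are treated as ground truth.

The shipped equation bundle (`inst/extdata/normative_equations.json`)
contains the printed coefficients: the PDR cubic
$9.77 + 0.03y - 0.0004y^2 - 0.000002y^3$ (maximum 10.3 Hz within the
10–74 y range), the posterior amplitude offset exponentials
$14.62 + 99.31\,e^{-0.127y}$ µV (left; right analogous), and six regional
SSE cubics. The amplitude exponent is **negative**: the curves are
explicitly decaying (amplitude halves roughly every 5.5 years of youth and
levels at the 14.62 µV offset), and a growing exponential would contradict
both the reported fits and physiology, so the printed positive exponent is
read as a typographical artifact. Band-power (logPS) regressions are not
shipped: `fitNormative()` regenerates analogous equations from user
cohorts (raw-polynomial least squares up to cubic, or offset-exponential
via Levenberg–Marquardt), with fit correlation $r = cor(y, \hat y)$ and
one-tailed significance from $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$
degrees of freedom.

The statistical layer fixes α = 0.05 throughout with no multiple-testing
correction, matching the normative study's design (a Holm option exists in
`pairedCompare()` callers' hands via `p.adjust` but is not applied by
default). Normality gating uses the Lilliefors-corrected
Kolmogorov–Smirnov test because mean and SD are estimated from the sample;
symmetric-lobe comparisons are two-sided (the regression significance test
is the explicitly one-tailed one).

## The synthetic-data generator

The generator exists so that every pipeline stage is testable without
clinical recordings. It emulates: eye-closed rsEEG band-power structure
per lobe and age group (targets are $10^{logPS}$ of the bundled group
means), within-lobe synchronization (shared-source fractions defaulting to
the group band coherences), and a posterior alpha oscillator whose
frequency and amplitude follow the bundled age curves. Every electrode is
a sum over bands of band-limited Gaussian noise
$\sqrt{1-c}\,\xi_e + \sqrt{c}\,S_r$; each lobe's shared source $S_r$
enters at two lobe-exclusive electrodes with opposite signs — the unique
injection pattern on the montage graph for which every in-lobe bipolar
channel receives the source (gains 2/−1/1 along the chain) while no
neighbouring lobe's channel receives any of it. Junction electrodes (C3,
F7, T5, O1 and right homologues) parent channels of two lobes and receive
the geometric mean of their lobes' band amplitudes, a spatial amplitude
gradient without which young-group posterior alpha would flood the
frontal channel F3-C3 beyond the entire frontal alpha target.

Numerical choices in the generator:

* **Source bands are inset** from the nominal band edges (δ 1.5–3,
  θ 5–7, α 10–12, β 14.5–24 Hz; order-8 Butterworth edges, order 6 for δ
  where higher orders degrade numerically). The 1 s analysis windows smear
  power by about ±1 Hz and the 30 Hz analysis low-pass attenuates
  24–30 Hz, so power placed at a band edge is attributed to the wrong band
  or lost *by the estimator*; insetting keeps each source's power
  recoverable in its own band. Cohort simulations jitter the θ/α/β source
  bandwidths per subject and session ("spectral concentration"), which
  moves spectral entropy without touching band-power targets.
* **Calibration**: source amplitudes are scaled iteratively (≤ 5 passes:
  2 against component variances, the rest against the full analysis
  chain) until the measured band power of each lobe's three bipolar
  channels matches the targets post-derivation. Calibrating against the
  chain also compensates residual cross-band kernel leakage, which is
  irreducible where a neighbouring band is an order of magnitude stronger
  (young-group posterior alpha versus beta). Infeasible target
  combinations are rejected.
* **The oscillator** is a sinusoid at the target PDR frequency injected at
  O1/O2 with random phase, scaled so its RMS on the posterior bipolar
  channels equals the target amplitude. The normative amplitude curve
  implies substantially more posterior power than the alpha band-area
  targets alone — the two published measurements are not mutually
  consistent at face value — so the generator treats the amplitude as the
  oscillator's own RMS and reports ground truth including the oscillator's
  analytic contribution to the alpha areas.
* **Cohort variability**: per-subject scatter of log band powers (0.25
  dex per region × band) plus a global amplitude gain (0.2 dex) common to
  all bands — inter-individual EEG amplitude differences are large and
  stable, and because the gain cancels in scale-invariant features it is
  what makes logPS the most reliable feature family in twin-session
  simulations (logPS ≈ 0.96 > SSE ≈ 0.92 > coherence ≈ 0.68 under the
  default session-level parameter jitter), matching the normative study's
  reliability ranking. All randomness derives from one master seed; the
  same spec and seed reproduce a recording bit-for-bit.

What the generator does **not** emulate: artifacts (blinks, EMG, cable
sway), the 1/f aperiodic background beyond band-level targets,
cross-hemisphere synchronization (homologous lobes are generated
independently, so interhemispheric coherence reflects only the montage's
structural baseline), non-Gaussian waveform features (spindles,
sharp transients), and eyes-open reactivity. Passing tests on generator
output therefore demonstrate estimator correctness and pipeline
consistency — not robustness to real-world artifact load, which remains
the reader's responsibility during segment selection.

In the saturated-sharing limit ($c = 1$) all in-lobe pairwise coherences
reach 1 except pairs involving the genuinely bi-lobar channel T5-O1
(T6-O2), which mixes two independent lobe sources and caps near 0.5 —
a structural property of the montage definition, not an implementation
limit. Coherence is monotone in the shared fraction throughout.

## Problem sizes used in the shipped checks

The test suite exercises full 180 s subjects at 512 Hz for band-power
recovery (lobe-level agreement within 10%, typically ≤ 4%), an
8-subject × 2-session twin cohort at 120 s for the reliability ranking,
n = 200 feature-level cohorts for normative-curve parameter recovery
(coefficients within their 95% confidence intervals), 400-replicate null
simulations for the paired test's type-I calibration, and 199-window
records for the coherence bias checks. These sizes were chosen so each
check's sampling error is comfortably below the tolerance it asserts.

## Known limitations

* The upper beta band is attenuated by the analysis filter (see above);
  beta logPS values are therefore only comparable between recordings
  analyzed with the same filter, which is also true of the normative
  values themselves.
* The EDF codec is minimal: 16-bit EDF with 1 s records, one sampling
  rate across the scalp channels, no EDF+ annotations.
* Normative equations are a pilot-scale reference (N = 37, single
  centre); deviations should be read as screening signals, not
  diagnostic thresholds. The deviation report deliberately reports
  residual-SD units only when the user supplies a reference cohort.
* Integer-factor downsampling only; recordings whose rate is not an
  integer multiple of 128 Hz must be resampled externally first.
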