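---
title: "Detecting traveling oscillations on electrode microgrids"
author: "gridwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting traveling oscillations on electrode microgrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridwave)
```

## The problem

Low-frequency neural oscillations (roughly 1–15 Hz) recorded with a dense
two-dimensional electrode grid often show systematic phase offsets across
space: at a fixed instant, the oscillation's phase advances smoothly along
some direction over the tissue, so cycle peaks sweep across the array — a
traveling wave. `gridwave` implements a complete analysis chain for such
recordings: finding each recording's preferred oscillation frequencies,
fitting a plane wave to the instantaneous phase field at every timepoint,
deciding which timepoints carry a statistically valid wave, characterizing
the distribution of travel directions, measuring how consistently waves
align across task trials, and testing whether the spatial pattern of
oscillation amplitude predicts the travel direction.

Because grid recordings of this kind are rarely public, the package ships a
first-class synthetic generator: a 4 × 8 grid at 2 mm pitch carrying planar
phase gradients with known direction and spatial frequency, switching
between two roughly opposite direction regimes, over a 1/f aperiodic
background. Every downstream stage is validated against this ground truth.

## The plane-wave model

At one timepoint, let $\phi_i$ be the instantaneous phase at electrode $i$
with position $(x_i, y_i)$ in mm. The model is

$$\phi_i \;=\; \phi_0 \;-\; k_{rad}\,(x_i\cos\theta + y_i\sin\theta),$$

where $\theta$ is the direction of travel (the direction of $-\nabla\phi$;
0° along +x, counterclockwise positive) and $k$ is the spatial frequency
(reported in °/mm; $k_{rad} = k\pi/180$). Derived quantities are the
wavelength $\lambda = 360/k$ mm and the wave speed $\lambda f$ mm/s for an
oscillation at $f$ Hz.

Because phase is circular, the fit is a circular–linear regression solved
by exhaustive search: directions in 1° steps over 360° and spatial
frequencies in 1 °/mm steps up to the grid's spatial Nyquist limit of
half a phase cycle per electrode spacing — $180/\text{pitch} = 90$ °/mm at
2 mm pitch. For each candidate $(\theta, k)$ the residuals
$\delta_i = \phi_i + k_{rad}(x_i\cos\theta + y_i\sin\theta)$ are formed;
the fit score is their mean resultant length and the phase offset is their
circular mean. $k = 0$ (a spatially uniform field, direction undefined) is
always a candidate, and lattice ties break toward smaller $k$, then
smaller $\theta$, making the search fully deterministic. The search is
implemented as a batch of complex matrix products over all timepoints at
once, so a full recording fits in seconds.

Goodness of fit is reported as $R^2$, the squared Jammalamadaka–SenGupta
circular–circular correlation between observed and fitted phases. It is
bounded in $[0,1]$, equals 1 exactly for a noiseless planar field, and is
defined as 0 for degenerate fits ($k = 0$). The resultant-length score used
for optimization is also exposed; the two agree closely on good fits but
the correlation form is the default because of its fixed range and its use
in the antecedent cortical traveling-wave literature.

Useful invariances, each verified by tests: rotating all electrode
coordinates by $\alpha$ rotates the fitted direction by exactly $-\alpha$
at lattice resolution; translating coordinates or adding a constant to all
phases changes only the offset; scaling the raw signal changes nothing
downstream of the analytic transform.

## Validity screening

Phase is meaningless when the underlying oscillation is weak, so timepoints
are screened twice.

*Amplitude gating.* The analytic amplitude is averaged across channels;
timepoints in the lowest 10% are dropped, and a surviving timepoint must
sit inside a contiguous above-threshold run of at least 3 oscillation
cycles ($3/f$ seconds). The 10% threshold is computed within the recording
block.

*Permutation null.* For each timepoint the electrode-to-location
assignment is shuffled (200 iterations by default) and the full lattice
search is re-run; the timepoint is a valid traveling wave only if its
observed $R^2$ exceeds the 99th percentile of its own shuffled
distribution. The package exposes the confidence level (`ci_percent`)
because both 95 and 99 are defensible; 99 is the default used for
screening throughout.

## Preferred-frequency discovery

Each channel's spectrum is the time-averaged power of a continuous Morlet
wavelet transform (analytic Morlet, $\omega_0 = 6$, L1-normalized), on 211
log-spaced frequencies over 1–32 Hz (42 voices per octave). When no
artifact intervals are annotated, the time average is computed in the
frequency domain via Parseval's identity, which is exact and much faster;
otherwise artifact samples are excluded from the average in the time
domain.

The aperiodic 1/f trend is removed by a robust straight-line fit
(iteratively reweighted least squares, bisquare weights) of log power
against log frequency; residuals are z-scored within channel. Per-channel
peaks are local maxima of the adjusted z-score above 1 SD; peaks are
clustered greedily (strongest peak seeds a cluster, absorbing each
channel's nearest peak within ±1 Hz, i.e. a 2 Hz total span), and a
cluster supported by at least 5 distinct channels becomes a consensus peak
at the mean of its member frequencies.

A limitation worth knowing: because the adjusted spectrum is z-scored per
channel, even a featureless noise spectrum has local maxima above 1 SD
(the residual has unit SD by construction), and at the low-frequency end a
2 Hz window is wide in log-frequency terms, so chance co-location of such
maxima across ≥ 5 of 32 channels does occur on aperiodic-only input. What
distinguishes a genuine oscillation is near-unanimous channel support: in
the synthetic study conditions a planted wave recruits essentially all 32
channels into its consensus cluster, while chance clusters stay well below
that, and the test suite asserts exactly this separation. On real data the
consensus list should be read as candidates, strongest support first.

## Direction distributions

Directions of valid fits are binned in 10° bins and smoothed with a
mass-preserving circular window of 60° total support (seven 10° bins with
half-weight ends, since a 60° span covers an even number of bins).
Modes are plateaus of the smoothed histogram that dominate both circular
neighbors; a plateau's mode is the circular mean of its bin centers, which
resolves ties deterministically. The distribution is classified
bidirectional when the second-highest smoothed peak reaches at least 25%
of the highest. Bidirectional distributions are tested for non-uniformity
with the Hodges–Ajne test (exact p for $n \le 50$, the standard asymptotic
above), unidirectional ones with the Rayleigh test (Zar's large-sample
approximation, underflow-safe). Note that the Hodges–Ajne statistic — the
minimum count in a closed half-circle — loses power as an antipodal
bimodal distribution approaches 50/50 balance; it detects non-uniformity,
not bimodality, and the modality call rests on the 25% rule, not on the
test. Distributions measured under different grid orientations are
compared with Fisher's nonparametric common-median chi-square test.

## Event-locked directionality consistency

For task recordings, fits are computed at 100 Hz and epoched from 2 s
before to 2 s after each event; trials overlapping artifact intervals are
excluded, and at least 10 trials are required. At each event-locked
timepoint the directionality consistency (DC) is the mean resultant length
of the per-trial directions: 0 when directions scatter uniformly across
trials, 1 when every trial's wave travels the same way. Rayleigh p-values
per timepoint are corrected across the window by Benjamini–Hochberg.
Timepoints whose fits failed the validity screen are included by default
(with per-timepoint n recorded), since the fit's $R^2$ is tracked
separately; a flag excludes them. The null band circularly shifts each
trial's direction series by an independent random offset — preserving
within-trial autocorrelation — and pools DC over all timepoints of 200
surrogates, taking the central 95% band. A median split of reaction times
(ties to the fast half) supports performance contrasts.

## Amplitude-topography direction classifier

For a bidirectional frequency, timepoints within 45° of either mode form
two direction conditions. Features are the per-electrode z-scored analytic
amplitudes at those timepoints (amplitude is independent of the phase used
to compute direction); classes are balanced by subsampling the majority
once under seed. A linear-kernel SVM with standardized features — no
hyperparameter optimization — is evaluated by 5-fold cross-validation
(80/20 per fold), and the mean held-out accuracy is compared against a
label-shuffle null in which the entire procedure is repeated with permuted
labels (10,000 iterations by default); significance means exceeding the
99th null percentile. For balanced classes the null is centred at 50%.
Complementary per-frequency summaries report the anterior/posterior
timepoint ratio against frequency (Spearman) and the anterior-minus-
posterior amplitude gradient between conditions (paired t), where the
anterior and posterior halves are the 16 electrodes with largest and
smallest x.

## The synthetic generator

`synthesize()` sums plane-wave components
$A g_i \cos(2\pi f t - k_{rad}(x_i\cos\theta + y_i\sin\theta) + \phi_0)$
on the grid, with a per-component unit-mean gain map $g_i$ for amplitude
topography, gated by a regime schedule with 100 ms raised-cosine ramps at
segment boundaries (avoiding broadband transients). Per channel it adds
independent 1/f² background noise — white noise shaped in the frequency
domain, with a 0.3 Hz knee so the sub-Hz divergence does not absorb the
variance budget and the in-band spectrum is a clean power law — plus a
small white floor (background SD / 50, an amplifier-like noise floor).
Trial structure plants events whose aligned trials (with probability
`align_prob`) adopt a designated component's direction inside a window
0.7–1.6 s after the event.

Default study conditions: a 4 × 8 grid at 2 mm pitch; 6 Hz components at
15 °/mm (wavelength 24 mm, within the 12–22 °/mm range typical of such
recordings) traveling at 30° and 210° — two roughly opposite oblique
directions; amplitude 10 µV against a 2 µV background (analytic-amplitude
SNR ≈ 5); 512 Hz sampling by default, with tests and the acceptance script
using 128–256 Hz since all analysis happens below 16 Hz. The same seed
always reproduces the same recording bit-for-bit.

What the generator does *not* emulate: volume-conduction correlation
between channels (noise is independent per channel; spatial noise
correlation is left configurable by design), non-planar (spiral or radial)
waves, epileptiform discharges, electrode drift, and the curvature-induced
direction shifts seen along a real hippocampal body. Passing tests
therefore demonstrate correctness of the estimators under planar ground
truth with independent noise, not robustness to every failure mode of real
recordings.

## Numerical choices and degenerate inputs

* Phases live in radians internally, wrapped to $(-\pi, \pi]$; user-facing
  directions are degrees in $[0, 360)$.
* The analytic signal comes from the FFT Hilbert transform after a
  zero-phase (forward–backward) 6th-order Butterworth band-pass at
  center ± 1.5 Hz; the band-pass doubles as the anti-alias filter for
  decimation to the 30 Hz analysis rate (100 Hz for trials), which
  requires the upper band edge below half the analysis rate.
* Spatially uniform phase fields return $k = 0$ with direction `NA` and
  $R^2 = 0$; fits require 8 usable electrodes (6 for deliberately reduced
  layouts, e.g. oblique 3 × 2 subsets).
* An exactly linear log-log spectrum leaves residuals at machine
  precision; these are reported as z = 0 rather than amplified noise.
* Hodges–Ajne half-circle counts are evaluated at generic boundaries
  (midpoints between consecutive data angles and their antipodes), which
  is exact and immune to floating-point ties; a maximally balanced sample
  ($2m \ge n$) is capped at p = 1.
* The permutation engine precomputes the lattice phasor matrices once per
  geometry and batches several permutations into each BLAS pass.

## Problem sizes

The test suite and the acceptance script run the full chain at reduced
problem sizes chosen to keep total runtime modest while leaving every
statistical conclusion comfortably powered: recordings of 10–60 s at
128–256 Hz, permutation nulls of 40–200 iterations, 100–250 classifier
label shuffles in property tests and 1,000 in the chance-level
calibration, and Monte Carlo loops of 50–1,000 repetitions. The defaults
baked into `pipeline_config()` (200 electrode shuffles, 10,000 label
shuffles) reflect full-scale analysis practice.

## Known limitations

* The consensus-peak rule's chance co-location at low frequencies,
  discussed above.
* The lattice search cost grows linearly in timepoints × directions ×
  spatial frequencies; per-timepoint permutation nulls multiply this by
  the iteration count, dominating pipeline runtime.
* DC inherits the temporal autocorrelation of the underlying band, so
  neighboring timepoints are not independent tests; BH correction is
  applied across timepoints regardless, matching standard practice.
* The SVM analysis assumes the two direction conditions are linearly
  separable in amplitude space at best; no nonlinear kernel is offered by
  design.
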