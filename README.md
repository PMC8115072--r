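# gridwave

Traveling-wave analysis of low-frequency oscillations recorded with
two-dimensional electrode microgrids on neural tissue.

Low-frequency oscillations (1–15 Hz) over structures such as the
hippocampal surface are not spatially static: their phase often advances
systematically across a dense electrode grid, so oscillation cycles sweep
across the tissue as traveling waves, sometimes switching between two
roughly opposite directions. `gridwave` is for electrophysiologists who
record with regular 2D grids (the reference layout is 4 × 8 contacts at
2 mm pitch) and want to quantify that propagation: which frequencies
travel, in which directions, how consistently relative to task events, and
whether the spatial pattern of oscillation strength predicts the direction
of travel.

## The model

At each analysis timepoint the instantaneous phase phi_i at electrode *i*
at position (x<sub>i</sub>, y<sub>i</sub>) (mm) is fitted by the
plane-wave (circular–linear) model

    phi_i = phi0 − k_rad (x_i cos θ + y_i sin θ)

with θ the direction of travel and k the spatial frequency in °/mm
(k_rad = kπ/180). The fit maximizes the mean resultant length of the phase
residuals over an exhaustive lattice — θ in 1° steps over 360°, k in 1 °/mm
steps up to the spatial Nyquist limit 180/pitch = 90 °/mm at 2 mm pitch —
and reports R² as the squared circular–circular correlation between
observed and fitted phases, the wavelength λ = 360/k (mm), and the speed
λ·f (mm/s). A timepoint counts as a valid traveling wave only when its R²
exceeds the 99th percentile of an electrode-location-shuffle null (200
iterations) and it passes amplitude gating (lowest 10% of channel-mean
analytic amplitude excluded, minimum 3 contiguous cycles).

Downstream, travel directions are summarized as smoothed 10°-binned
circular distributions with rule-based uni/bidirectional classification
(secondary peak ≥ 25% of the primary) and Rayleigh or Hodges–Ajne
uniformity tests; event-locked analyses measure directionality consistency
(DC — the mean resultant length of per-trial directions at each timepoint)
with Benjamini–Hochberg FDR control and a shuffled-timepoint null band;
and a 5-fold cross-validated linear SVM tests whether per-electrode
amplitude topography predicts the travel direction against a label-shuffle
null. A synthetic LFP generator with planted ground truth (directions,
spatial frequencies, regime schedules, amplitude topographies, trial
alignment, 1/f background) backs the entire test suite.

## Worked example

Synthesize a 20 s recording with a 6 Hz wave alternating every 2 s between
travel directions 30° and 210° at 15 °/mm, then recover all of it:

```r
library(gridwave)

grid  <- make_grid(4, 8, 2)                      # 4 x 8 electrodes, 2 mm pitch
waves <- list(
  wave_component(6, direction = 30,  spatial_freq = 15, amplitude = 10),
  wave_component(6, direction = 210, spatial_freq = 15, amplitude = 10))
starts <- seq(0, 18, 2)
segments <- data.frame(start_s = starts, end_s = starts + 2)
segments$component <- as.list(rep(1:2, 5))       # alternate the two regimes
rec <- synthesize(grid, waves, regime_schedule(segments),
                  noise_sd = 2, duration_s = 20, fs = 256, seed = 42)

peaks <- find_consensus_peaks(detrend_and_score(wavelet_spectrum(rec)))
peaks[, c("center_freq", "n_channels")]
#>   center_freq n_channels
#> 1    6.074311         32

band <- extract_band(rec, peaks$center_freq[1])  # 6.07 +/- 1.5 Hz, 30 Hz rate
fits <- fit_series(band, null_iters = 200, seed = 1)
fits
#> <wave_fit_series> 6.07 Hz, 600 timepoints @ 30 Hz, 540 valid (90.0%)

head(fits[fits$is_valid,
          c("t", "direction_deg", "k_deg_mm", "r2", "wavelength_mm", "speed_mm_s")], 3)
#>           t direction_deg k_deg_mm        r2 wavelength_mm speed_mm_s
#> 4 0.1015625            30       15 0.9990529            24   145.7835
#> 5 0.1328125            30       15 0.9994232            24   145.7835
#> 6 0.1679688            30       15 0.9995483            24   145.7835

build_distribution(fits$direction_deg[fits$is_valid])
#> <direction_distribution> n = 540, bidirectional; mode(s): 30, 210 deg
#>   hodges_ajne test: statistic = 265, p = 0.626
```

Reading the output: the consensus-peak stage finds one oscillation near
6 Hz supported by all 32 channels; 90% of timepoints carry a valid plane
wave whose direction (30° or 210°), spatial frequency (15 °/mm, i.e. 24 mm
wavelength, 146 mm/s at 6 Hz) and near-unity R² match the planted ground
truth; and the direction distribution is classified bidirectional with
modes exactly at the planted directions. (The Hodges–Ajne p illustrates a
documented property, not a failure: the test loses power for *balanced*
antipodal bimodality — the modality call rests on the 25% peak rule.)

`run_pipeline(rec, pipeline_config(), events = ...)` chains all stages —
artifact screening, peaks, fits, distributions, classifier, and
event-locked DC when events are supplied — into one report object.

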