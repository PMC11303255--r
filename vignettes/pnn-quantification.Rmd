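---
title: "Quantifying perineuronal net holes and their contents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perineuronal net holes and their contents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(pnntools)
library(dplyr)
```

## The measurement problem

Perineuronal nets (PNNs) are condensed extracellular-matrix coats around the
somata of fast-spiking cortical interneurons, labelled by the lectin WFA.
The coat is not continuous: it is perforated by micrometre-scale holes, and
the biological question this package serves is *what sits inside those
holes* — astrocytic processes (AldheGFP, Kir4.1, GLT1, GAT1/GAT3),
presynaptic terminals (vGlut1, vGlut2, vGAT), both, or nothing. The raw
data are multi-channel confocal micrographs (12-bit, ~0.031 µm/px at the
highest magnification) of single optical planes through the net's largest
perimeter, plus patch-clamp uptake currents, glutamate-sensor transients
and video-EEG records from the accompanying physiology.

Everything downstream hangs on a one-dimensional reduction: a closed
polyline traced along the net periphery, from which a multi-channel
arc-length intensity profile is read. Holes become troughs of the WFA
profile; hole contents become marker peaks inside those troughs. The
package implements that reduction and every derived quantification as
tested, seedable code, together with a synthetic-data module that generates
profiles, images, sweeps and EEG with exact ground truth so each stage can
be validated without any external data.

## Hole detection on line profiles

`extract_profile()` resamples the contour at uniform arc length (default:
one pixel) and reads each channel as the mean of `band_px = 3` bilinear
samples along the local normal — the finite width of a hand-traced
polyline, which suppresses single-pixel noise while staying well below the
0.5 µm minimum hole width. Coordinates are continuous µm with pixel
centres at $(i + 0.5)\,\mathrm{px}$; profiles are circular (`s = 0`
adjacent to `s = L`), and arc intervals are half-open `[start, end)`.

Detection follows the published operational definition:

* **Reference peak.** The threshold is expressed as a fraction of the
  *unsaturated* peak WFA intensity — the maximum sample strictly below the
  saturation level ($2^{12}-1$), so clipped pixels cannot inflate it
  (`unsaturated_peak()`).
* **Threshold selection.** `select_threshold()` sweeps the fraction over
  0.40–0.66 in steps of 0.01 and keeps the fraction that maximizes the
  number of qualifying holes, ties broken toward the smallest fraction
  (the most conservative boundaries). The sweep is per cell; the chosen
  fraction is logged per cell by the pipeline.
* **Holes.** `detect_holes()` takes maximal circular runs of samples
  strictly below the threshold; runs at least `w_min = 0.5` µm wide become
  holes (the cutoff mirrors the 250–310 nm optical resolution limit). Runs
  wrapping the origin are merged; boundaries are linearly interpolated
  threshold crossings, so widths are sub-sample accurate and the 0.5 µm
  cutoff does not depend on the sample spacing. Any single supra-threshold
  sample splits a run — a deliberate, documented choice; the alternative
  (ignoring one-sample blips) would make widths depend on `ds`.
* **Normalization.** Hole counts are reported per µm of perimeter
  (`holes_per_perimeter()`).

Below-threshold arc length is monotone in the threshold; the hole *count*
need not be (a rising threshold can split one wide trough into two
qualifying holes, or promote a sub-width dip past 0.5 µm).

```{r holes-demo}
spec <- net_spec(snr = 10)
syn <- simulate_profile(spec, occupancy_presets("fig2cd"), seed = 42)
res <- analyze_net_profile(syn$profile)
res$threshold
nrow(res$holes)          # true number: nrow(syn$truth$holes)
autoplot(syn$profile)
```

## Occupancy classification

A hole is called occupied by a channel when the channel shows a *clearly
distinguishable peak* between the two flanking WFA peaks. The published
description gives no numeric criterion, so the package operationalizes it
and exposes every knob:

* the candidate peak is the channel maximum strictly inside the hole
  interval;
* its **prominence** is its height above the larger of the two channel
  values at the hole boundaries;
* the call is positive when prominence ≥ `k_sigma` (default 3) times the
  channel's robust noise sd.

The noise sd comes from the median absolute deviation of lag-3 sample
differences (`mad(diff(v, 3))/sqrt(2)`). The MAD makes the estimate immune
to the marker bumps themselves; the lag matters because band averaging and
sub-pixel interpolation correlate neighbouring samples of an extracted
profile, and *first* differences of such smoothed noise systematically
underestimate its sd (we measured ~25% underestimation on rendered
images, which inflates false-positive occupancy calls). For uncorrelated
samples the lag is immaterial. Both `k_sigma` and `noise_lag` are recorded
in the call table's attributes.

`occupancy_summary()` reports, per cell and pooled over holes, the full
exclusive partition over channel combinations (sums to 100 per cell),
per-channel marginals, pairwise and full intersections, and the derived
`any`/`none` categories; the cohort statistic is the per-cell mean ± sd
across nets, matching the way occupancy panels report n = 40 nets per
group.

## The synthetic net generator

`net_spec()` fixes the study conditions; `simulate_profile()` /
`simulate_net_image()` render them in 1D and 2D with a full ground-truth
manifest:

* **Geometry.** A circular contour of radius 8 µm (≈50 µm perimeter)
  carries 25 holes with widths uniform on 0.6–1.2 µm and inter-hole WFA
  ridges of at least 0.5 µm. Reported hole widths run from
  0.5 µm to several µm, with no published width or spacing distribution,
  so these defaults are documented placeholders chosen to keep ~25 holes
  per net geometrically feasible, not empirical claims.
* **Trough shape.** The WFA coat sits at 3000 (12-bit scale) and drops to
  `wfa_floor_frac = 0.15` of peak inside holes. Edges are raised-cosine
  ramps one PSF FWHM wide (2.355 × `psf_sigma`, `psf_sigma = 0.1` µm)
  placed entirely *outside* the true interval: the ramp is the model of the
  PSF's edge spread (a raised cosine closely tracks a Gaussian-convolved
  step), and keeping it outside the interval guarantees that every
  ground-truth hole lies strictly below the 0.40 × peak detection floor in
  the noise-free signal — the generator's central soundness invariant. A
  second explicit convolution would smear the floor above that line and
  break the invariant, which is why the edge model *is* the PSF treatment.
* **Noise.** Additive Gaussian with sd = trough depth / `snr` (optional
  Poisson shot noise first), clipped to the 12-bit range. The cohort
  condition used throughout the validation suite is SNR 10.
* **Markers.** Each hole draws its contents from the occupancy partition;
  occupied channels get a Gaussian bump (sd = PSF sigma) centred uniformly
  within the central 60% of the hole — edge placement would make
  boundary-referenced prominence ambiguous by construction. Bump amplitude
  is `marker_snr = 10` × noise sd (contract: at least 5×). Marker channels
  ride on a diffuse background of 4 × noise sd so the Gaussian noise is not
  clipped at zero — real fluorescence backgrounds sit above zero offset,
  and clipping would bias any difference-based noise estimate.
* **Occupancy presets.** `occupancy_presets()` bundles the exclusive
  partitions transcribed from the published occupancy panels (e.g. the
  AldheGFP/vGlut1 panel: both 44%, astro-only 9%, vGlut1-only 27%, empty
  20%). For the three-channel panel the printed constraints (union 95%,
  vGlut1∩vGAT 37%, AldheGFP 64%, vGlut1-without-vGAT 33%,
  vGAT-without-vGlut1 19%) do not pin all eight cells; the free cells
  allocate AldheGFP proportionally across the synapse categories. For the
  vGlut1/GLT1 and vGAT/GAT3 panels the second marginal is inferred from the
  printed conditional fractions (75% of excitatory, 67% of inhibitory
  terminals accompanied by the transporter) and an overall occupancy of
  80%.

What the generator deliberately does **not** emulate: irregular (non-
circular) somata, spatially varying WFA brightness, anisotropic PSFs,
marker bumps outside holes, bleed-through between channels, and 3D
structure. Passing the recovery tests therefore shows that the
detection/classification chain is unbiased under the stated noise model on
idealized geometry — not that it is robust to every artefact of real
tissue. The contour is taken as given throughout (the package does not fit
contours), mirroring the manual tracing step.

## Pericellular morphometry

The soma mask is the Otsu-binarized soma channel, largest connected
component, holes filled (`soma_mask()`); the pericellular band is every
outside pixel within 0.8 µm Euclidean distance of it, via a distance
transform (`pericellular_band()`); bands narrower than one pixel fall back
to the one-pixel dilation shell. Coverage is binary marker area inside the
band, in µm² and normalized per µm of perimeter, with a `combined` union
(`coverage()`). Puncta come from `find_maxima()`, which implements
flood-from-maximum prominence (the "noise tolerance" semantics under which
the published settings 500 for vGlut1 and 2000 for vGAT are meaningful):
a candidate maximum is rejected exactly when strictly higher ground is
reachable without descending more than the prominence below it; plateaus
report once at their centroid; ties among equal maxima fall to scan order.
Those two prominence values are acquisition-specific configuration and are
never rescaled to other bit depths. Contact calls
(`puncta_with_astro_contact()`) flag puncta with astrocyte mask pixels
within one pixel by default (a Boolean overlap), radius configurable.
`disruption_profile()` lays 0.4 × 0.4 mm ROIs from an injection site along
the +x (lateral) axis — section orientation is an acquisition property
supplied by the user — and `pericellular_wfa()` scores net integrity per
cell as mean band WFA plus Otsu-binarized WFA⁺ band area (a constant band
has no Otsu threshold: its WFA⁺ area is the full band if positive, else
zero).

## Ephys and EEG metrics

Sweep QC excludes sweeps whose baseline sd exceeds 3× the group median —
the formalization of discarding sweeps with baseline fluctuation — and
averages at least two survivors (`qc_and_average()`). After baseline
subtraction, `trace_metrics()` reports: peak (extremum magnitude in the
response window), charge transfer (absolute trapezoidal area; pA·s = pC
directly), and decay time measured from the peak to the first crossing of
37% of the peak, linearly interpolated. Decay is deliberately *not* an
exponential fit — the definition is the literal 100%→37% reading, so on a
pure exponential the measured time is $\tau\ln(1/0.37) = 0.994\tau$,
within one sample of $\tau$ at ordinary sampling rates. Currents are
stored signed and reported as magnitudes with a polarity flag. A trace
that never reaches 37% inside the window gets a censored flag rather than
a number. The charge integration window is a required argument because the
published description does not fix it. `io_curve()` assembles these per
stimulus level over the bundled ladders (`glu_protocol()`: 10, 20,
40…200 µA; `k_protocol()`: 0.1, 0.2, 0.5…3 mA); levels failing QC are
reported missing rather than aborting the curve.
`iglusnfr_net_change()` normalizes the transporter-blocked peak to the
ACSF peak as 100%: `100 (peak_blocked − peak_acsf) / peak_acsf`.

`detect_seizures()` implements the three-part electrographic rule —
amplitude at least 2× baseline, rate at least 2 Hz, duration at least 5 s.
"Baseline amplitude" is operationalized as the mean over 100-ms windows of
the maximum absolute deflection, i.e. the height of the background waves a
human scorer reads off the trace. The naive alternative (mean absolute
sample value) would put the 2× threshold at ~1.6 sd of Gaussian
background, which ~11% of samples exceed, making the zero-false-positive
requirement on noise unattainable for any rate/duration gate; the
windowed-peak statistic puts 2× at ≈4.4 sd, where isolated crossings are
far too sparse to assemble into ≥5 s events. Spikes are rectified
supra-threshold excursions merged within 1 ms; candidate events are spike
spans with inter-spike intervals ≤ 0.5 s, padded by one interval at each
end; events must reach 5 s and a mean rate of 2 Hz. The EEG generator
scales its spike amplitudes by the same realized statistic, so generator
and detector agree about what "2× baseline" means; this is stated here
because it is a package-level modelling decision, not a measured property
of any instrument.

## Problem sizes and numerical choices

The validation suite runs cohorts of 40 nets × ~25 holes (≈1000 holes per
cohort, matching the reported n = 40 PNNs and >1000 holes per panel) at
SNR 10 for each bundled preset, and checks recovered percentages within
±5 points of the transcribed panel values. The hole detector is verified
against a brute-force circular run-length scan on 1000 random profiles up
to 10⁴ samples, and `find_maxima()` against an exhaustive component-based
saddle search on images up to 64 × 64. Seizure detection is validated on
records of up to one hour of pure noise (zero events) and on epochs
clearing every criterion by ≥20% (full recall, full extent). All
randomness flows through a single integer seed per generator call; no
global RNG state is consumed or disturbed. Degenerate inputs have defined
behaviour throughout: all-saturated profiles and constant images raise
errors; an entirely sub-threshold profile is one full-circle hole;
zero-variance channels refuse a correlation; a constant EEG record is
rejected rather than scored.

## Known limitations

Arc-width is the only hole size measure (no 2D hole segmentation or 3D
topology, as in the source analyses). The threshold sweep is per cell;
batch-level thresholding is available only by overriding the fraction
range to a point. Prominence-based occupancy inherits a small
false-positive floor (~1–2% per channel at k_sigma = 3 under SNR 10),
visible as a point or two of upward bias in cohort percentages; raising
`k_sigma` trades it against misses of dim processes. The pericellular
generator draws coverage as angular sectors, which is a coarser texture
than real astrocytic leaflets. None of the hypothesis tests of the source
study are reimplemented: per-cell tables are exported for standard tools
(`aov`, `TukeyHSD`, t-tests) instead.
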