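# pnntools

Quantification of perineuronal net (PNN) holes and their contents from
multi-channel fluorescence micrographs, with the accompanying physiology
metrics: pericellular astrocytic coverage and synaptic-puncta morphometry,
astrocytic uptake-current kinetics, and electrographic seizure detection.

## Who this is for

PNNs are condensed extracellular-matrix coats around fast-spiking cortical
interneurons, labelled by WFA. The coat is perforated by micrometre-scale
holes that house synaptic terminals and astrocytic processes (tripartite
synapses). This package is for imaging and physiology labs who quantify
that organization: it turns a traced soma contour plus a multi-channel
image into per-hole occupancy calls and cohort statistics, and scores the
downstream functional readouts (uptake currents, glutamate-sensor
transients, EEG) with explicit, seedable, tested code instead of ad-hoc
spreadsheet steps.

## The core method

Along a closed contour of perimeter $L$ traced on the net, each channel is
read as an arc-length intensity profile $I(s)$, $s \in [0, L)$ (circular,
bilinear sampling, 3-sample normal band). On the WFA channel:

* threshold $T = f \cdot P$, where $P$ is the **unsaturated peak** (maximum
  sample below the 12-bit saturation level) and the fraction $f$ sweeps
  0.40–0.66 in 0.01 steps; the $f$ that maximizes the number of qualifying
  holes is selected (ties to the smallest $f$);
* **holes** are maximal circular runs with $I(s) < T$ at least
  $w_{\min} = 0.5$ µm wide, boundaries interpolated at threshold
  crossings, counts normalized per µm of perimeter;
* a hole **contains** a marker when the marker's maximum inside the hole
  has prominence (height above the larger boundary value) of at least
  $k_\sigma = 3$ robust noise sd;
* cohort occupancy is reported over the exclusive combination partition,
  the per-channel marginals, intersections, and the derived `any`/`none`
  categories, per cell (mean ± sd across nets) and pooled over holes.

A synthetic-data module generates profiles, 2D net images, pericellular
images, current sweeps and EEG with exact ground-truth manifests; every
analysis stage is validated against it (plus brute-force oracles for hole
runs and prominence maxima).

## Worked example

Simulate a 40-net cohort whose per-hole occupancy follows the bundled
AldheGFP/vGlut1 panel preset (both 44%, astro-only 9%, vGlut1-only 27%,
empty 20%), then re-measure it with the full detection/classification
pipeline at SNR 10:

```r
library(pnntools)

spec <- net_spec(snr = 10)                      # 8 um radius, ~25 holes/net
coh  <- simulate_cohort(spec, occupancy_presets("fig2cd"),
                        n_cells = 40, seed = 13)
res  <- measure_cohort_occupancy(lapply(coh, `[[`, "profile"))
res$summary
#> <occupancy_table> 1001 holes, 40 cells, channels: AldheGFP, vGlut1
#> # A tibble: 9 x 5
#>   combination     type       mean    sd n_cells
#>   <chr>           <chr>     <dbl> <dbl>   <int>
#> 1 AldheGFP        contains   54.1 10.5       40
#> 2 AldheGFP        exclusive   8.3  5.54      40
#> 3 AldheGFP&vGlut1 contains   45.8 10.9       40
#> 4 AldheGFP+vGlut1 exclusive  45.8 10.9       40
#> 5 any             derived    79.9  8.12      40
#> 6 none            derived    20.1  8.12      40
#> 7 none            exclusive  20.1  8.12      40
#> 8 vGlut1          contains   71.6  9.80      40
#> 9 vGlut1          exclusive  25.9  8.34      40
```

Reading it: 71.6% of detected holes contain the excitatory presynaptic
marker, 54.1% the astrocytic reporter, 45.8% both, and 20.1% are empty —
per-cell means ± sd over 40 nets (1001 holes), recovering the encoded 71 /
53 / 44 / 20 within a couple of points (the residual is the classifier's
small false-positive floor plus cohort sampling).

Uptake-current metrics and seizure scoring work the same way:

```r
g   <- simulate_uptake_sweeps(peak = 120, tau_decay = 0.04,
                              n_sweeps = 5, noise_sd = 4, seed = 8)
avg <- qc_and_average(g$sweeps, g$truth$baseline_window)
trace_metrics(baseline_correct(avg, g$truth$baseline_window), c(0.19, 1))
#>   peak_pa polarity charge_pc decay_time_ms decay_slope_pa_ms decay_censored
#> 1   123.1       -1      4.78          36.9              2.10          FALSE
```

The 120 pA inward deflection is recovered at 123 pA with 4.8 pC charge
transfer; the 100%→37% decay reads 36.9 ms against the generator's
$\tau = 40$ ms (the 37% crossing of an exponential sits at $0.994\tau$;
the rest is noise on the 5-sweep average).

```r
eegr <- simulate_eeg(300, seizures = tibble::tibble(
  t_start = 120, duration = 15, spike_hz = 3, amp_ratio = 2.5), seed = 5)
detect_seizures(eegr$eeg, baseline_window = c(0, 60))
#>   t_start  t_end duration n_spikes spike_rate mean_amplitude_ratio
#> 1   119.5  135.2     15.7       62       3.96                 2.66
```

One embedded 15-s, 3-Hz, 2.5× epoch; one detected event with matching
extent, rate and amplitude ratio.

A thin CLI over the same functions lives in `inst/scripts/pnn-cli.R`
(subcommands `synth`, `holes`, `profile`, `uptake`, `eeg`, `report`).

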