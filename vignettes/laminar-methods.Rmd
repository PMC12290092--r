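---
title: "Methods: laminar LFP analysis with spline inverse CSD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar LFP analysis with spline inverse CSD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminarlfp)
```

## The analysis problem

High-density probes (Neuropixels-class) record local field potentials (LFP)
at hundreds of contacts spanning the cortical depth. Comparing cortical
function between animal groups (e.g. genotypes) from such recordings
requires a chain of steps, each with choices that affect the numbers:
estimating current source density (CSD) from the depth profile of the LFP,
quantifying oscillatory power by depth and its change under sensory
stimulation, detecting and excising epileptiform episodes that would
otherwise contaminate every downstream statistic, summarising spiking by
cortical layer, and testing per-session scalars between groups. This
package implements that chain as composable, tested functions plus an
orchestrating pipeline, and pairs it with a forward-model simulator so that
every stage can be validated by recovery from known ground truth.

Conventions used throughout: depth is micrometres below the pial surface
(0 at the pia, increasing downward); LFP is stored in millivolts; time is
seconds in double precision, session-relative. Channels sharing a depth
form a "depth row", the spatial unit of all laminar computations.

## Channel handling

Broken or out-of-brain channels must be removed before depth averaging.
Published workflows typically delegate this to acquisition-specific
toolboxes whose criteria are not part of the analysis itself, so
`reject_channels()` uses a deliberately parameter-light robust rule: a
channel is flagged when its log root-mean-square amplitude deviates from
the cross-channel median by more than `mad_k` (default 5) median absolute
deviations (scaled by 1.4826), or when its variance is exactly zero. On
homogeneous Gaussian channels the false-positive rate of this rule is far
below 1% (verified by simulation in the test suite). `average_same_depth()`
then averages the included contacts of each depth row; it is the identity
on already-averaged input.

## Epileptiform event detection and exclusion

`detect_session_events()` operates on the LFP row nearest 500 um depth:

1. short-time Fourier spectrogram with a 2-s periodic Hamming window moved
   in 0.1-s steps;
2. per frequency bin, subtraction of that bin's median over all window
   centres, in linear power units (no dB at this step);
3. the mean over the 0.5-10 Hz bins, giving one trace per window centre;
4. z-scoring of that trace by its own session mean and SD.

Events are maximal runs of window centres with z > 2 whose span is at
least 10 s. Because "at least 10 s" is ambiguous at the step level, the
rule is pinned explicitly: a run of *m* consecutive centres spans
`m * step` seconds (span between first and last centre plus one step), so
100 consecutive 0.1-s steps qualify and 99 do not. Runs separated by even
a single sub-threshold step are kept separate — the rule is a plain
threshold-run rule, with no merging heuristics. Event boundaries are the
first/last centre minus/plus half a step.

Two caveats are deliberate: the z-score uses the plain mean and SD of the
whole session trace, so very long episodes inflate the SD and weaken the
threshold (a contaminated-baseline effect users should be aware of with
heavily affected sessions); and no attempt is made to exclude the events
themselves from the z-scoring baseline, matching the plain reading of
"z-scored". The simulation battery shows that with episodes at
physiological-pathological amplitudes (8x the background band RMS) and up
to ~13% of the session affected, sensitivity is unimpaired.

Detected events are expanded by 15 s on both sides
(`exclusion_mask_from_events()`), merged, and clipped to the recording;
trials whose analysis windows overlap the mask are dropped, and PSD
estimation skips spectrogram windows whose centres fall inside it. Stage
order in `run_pipeline()` is fixed: detect, exclude, then everything else.

## Spline inverse CSD

The forward model assumes the CSD at each depth is uniform over a disc of
radius $R$ centred on the probe axis, in a homogeneous, isotropic medium of
conductivity $\sigma$ (0.3 S/m):

$$\phi(z_i) \;=\; \frac{1}{2\sigma}\int C(z)\,
\Big[\sqrt{(z-z_i)^2+R^2}-|z-z_i|\Big]\,dz .$$

With depths in mm, $C$ in $\mu A/mm^3$ and $\sigma$ in S/m the potential
comes out directly in mV ($1\,\mathrm{mV\,S\,m^{-1}\,mm^{-2}} =
1\,\mu\mathrm{A\,mm^{-3}}$). The spline variant interpolates $C$ between
electrode contacts with a natural cubic spline and assumes zero CSD outside
the outermost contacts; `build_spline_forward_matrix()` integrates each
cardinal spline basis function against the kernel with per-segment
Gauss-Legendre quadrature (the kernel kink at $z = z_i$ always lies on a
segment boundary, so each integrand is smooth). `estimate_csd()` solves
$F c = \phi$ per time sample with one LU factorisation reused across
samples. No regularisation is applied by default; instead the condition
number of $F$ is checked (error above 1e8) — for the default geometry it is
a few thousand.

Choices worth knowing:

* **Disc radius $R$.** Not identifiable from a recording and often left
  unstated in the literature. The default is 500 um, the scale of a
  cortical column; it is a `csd_config()` knob and reported outputs should
  cite the value used. Larger $R$ drives the estimate toward the standard
  second-difference CSD $-\sigma\,\partial^2\phi/\partial z^2$; the test
  suite verifies agreement within 10% RMS at $R$ = 50 mm.
* **Endpoint condition.** Natural spline with zero CSD beyond the end
  contacts, the common convention for smoothly varying laminar CSD.
* **Depth smoothing.** `smooth_csd_depth()` convolves each time sample
  with a Gaussian (SD 0.1 mm by default), truncated at 4 SD and
  renormalised to unit sum, using symmetric (half-sample) reflection at
  the boundaries. Reflection avoids the edge attenuation zero padding
  would cause at the pia and preserves the depth-sum of the profile
  exactly.
* **Peak read-out.** `extract_peak_response()` reports the most negative
  deflection (the strongest sink) at the row nearest the requested depth
  within a search window, and its latency; ties break to the earliest
  time. Note that smoothing and sink/source overlap attenuate the peak
  relative to the underlying CSD amplitude — the read-out is a linear
  functional of the truth, not the raw truth amplitude, which is exactly
  how the recovery tests treat it.

## Spectral analysis

One estimator serves all spectral consumers: Hamming-tapered one-sided
periodograms on the sliding 2-s/0.1-s grid (equivalently Welch with 95%
overlap), normalised as power spectral density so that white noise of
variance $s^2$ has mean PSD $s^2/(f_s/2)$ and integrating power over
frequency recovers the variance. A band-limited direct-DFT path computes
exactly the same bins when only a narrow band is needed; the test suite
asserts bit-level equivalence of the two paths. The periodic (DFT-even)
Hamming window is used, as is standard for spectral estimation.

"dBmV" is interpreted as $10\log_{10}(\mathrm{PSD}/1\,\mathrm{mV^2/Hz})$;
this is documented prominently because absolute dB values depend on the
reference choice. The session-level gamma scalar (`band_power()`) is the
mean of dB values over the 30-120 Hz bins and the selected depth rows;
averaging in dB keeps groups comparable when per-session spectra differ by
scale factors, and `mode = "db_of_mean"` offers the linear-mean alternative.
Band edges snap to the nearest frequency bins and are inclusive, so
30-120 Hz at 0.5 Hz resolution covers 181 bins.

`stimulus_psd_change()` computes $100\,(P_{stim}-P_{base})/P_{base}$ per
depth and frequency bin from trial-averaged mean PSDs over spectrogram
windows whose centres fall in the stimulus and baseline windows; bins with
exactly zero baseline power are flagged `NA` and excluded from summaries.
As a ratio statistic it is invariant to rescaling the recording. When
choosing analysis windows, note that a window *centre* inside the stimulus
interval can still average data from outside it (the window is 2 s long);
recovery tests therefore place stimulus centres in the interior of the
5-s stimulation period.

## Spiking

`compute_peth()` bins spike times relative to trial onsets into 10-ms bins,
converts to rate (count / trials / bin width) and subtracts the mean rate
over the baseline window, 2 to 1 s before the first stimulus of the trial —
the same per-trial baseline convention used for the trial-averaged LFP.
(Descriptions of this convention sometimes anchor the window to an
optogenetic "laser onset" even in sessions with no laser; this package
anchors all baselines to the first stimulus of the trial, which is the
only alignment available in purely sensory sessions, and the window is a
parameter wherever it is used.)
The unsubtracted rate is kept alongside, so the count-conservation identity
(rate integral = spikes per trial) stays checkable. `assign_layer()` maps
depth to supragranular (< 350 um), granular (350-500 um) and infragranular
(>= 500 um); the cutpoints are exposed because anatomical descriptions give
ranges (layer II/III 100-300 um, granular ~400 um, layer V 500-900 um),
not boundaries. Population PETHs average member clusters unweighted (each
cluster one vote); a spike-weighted average would let a few high-rate units
dominate a layer.

## Group comparison

`ranksum_test()` implements the two-sided Wilcoxon rank-sum test with
midranks for ties. For $n_1+n_2 \le 25$ the p-value is exact under the
permutation null: the full distribution of the rank-sum over all
$\binom{n}{n_1}$ reassignments of the pooled values, computed by dynamic
programming over the (doubled, hence integer) midrank multiset — this is
exact with ties, where classical tables are not. The two-sided p doubles
the smaller tail and caps at 1, the standard convention for discrete exact
tests. Larger samples use the normal approximation with tie-corrected
variance and continuity correction; at 15 per group it is within 0.01 of
exact. Group summaries report mean ± SEM (SD/$\sqrt{n}$, undefined at
n = 1).

## The simulator and what passing tests mean

`simulate_session()` builds an LFP as the sum of:

* **Pink (1/f) background noise** with an exponential spatial correlation
  across depth (length 200 um) — realistic LFP spectra make the detector's
  false-positive tests honest, where white noise would be too easy. The
  spectrum is flat below 0.5 Hz and rolls off above 100 Hz, mimicking the
  acquisition band; `pink_noise_psd()` exposes the exact theoretical PSD so
  recovery tests can form analytic predictions.
* **Evoked responses**: separable Gaussian(depth) x Gaussian(time) current
  sinks, each paired with an opposite-sign return source so the depth
  integral of the CSD is exactly zero (the source is rescaled to cancel the
  sink's truncated mass at the probe ends). The ground-truth CSD lives on a
  1-um grid — 20-30x finer than the electrode spacing — and is mapped to
  electrode potentials by direct trapezoidal quadrature of the disc kernel,
  a forward path entirely independent of the spline machinery it is used to
  validate. Responses are locked to every tactile air puff (two per trial,
  500 ms apart).
* **Gamma bursts**: a 70-Hz sinusoid within a depth band during each 5-s
  visual stimulus, with 0.1-s cosine ramps.
* **Epileptiform episodes**: 1-4 Hz sinusoids at a configured multiple of
  the background 0.5-10 Hz band RMS (measured on the generated noise at the
  detection depth), with 1-s cosine ramps to avoid STFT step artifacts that
  real transitions would not show.
* **Spikes**: inhomogeneous Poisson trains, baseline rate plus a boxcar
  rate increase after each tactile stimulus.

Reference defaults mirror the study design this pipeline targets: 2.5 kHz
LFP sampling, 20-um depth rows, 50 tactile + 50 visual trials in random
order with 3-5 s inter-trial intervals, sigma = 0.3 S/m. The default noise
RMS (0.05 mV) and evoked sink amplitude (-5 uA/mm^3 at 400 um with a
~25 ms latency) were chosen once so that single-session trial-averaged CSD
maps are clean but single trials are visibly noisy, the regime typical of
awake laminar recordings.

The simulator is a signal-level emulation, not a biophysical model: no
compartmental neurons, no spike-LFP coupling, no behavioural covariates,
and sources are perfectly charge-balanced Gaussians. Recovery tests
therefore demonstrate that the *analysis chain* is correct and calibrated
(unbiased under the null, sensitive to injected differences); they do not
certify performance on real tissue, where conductivity inhomogeneity,
drift, and non-stationary artifacts add failure modes this model does not
contain.

## Numerical and reproducibility notes

* Quadrature: 20-node Gauss-Legendre per electrode segment for the forward
  matrix; 1-um trapezoid for the oracle forward model. Both leave errors
  orders of magnitude below the 5% round-trip tolerance.
* All simulator randomness is seeded (`seed` is mandatory in
  `sim_config()`); cohort sessions derive per-session seeds from a master
  seed. `run_pipeline()` contains no randomness of its own, so a rerun with
  the same sessions and parameters reproduces every TSV byte for byte.
* The test and acceptance batteries run at reduced problem sizes chosen as
  package defaults for validation work: 1 kHz sampling, 8-32 depth rows,
  600-s sessions for the detector battery, 30 tactile + 10 visual trials
  and 8 sessions per group for the cohort recovery, PSD steps of
  0.25-0.5 s where only band summaries are consumed (the estimator's
  overlap is a config knob; band means are insensitive to it). The
  reference 2.5-kHz/0.1-s defaults remain in place for real use.

## Known limitations

* The exact rank-sum enumeration is quadratic in the midrank sum; beyond
  `exact_limit` (25 total) the normal approximation takes over.
* The detector's session-wide z-score can under-detect when epileptiform
  activity occupies a large fraction of the session (see above).
* CSD estimates on noisy single trials amplify high-spatial-frequency
  noise, as any inverse method does; use trial averages (the pipeline
  does) and report the smoothing SD and disc radius alongside results.
* `read_session()` reads only this package's flat-binary session layout;
  vendor formats should be converted upstream.
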