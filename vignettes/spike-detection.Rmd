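---
title: "Detecting nuclear calcium spikes in growing root meristems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nuclear calcium spikes in growing root meristems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucspike)
```

## The measurement problem

Growing *Arabidopsis* root meristems produce brief, cell-autonomous
calcium transients that originate inside the nucleus and subsequently
spread to the cytosol. Dual-targeted genetically encoded indicators
(a nuclear red and a cytosolic green GECO variant) report these events
as fluorescence time series sampled every 2–3 s for roughly 1.5 h per
root. Each responding cell shows a single asymmetric spike — a rise of
roughly fifteen seconds followed by a slower fall of about twenty-five —
riding on a slowly drifting baseline contaminated by shot and detector
noise. The biological questions hang on a handful of summary numbers:
how long the rise, fall and total duration of the transient are, what
fraction of plants respond, how many cells spike per plant-hour near the
tip, how spikes partition between the meristem and the elongation zone,
and whether spike frequency tracks primary-root growth rate.

`nucspike` implements that measurement chain end to end: trace
normalisation and detrending, pulse-boundary detection, per-spike
kinetics, nuclear-versus-cytosolic origin calls, cohort summaries, and a
fully seeded synthetic-data generator with exact ground truth so that
every stage can be benchmarked against known inputs.

## The detection model

For a raw fluorescence series $F(t)$ the pipeline computes, per trace:

1. **Normalisation.** $\Delta F/F = (F - F_0)/F_0$ with $F_0$ the mean
   of the first `n_baseline` (default 20) frames. The result is
   dimensionless and invariant under multiplicative rescaling of the
   raw counts; the mean of the baseline window is exactly zero.
2. **Detrending.** An ordinary least-squares polynomial of order
   `poly_order` (default 3) in time is fitted to the full series and
   subtracted. A cubic absorbs slow drift — focus creep, bleaching,
   growth-induced displacement — over a 1.5 h recording without eating
   a 40 s transient. The order is configurable from 0 to 5.
3. **Gradient.** Central differences divided by the frame interval
   (one-sided at the edges), so thresholds carry per-second units.
4. **Candidate peaks.** The highest remaining local maximum whose
   height on a 5-frame running mean reaches `amp_mult` (default 5)
   times the robust noise scale of that smoothed series. The noise
   scale is always $1.4826 \times \mathrm{MAD}$, estimated per trace.
5. **Boundaries.** Scanning backward and forward from the peak, the
   pulse bounds are the first frames at which the detrended signal
   falls below $\theta_s$ **and** the absolute gradient falls below
   $\theta_g$, with $\theta_s$ and $\theta_g$ expressed as multiples
   (`theta_s_mult`, `theta_g_mult`) of the per-trace noise scales. A
   scan that reaches the trace edge censors that boundary instead of
   failing.
6. **Kinetics.** Rise = peak − onset, fall = offset − peak, duration =
   rise + fall (exactly, by construction), amplitude = the detrended
   value at the peak. Accepted pulses must last at least
   `min_duration_s` (default two frames) and must not be censored at
   both ends. The pulse interval is masked and the search repeats, so
   multiple well-separated spikes on one trace are returned in onset
   order.

The absolute value in the gradient criterion is a deliberate choice:
immediately after the peak the signed gradient is negative and would
satisfy a signed "falls below" test at the very next frame, collapsing
every fall time to one frame. The absolute form makes the backward and
forward scans symmetric.

## Precision refinements and their rationale

Index-based threshold crossings quantise boundaries to the frame grid
and carry systematic offsets: the crossing of a positive threshold
always sits $\theta_s T / A$ seconds inside the true pulse foot (limb
duration $T$, amplitude $A$), single-frame noise jitters first-passage
scans, and the raw argmax of a noisy asymmetric pulse drifts toward the
shallower limb because more frames sit within a noise scale of the
maximum there. Three default-on refinements address these; all are
switchable:

* **Scan smoothing** (`bound_smooth_frames = 3`): the boundary scan and
  its gradient run on a 3-frame running mean, roughly halving the
  frame-to-frame noise while widening a pulse's support by at most one
  frame per side, which preserves the noiseless one-frame recovery
  guarantee.
* **Sub-frame interpolation** (`boundary_refine = "interpolate"`): the
  reported boundary is the linearly interpolated threshold-crossing
  time rather than the stopping frame.
* **Template refinement** (`refine_shape = TRUE`): each accepted pulse
  is re-measured by least-squares fitting a piecewise-linear (tent)
  pulse to the unsmoothed detrended signal over the pulse window. The
  fit is initialised by a coarse grid over breakpoint triples with the
  amplitude profiled out in closed form — the kinked error surface has
  local basins, and a local optimiser started from the scan boundaries
  inherits their bias — and finished with a derivative-free polish. On
  simulated transients this estimator is unbiased at the boundary level
  to well under a frame.

Additionally, detection runs in two passes (`redetrend = TRUE`): pulse
intervals found in a first pass are excluded from a second polynomial
fit, because a single global fit absorbs part of each pulse into the
trend and dents the baseline around it, pulling both boundaries inward.

Two calibration facts drove the default multipliers, established on
simulated tent spikes with known truth. First, a signal threshold of
two noise scales places the boundary crossing 40% of the way up the
limb — an error of roughly $0.4T$, i.e. 6–10 s — so `theta_s_mult`
defaults to 0.5, where the residual crossing offset is a fraction of a
frame. Second, a raw-peak amplitude gate of five noise scales sits
exactly at the amplitude of a spike whose peak is five noise scales
high and therefore misses about a fifth of such spikes, while lowering
it collides with the expected extreme of ~2 700 noise samples (about
four noise scales); screening candidates on a 5-frame running mean
resolves the dilemma, because averaging under the pulse keeps most of a
30–50 s transient's height while shrinking the noise scale by
$\sqrt 5$. With these defaults, 200 simulated spikes at
amplitude-to-noise 5 are recovered with no misses, no false positives
on pure-noise traces, and mean absolute rise/fall errors under two
frames.

## Origin classification

Per cell, nuclear and cytosolic calls are paired by the smallest
absolute peak-time difference; the lag is the cytosolic onset minus the
nuclear onset, and the compartment of origin is called from the sign of
the lag against a tolerance of one frame interval. Onset order — not
peak order — defines origin, since the claim under test is where the
release *starts*.

A resolution limit is worth stating plainly: at amplitude-to-noise 5,
each channel's onset is only determined to about 3 s (the information
in the limb frames bounds it near 2 s), so the onset-lag estimate has a
standard deviation of roughly 4 s. Lags of two frames are therefore
classified correctly essentially always only in low-noise recordings;
at this noise level, near-certain classification needs lags upwards of
five frames. Cross-correlation lag estimation, which pools the whole
pulse and would sharpen this several-fold, is deliberately out of scope.

## Cohort statistics

Per plant: the responder flag (any accepted nuclear call), the count of
accepted nuclear calls from cells within `span_um` (default 200 µm) of
the tip, and that count divided by the imaging duration in hours.
"Within 200 µm" is implemented as a positional filter on the cells, not
a rate rescaling; a rescaling mode exists (`span_mode = "rescale"`) but
counting is the default. Zone partition assigns a call at a position
less than or equal to its plant's boundary to the meristem — the tie
goes inward, consistent with inclusive "last meristematic cell"
terminology. Shape means are arithmetic means over uncensored calls, so
the mean duration equals mean rise plus mean fall identically. The
growth regression is an ordinary least-squares line of growth rate
(cm/day, from root lengths at days 3 and 5) on spike rate, using every
matched plant with no outlier handling. Hypothesis tests quoted in the
original figure legends (χ², ANOVA, multiple-comparison corrections)
are outside this package's scope; it emits the tables such tests
consume.

## The synthetic-data generator

`sim_config()` fixes one emulated imaging session. Defaults are the
study conditions: 2 s frames for 5 400 s, baseline 100 arbitrary units,
a gentle cubic relative drift, additive Gaussian noise of 10 units
(dF/F noise 0.1, one fifth of the default spike amplitude 0.5), tent
spike kernels with rise 15.4 ± 5 s and fall 24.1 ± 7 s, a 4 s (two
frame) nuclear lead for dual-channel pairs, responder probability 0.7,
6.25 spiking cells per responding plant-hour over the whole region
(5/0.8, so that the expected rate within the 200 µm window — which
holds 80% of spikes — is the reported five), and an 80/20
meristem/elongation position mix. Where the study reports a number, the
default is that number; where it does not (noise level, dispersions,
amplitude, responder probability, the mutant-preset multipliers, the
growth-regression coefficients), a value typical of this kind of
recording was chosen once and is documented here as invented. The
`low_frequency` and `slow_kinetics` presets encode direction of effect
only.

The tent kernel is the benchmarking default because its onset, peak and
end are analytic, so ground truth is exact; a double-exponential kernel
is provided for realism, with ground-truth boundaries defined as the 5%
-of-amplitude crossings. Everything is deterministic under a fixed
seed, to the byte, including CSV and TIFF output.

What the generator does **not** emulate — and hence what passing
recovery tests cannot certify about real data: motion and focus drift
beyond a smooth polynomial, photobleaching with spike-correlated
structure, indicator saturation or nonlinearity, overlapping or
repeated spikes within a cell, cell-to-cell optical cross-talk, and
non-Gaussian noise beyond the optional Poisson mode.

## Imaging front end

The in-scope portion of the original image preprocessing: constant or
per-frame-percentile background subtraction (clipped at zero) and
circular-ROI mean-intensity extraction from multi-page 16-bit grayscale
TIFF stacks, plus a simulator that renders nuclei as Gaussian blobs
whose brightness follows simulated traces (pixel values rounded to
integer counts so TIFF round trips are exact). Image registration is
explicitly out of scope.

## Numerical choices and degenerate inputs

* Polynomial fits run on unit-rescaled time for conditioning;
  coefficients are reported in ascending degree on the seconds axis,
  and subtracting the evaluated polynomial reproduces the detrended
  series to 1e-9.
* Thresholds are floored at $10^{-9}$ of the signal range so that
  noiseless series (MAD exactly zero) are still scannable.
* An absolute amplitude floor of $10^{-6}$ dF/F rejects rounding-level
  maxima on effectively constant traces.
* Ties at the peak break to the earliest frame; boundary scans start at
  the frames adjacent to the peak.
* Non-uniform sampling beyond a 1% relative tolerance is rejected, not
  resampled — resampling would silently change gradient estimates.
* Censored (edge-truncated) calls are emitted with a flag and excluded
  from cohort shape means.

## Problem sizes

The test-suite and acceptance computations use 200 single-spike traces
for recovery benchmarking, 1 000 random series for the peak-localisation
oracle, 100 for the boundary oracle, a 50-plant cohort (~300 detected
spikes) for end-to-end recovery, 200 simulated cell pairs for origin
statistics, and 48×48-pixel movies for the imaging round trip. These
sizes put the binomial and standard-error bounds being asserted well
inside detectable range while keeping a full run in tens of seconds.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42, n_plants = 12)
coh <- simulate_cohort(cfg)

fits <- detect_spikes(coh$collection)
calls <- spike_calls(fits)
shape_means(calls)

summ <- summarize_plants(calls, coh$plants, coh$positions)
responder_fraction(summ)
partition_by_zone(calls, coh$positions,
                  coh$plants[, c("plant_id", "boundary_um")])
correlate_growth_spiking(growth_records(coh$plants), summ)
```

## Known limitations

The detector is a single-template, single-scale method: it assumes one
dominant transient shape and will split strongly multi-peaked events.
Kinetics estimates degrade below an amplitude-to-noise ratio of about
three, and spikes near that level are detected with noticeable
selection effects. Absolute calcium concentrations are out of reach by
design — the pipeline quantifies indicator fluorescence only. The
origin classifier resolves onset order only down to the few-frame lags
discussed above.
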