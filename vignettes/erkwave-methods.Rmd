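---
title: "Quantifying intercellular ERK activation waves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intercellular ERK activation waves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erkwave)
```

## The phenomenon and the measurement problem

In live imaging of epidermis expressing a FRET biosensor for ERK, kinase
activity is read out per cell as the acceptor/donor (FRET/CFP) intensity
ratio. Two propagation phenomena are quantified by this package:

* **SPREADs** -- transient bursts of ERK activation that start in a small
  group of cells and travel outward as a radial wave, with the amplitude
  and the probability of responding decreasing away from the origin;
* **wound-edge waves** -- repetitive, planar ERK activation waves that
  emerge parallel to a wound edge and propagate into the tissue with
  *undiminished* amplitude (trigger-wave behaviour).

The raw data are two-channel time-lapse stacks. The quantities of
interest are geometric and kinetic: the wave's origin, onset, velocity,
spatial radius, per-cell pulse duration and amplitude, the association of
cell division with recent ERK activity, clustering of wave origins, and
cell-cycle composition from Fucci reporters.

## Pipeline overview

`compute_ratio_stack()` forms the masked pixelwise FRET/CFP ratio
(optionally 3x3-median-filtered); `segment_nuclei()` segments nuclei by
adaptive local thresholding (foreground = intensity at least 30 native
units above the local mean in a window of three maximal nucleus
diameters; components kept when their equivalent diameter lies in 4-10
px); `extract_traces()` averages the ratio over each static nucleus mask
per frame. Static masks are deliberate: epidermal nuclei move little
over the hours analysed, and a single reference mask (temporal-mean
donor image) avoids tracking errors. Per-cell analysis then proceeds on
the trace table alone, so pre-extracted traces can enter the pipeline
directly.

## Per-cell model: flat line versus a sum of sines

Each trace is smoothed by a centred moving average spanning 15 min (the
smallest odd number of frames covering it; 11 frames at 90-s intervals).
The smoothed trace is first fit by a flat line. If the mean squared
residual (MSE, squared-ratio units) is below 0.003 the cell is a
**non-responder**. Otherwise sine components are added one at a time,

$$f(t) = b + \sum_{j=1}^{k} A_j \sin(2\pi t / T_j + \varphi_j), \qquad
k \le 3,$$

stopping as soon as the MSE drops below 0.003; any cell not adequately
fit by the flat line is a **responder**, and a responder still above
threshold at $k = 3$ is flagged `poor_fit`. The threshold, the 15-min
smoothing, the cap of three components and the search span of the origin
optimisation below are fixed constants of the original analysis
procedure; the
residual metric (`mse` vs `rmse`) and whether it applies to smoothed or
raw residuals are configurable in `fit_config()` because the procedure's
description leaves them ambiguous -- the defaults (MSE, smoothed) are
the simplest reading consistent with a fixed 0.003 cutoff given ratio
noise of order 0.02.

Fitting uses variable projection: for fixed periods the baseline and the
amplitude/phase pairs (as $a_j \sin + c_j \cos$) are solved by linear
least squares, and only the periods are optimised by
Levenberg-Marquardt, seeded from a deterministic geometric grid between
two frame intervals (the Nyquist bound, also the lower box constraint)
and twice the window length. For $k > 1$ the starts extend the best
$(k-1)$-component solution, so the residual sequence over
flat, 1, 2, 3 components is non-increasing by construction. Ties among
equal-MSE solutions resolve to the smallest $k$, then the first start.

### Pulse parameters and the pulse base

Peak time and peak ratio are read off the fitted curve on a fine grid
(1/20 frame interval). Two subtleties required design decisions:

* **Parameters come from the fully refined fit.** The 0.003 stopping
  rule classifies cells and reports the minimal adequate model order,
  but a single sine that merely *passes* the threshold can be a
  shape-compromise (long period, raised constant term) whose half-max
  width is several minutes off. Pulse parameters are therefore extracted
  from the three-component refinement, whose curve tracks the pulse
  shape to residuals far below threshold.
* **The pulse base is read off the curve, not the constant term.** Sine
  components have non-zero means over a finite window, so even a
  near-perfect fit's constant term $b$ sits well above the resting
  level of a one-sided pulse. The base is instead the higher of the
  fitted curve's minima on the two sides of the peak (the topographic
  prominence convention of standard peak-width routines). The
  **duration** is the contiguous time around the peak with
  $f(t) \ge \mathrm{base} + 0.5\,(\mathrm{peak} - \mathrm{base})$,
  crossings interpolated linearly; the **amplitude** is
  $\mathrm{peak} - \mathrm{base}$. On a generator half-sine of width
  $\tau$ this recovers the analytic duration $(2/3)\tau$ and the true
  amplitude; measuring against the constant term instead gave durations
  biased by up to ~7 min and amplitudes halved. A consequence worth
  knowing: for a trace that oscillates for the whole window (a pure
  sine), the half-prominence width is $T/2$, not $T/3$.

## SPREAD geometry

With classified cells in hand, `optimize_origin()` refines a visually
chosen origin by exhaustive search over integer pixel offsets within
+/-10 px, maximising the Pearson correlation between responder distance
and peak time (ties: smallest offset, then lexicographic).
`estimate_velocity()` regresses distance (response) on peak time
(predictor) -- this orientation makes the slope directly um/min -- and
dates the SPREAD onset at the zero-distance intercept; note this
regression-based onset includes the half-pulse lag, because it is
anchored to peak times. `fit_sqrt_law()` fits $d = a\sqrt{t - t_0}$
(with $t_0$ bounded by the earliest peak) as the diffusion-like
alternative; over a typical 30-min observation window the two fits'
$R^2$ differ by less than 0.1 on data generated from either law, which
is exactly why the in vivo analysis could not decide whether the wave
decelerates -- the package reproduces that indeterminacy as a property
test rather than pretending to resolve it.

The **radius** uses annuli (10 um wide by default) rather than
cumulative disks: the original description of growing circles could be
read either way, but cumulative fractions smear the 50% crossing
outward, while distance classes keep it local. Annuli with fewer than
5 cells are excluded (the in vivo analysis likewise dropped a
sparsely populated central class). The radius is the first 50% crossing moving outward,
linearly interpolated between annulus centres; the inflection-point
variant (steepest decrease of the profile) is emitted alongside as a
secondary estimate, since both definitions are in use. The **SPREAD-level duration** is
operationalised as the width at half maximum of the responder peak-time
histogram (5-min bins, inclusive first-to-last bin span); the in vivo
analysis did not fix an exact per-SPREAD duration definition, so
outputs label the quantity as this operationalisation.

`detect_spread_candidates()` (grid-density maxima of responder
positions) stands in for visual SPREAD scoring only as a convenience to
seed the origin search; it is plumbing, not part of the published
procedure.

## Wound-edge waves

`distance_to_edge()` projects each cell onto a polyline wound edge
(static, drawn at the start of the analysed segment).
`estimate_wave_velocity()` applies the same distance-on-peak-time
regression keyed to edge distance within a user-supplied time window
isolating one wave; wave separation is manual because the published
analysis treated a single wave segment. `amplitude_vs_distance()`
reports the per-cell amplitude trend against edge distance -- flat (95%
CI covering zero) for generator trigger waves, significantly negative
for decaying SPREAD data through the same code path.

## Division enrichment and origin clustering

The **SPREAD area** is the spatio-temporal union of cylinders (100 um
around each origin, 1 hr after each onset), clipped to the field and
span; overlaps are unioned, never double-counted. Its volume is
computed by rasterisation (2-um grid by default) over the time intervals
between onset/offset breakpoints; a finer grid and a Monte Carlo oracle
agree within 1%. Division rates in events/mm^2/hr inside and outside
give the enrichment ratio.

The clustering test uses the mean nearest-neighbour distance of SPREAD
origins against a Monte Carlo null of uniform points in the analysed
rectangle, one-sided for clustering, with the standard +1 correction
($p = (1 + \#\{\text{null} \le \text{obs}\}) / (n_{\text{trials}} + 1)$)
so $p = 0$ is unattainable. A toroidal metric variant exists purely for
validation: without edge effects the null mean must equal
$1/(2\sqrt{\lambda})$, which the suite checks to 3%. Calibration
($P(p \le \alpha) \approx \alpha$) and power against Thomas-process
clusters are tested explicitly.

## Fucci cell-cycle classification

S/G2/M nuclei are segmented on the zero-clipped difference mAG - mKO2
and G0/G1 nuclei on mKO2 - mAG, with the same adaptive-threshold
segmentation; negative values are clipped because the published
subtraction does not state its negative handling. Detections
overlapping between the two difference images are resolved to the
channel with the greater mean intensity -- the original analysis does
not say how doubly-positive (early-S, "yellow") cells were handled, so
the majority-intensity rule is this package's choice and the resulting
phase masks are disjoint by construction. An optional pre-filter
removes small objects saturated in both channels (melanin granules).

## The synthetic-data generator

Because the underlying in vivo two-photon data are not deposited, every
estimator is validated against `simkin`-style synthetic fields whose
ground truth is known exactly:

* nuclei are non-overlapping disks (jittered grid by default; dart
  throwing optional), with per-cell baselines $\mathcal{N}(1.2, 0.03^2)$
  and i.i.d. Gaussian ratio noise of 0.02 per frame;
* a SPREAD is a half-sine pulse
  $A(d)\,\sin(\pi (t - t_i)/\tau)$ on $[t_i, t_i + \tau]$ with
  $t_i = \text{onset} + d/v$: closed-form peak time ($t_i + \tau/2$),
  peak elevation $A(d)$ and above-half-max duration $(2/3)\tau$ make it
  the natural oracle for a sine-fitting analysis;
* the default pulse width is $\tau = 70.5$ min so the true single-cell
  duration is 47 min, matching the published mean;
* responder probability is logistic in distance with midpoint
  `radius_um` -- the 50%-radius definition is then the generator's
  ground truth by construction -- and amplitude decays linearly
  (`amp_decay_per_um = 0.005`, i.e. halved at 100 um; exponential decay
  is available). The published account says only that amplitude
  decreases with distance; the linear default is a stated choice, not an
  inference from data;
* wound waves use the same pulse with constant amplitude, constant
  responder probability 0.9 within a 100-um reach, and delays keyed to
  edge distance;
* divisions are an inhomogeneous Poisson process (thinning) with one
  rate inside the SPREAD-area union and another outside; Fucci fields
  assign phases Bernoulli or in exact-count mode; origin patterns are
  uniform (CSR) or Thomas parent-offspring with toroidal wrapping;
* analysis windows in all presets cover every pulse with at least one
  smoothing window of flat trace on each side -- pulses flush against
  the window edge bias the prominence base and were the one observed
  source of systematic amplitude error.

`render_stack()` inverts the imaging module (donor disks at a constant
level, acceptor = ratio x donor), so segmentation plus extraction on a
noiseless render must return the generator traces to 1e-6 -- a
round-trip identity the suite enforces.

One preset deserves explanation: the SPREAD-duration scenario tunes the
velocity so that the analytic half-max width of the responder peak-time
density equals 30.5 min. The histogram estimator at 5-min bins is
quantised, and the number of responders per SPREAD is physically capped
near 200 by nucleus packing, so independent Bernoulli responder draws
leave the single-field estimate a coin flip between 25 and 35 min. That
preset therefore (a) assigns responders by *systematic* thinning along
the distance order -- a stratified variance-reduction device that keeps
the marginal responder fraction at every distance identical while
removing Bernoulli noise -- and (b) is evaluated as a mean over eight
replicate SPREADs, mirroring the eight-SPREAD mean behind the published
30.5 +/- 5.6 min. All other scenarios keep independent draws.

### What the generator does not emulate

No photon/multiplicative noise (additive Gaussian on the ratio only), no
photobleaching, no cell migration or tracking errors, no melanin
autofluorescence, no mechanistic ligand diffusion -- the pulse shape is
phenomenological. Passing recovery tests therefore demonstrates that
the estimators are correct and unbiased under the stated statistical
structure, not that they are robust to every imaging artefact of real
two-photon data.

## Numerical choices and degenerate inputs

Periods are box-constrained to at least two frame intervals; duplicate
periods make the linear subproblem rank-deficient and aliased
coefficients are zeroed. The origin search never leaves its +/-10-px
square and errors out when peak times are constant (undefined
correlation) or fewer than three responders exist. Radius estimation
requires two usable annuli and flags profiles that never cross 50%
("unbounded") or start below it ("all_below"). The IMD display uses
half-open bins with clipped ends (8 hues x 32 grades), so the range
midpoint falls in the fifth hue bin. Fits are deterministic given the
configuration; the `seed` in `fit_config()` exists only for interface
stability.

## Test problem sizes

The routine suite runs scaled-down scenarios (150-250 cells per field,
2,000-trial Monte Carlo nulls, 15 division replicates); the acceptance
suite runs the full presets (350-1,000 cells, 10,000-trial nulls, 50
division replicates, 200-run calibration). These sizes are the
package's chosen compromise between statistical resolution and a test
suite that runs in minutes on one core.

## Known limitations

Static segmentation masks misattribute signal if nuclei move more than
a radius; the sine-sum model cannot separate pulses closer than the
smoothing window; the wound analysis assumes a static edge; the
division-rate comparison treats the field as homogeneous apart from the
SPREAD areas; and the CSR test conditions on the observed number of
origins, treating repeated origins at one spot as distinct points.
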