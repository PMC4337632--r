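# erkwave

Quantification of intercellular ERK activation waves in epidermal
time-lapse FRET imaging.

In skin expressing an ERK FRET biosensor, kinase activity per cell is
the acceptor/donor (FRET/CFP) intensity ratio. Occasionally a small
group of cells fires and the activation propagates outward cell-to-cell
as a radial wave (a *SPREAD*); near wounds, repetitive planar waves
travel in from the edge with undiminished amplitude (trigger waves).
`erkwave` is for researchers who need to turn such two-channel stacks
(or pre-extracted per-cell traces) into wave statistics: velocities,
radii, durations, amplitudes, their association with cell division, the
spatial clustering of wave origins, and Fucci cell-cycle composition.

## The model at the core

Each cell's smoothed ratio trace $y(t)$ is classified by nested least
squares: a flat line first, and if its mean squared residual is at
least 0.003 (squared-ratio units), a sum of sine curves

$$f(t) = b + \sum_{j=1}^{k} A_j \sin\!\left(\frac{2\pi t}{T_j} + \varphi_j\right),
\qquad k \le 3,$$

adding components until the residual falls below 0.003. Cells fit by
the flat line are non-responders; the rest are responders and carry
pulse parameters read off the fitted curve: peak time, peak ratio, and
the duration above half of the peak's topographic prominence. SPREAD
geometry then follows from the responders: the origin maximises the
correlation between distance and peak time over a +/-10-pixel grid;
the velocity is the OLS slope of distance on peak time (um/min); the
radius is where the responder fraction in 10-um annuli first crosses
50%; and a square-root law $d = a\sqrt{t - t_0}$ is fit alongside the
line for model comparison. Origin clustering is tested by Monte Carlo:
the mean nearest-neighbour distance of observed origins against
uniform placement, one-sided for clustering.

Because the original in vivo data are not public, the package ships a
synthetic-data generator (`place_cells()`, `simulate_spread_traces()`,
`render_stack()`, `simulate_divisions()`, `simulate_fucci_field()`,
`simulate_origin_pattern()`) with closed-form ground truth — half-sine
pulses with logistic responder probability — against which every
estimator is validated end-to-end.

## Worked example

One synthetic SPREAD whose true velocity is 1.93 um/min (350 cells,
90-s frames, ratio noise 0.02), run through the full pipeline:

```r
library(erkwave)
sc <- synthetic_spread6(seed = 42)        # generator + ground truth
fits <- fit_pulses(sc$traces)             # flat-vs-sine classification
fits
#> pulse_fit_set: 350 cells, 122 responders (34.9%)
#>   responder peak ratio 1.444 +/- 0.034, duration 46.9 +/- 1.2 min

sf <- analyze_spread(fits, sc$truth$origin_xy_um + 5 * sc$config$pixel_size_um,
                     pixel_size_um = sc$config$pixel_size_um)
sf
#> SPREAD analysis
#>   origin (74.1, 75.0) um, onset 45.2 min (peak-time corr 0.982)
#>   velocity 1.90 um/min (R^2 0.964); sqrt fit a = 9.06, R^2 0.820
#>   radius 48.8 um [ok] (inflection 50.0 um), duration 20 min
#>   122 responders / 350 cells, max amplitude 0.300
```

Reading this: starting from an origin guess deliberately offset by 5
pixels, the grid search lands within one pixel of the true origin
(75, 75); the distance-versus-peak-time regression recovers 1.90 um/min
against a truth of 1.93; the 50% responder-fraction crossing puts the
radius at 48.8 um against a generator midpoint of 47.7 um; and the mean
fitted single-cell duration (46.9 min) matches the generator half-sine's
analytic 47 min. The "onset" is the regression's zero-distance
intercept, which is anchored to peak times and therefore includes the
half-pulse lag (10 + 70.5/2 ≈ 45 min here).

Clustered wave origins are detected against the uniform null:

```r
cl <- synthetic_clustered_origins(seed = 21)   # Thomas process, 20 points
mc_csr_test(cl$points, cl$region_um, n_trials = 10000, seed = 22)
#> Monte Carlo test of complete spatial randomness
#>   mean NN distance = 21.37 um (null mean 57.05 um), n = 20 points
#>   one-sided p = 9.999e-05 (10000 trials, planar metric)
```

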