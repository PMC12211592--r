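---
title: "Gait-space methods: phases, the hypertorus metric, clustering and stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-space methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitspace)
```

This vignette is the package's own account of its methods: the models and
assumptions, the tunable parameters and their defaults, the numerical
choices, what the synthetic-data generator does and does not emulate, and
the known limitations. Everything shown here is computed by the code in
this package; nothing is quoted from elsewhere.

## From tracks to phases

The input is a dorsal-view, fixed-frame-rate time series of 2-D landmarks
in mm: the body center of mass (COM), cranial and caudal body points, and
up to eight tarsus tips labeled `L1 L2 L3 L4 R4 R3 R2 R1` — the canonical
circuit from the foremost left leg, counterclockwise, to the foremost right
leg. Missing leg columns mean autotomized legs.

**Derivatives.** All velocities are slopes of a running least-squares
quadratic over a centered window: 50 ms for the COM and 40 ms for tarsi by
default. These window lengths are chosen so the smoothing changes the data
by no more than typical tracking uncertainty while suppressing frame-level
jitter; the filter is exact for locally quadratic motion, and on a
sinusoid of frequency $f$ it attenuates the derivative by a computable
factor $G = \sum_j j \sin(j\omega\Delta t) / (\omega\Delta t \sum_j j^2)$
(about 0.94 at 6 Hz, 40 ms, 500 Hz), which the test suite checks against
the closed form. Edge frames use truncated one-sided windows (degree
reduced when fewer than three samples remain) so all per-frame series stay
aligned; the first and last half-window of any derived series should be
treated with corresponding caution.

**Body frame.** Each frame is translated so the COM is at the origin and
rotated so the instantaneous COM velocity points along +y. The transform is
a rigid motion, so distances between landmarks are preserved. When the COM
speed falls below `min_speed` (default 1 mm/s) the heading is undefined and
the frame is flagged invalid rather than oriented arbitrarily.

**Phase.** For a harmonic oscillator $y = A\cos\omega t$ the phase is
exactly $\mathrm{atan2}(-v, \omega y)$. Standardizing position and velocity
to zero mean and unit variance eliminates both $A$ and $\omega$, so the
effective phase of any oscillatory signal is estimated as
$\varphi = \mathrm{atan2}(-\hat v, \hat y)/2\pi \bmod 1$. Standardization is
over the whole trial: per-stride or per-segment standardization would
reduce sensitivity to speed changes but adds segmentation noise, and
trials here are short, near-constant-speed runs. A fully dragged leg has
(near) zero variance and is rejected as un-phaseable rather than silently
assigned a phase.

## The gait space and its metric

The gait at a frame is the vector of adjacent-leg phase differences
$\Delta\varphi_i = (\varphi_{i+1} - \varphi_i) \bmod 1$, $i = 1 \dots
N_\mathrm{legs}-1$, a point on a hypertorus. Adding a common phase to all
legs — advancing the whole cycle — does not change the gait, which is why
only the $N-1$ differences are kept.

Distances come from quotienting the flat, unit-weight leg-phase torus by
that common phase. Writing the per-leg phase differences between two gaits
as $u_k$, the quotient distance is $\min_c \sum_k (u_k - c)^2 =
u^\top(I - J/N)u$; expressing this in successive-difference coordinates
$\delta_i = u_{i+1} - u_i$ induces

$$g_{ij} = (N - \max(i,j)) - \frac{(N-i)(N-j)}{N},$$

a symmetric positive-definite matrix with all entries positive. The package
wraps each coordinate difference to its minimal signed representative in
$(-0.5, 0.5]$ before contracting: keeping the sign is what makes the
quadratic form agree with the brute-force quotient distance (the test suite
checks 100 random near-field pairs against a grid minimization over the
common offset to a relative error below $10^{-3}$), whereas contracting
unsigned magnitudes with the all-positive $g$ would overestimate whenever
successive differences disagree in sign. At separations approaching half a
cycle per coordinate the single-chart form is an approximation to the true
torus quotient; model-gait anchors live well inside the chart.

The maximum distance $d_\mathrm{max} = \sqrt{0.25\sum_{ij} g_{ij}}$ is
attained when every coordinate is half a cycle apart, and normalized
distances $\Delta = d/d_\mathrm{max}$ lie in $[0,1]$:

```{r metric}
m6 <- metric_tensor(6)
m6$g
gait_distance(model_gaits(6)$ABT, model_gaits(6)$MT, m6)
```

The two six-leg model gaits — modified tripod (all 0.5) and ablated
tetrapod ((0.5, 0.5, 0, 0.5, 0.5)) — differ in one coordinate and sit at
$\Delta = 0.29$.

## Clustering and model naming

Pairwise normalized distances over all frames feed agglomerative
clustering with Ward's criterion via the Lance–Williams update
(`stats::hclust`, method `ward.D2`), applied directly to the precomputed
non-Euclidean distances. Ward's variance interpretation formally requires
Euclidean input; we follow the field's practice of using it anyway and
treat recovery of known mixtures in simulation as the validation (at
$\kappa = 4$, a 1000+1000 ABT/MT mixture is grouped with the originating
model for more than 95% of samples). The dendrogram is cut below its
$k-1$ highest merges; $k$ is a parameter (convention: 3 for empirical
datasets, 2 for two-model simulations) and no automatic gap statistic is
attempted. Cluster centroids are per-coordinate circular means; clusters
are named by the nearest model gait, numbered by increasing centroid
distance, with exact ties broken by canonical model order (ALT, ABT, MT)
and logged. The per-point baseline classifier
(`nearest_model_assignment`) uses the same distances and tie rule.

## Stability and posture measures

The support polygon of a frame is the convex hull of the tarsi in stance;
`n_support` counts stance tarsi including hull-interior ones. The static
stability margin (SSM) is the minimum distance from the COM projection to
the hull edges, positive inside, zero on the boundary, and the *negated*
distance to the hull when the COM is outside or fewer than three
non-collinear supports exist — a defined value in unstable frames is
needed for median/MAD summaries. The ideal margin (ISSM) evaluates the
same functional with the COM at the area centroid (not the Chebyshev
center: the centroid is the posture-balance reference). For regular
polygons the centroid margin is maximal and SSM ≤ ISSM; for irregular
hulls that inequality is not a theorem under the centroid definition, so
the package reports both without enforcing it.

Stance is detected from the sign of motion relative to the body: a tarsus
is in stance while its body-frame fore–aft velocity is below −2 mm/s
(default), with runs shorter than 3 frames removed. The threshold absorbs
tracking-derivative noise; the limiting case of a dragged tarsus (zero
velocity relative to the COM) is never in stance and yields duty factor 0.
Duty factor is the fraction of a stride's frames in stance, with stride
boundaries at plateau-aware peaks of the tarsus velocity along the motion
direction (minimum separation half the dominant autocorrelation period,
minimum prominence half the series s.d. — the data give no sharper
prescription).

Range-of-motion areas remove outliers before taking the hull: points whose
radial distance from the coordinate-wise 2-D median exceeds the median of
those distances by more than 3 scaled MADs are dropped. The rule is
one-sided — points unusually *close* to the median are not spatial
outliers — and uses the 1.4826 consistency constant. Adjacent-leg spacing
compares the circular-mean bearing gaps to the uniform expectation
$360/N$ degrees (45 for eight legs, 60 for six).

## The synthetic-data generator

`synth_trial` emulates what the analysis consumes: a straight
constant-speed run at 500 frames/s with each present tarsus oscillating
fore–aft about a leg-specific anchor, phase-offset according to a model
gait. The waveform is a duty-factor-asymmetric sawtooth (linear retraction
over the stance fraction, faster linear protraction over the swing
fraction); with the default amplitude $A = v\,\mathrm{duty}/f$ the tarsus
is exactly stationary in the lab frame during stance, making stance/swing
ground truth exact. Defaults, chosen once as a realistic juvenile-spider
regime and used unchanged throughout the tests: stride frequency 6 Hz,
speed 120 mm/s, body length 12 mm (10 BL/s), duty 0.5. Optional per-stride
von Mises phase jitter and Gaussian coordinate noise (0.4 mm emulates a
±0.8 mm tracking uncertainty) add measurement realism. Simulated gait
*points* (`sample_gait_points`) perturb each coordinate independently with
von Mises noise; correlated noise across leg pairs is not modeled.

What the generator does **not** emulate: turning and speed modulation,
stumbles and recovery maneuvers, leg dragging, body bounce or any vertical
motion, and waveforms of real tarsal trajectories. Passing round-trip
tests on these fixtures therefore demonstrates the correctness of the
estimation chain, not that real recordings are this clean; on real data
the phase estimator's robustness to amplitude/frequency noise and the
stance threshold carry the weight.

At duty 0.5 the ideal footfall patterns reproduce the model support
counts exactly:

```{r footfall}
table(footfall_pattern(model_gaits(8)$ALT, duty = 0.5)$n_support)
table(footfall_pattern(model_gaits(6)$MT,  duty = 0.5)$n_support)
table(footfall_pattern(model_gaits(6)$ABT, duty = 0.5)$n_support)
```

## Numerical choices

- Phases and phase differences are held in $[0,1)$ cycles; signed minimal
  differences use the $(-0.5, 0.5]$ convention so exact antipodes are
  unambiguous (+0.5).
- Circular means within $10^{-12}$ of a full turn snap to 0.
- Peak plateaus (analytically flat velocity segments) are grouped with a
  tolerance of $10^{-8}$ of the series range and reported at the plateau
  center, so flat-topped profiles give stable stride boundaries.
- The von Mises sampler is the Best–Fisher (1979) rejection method;
  $\kappa$ estimation inverts $A(\kappa) = I_1(\kappa)/I_0(\kappa) = \bar R$
  with the standard rational approximation refined by Newton steps on the
  exponentially-scaled Bessel ratio. $\bar R = 1$ flags infinite
  concentration instead of returning a number.
- Bootstrap CIs are percentile intervals over 1000 resamples by default,
  with an explicit seed argument; the caller's RNG stream is restored
  afterwards.
- Short tracking gaps (≤ 3 frames) are linearly interpolated with a
  warning at read time; longer gaps in a present leg are an error rather
  than a guess.
- Test problem sizes (6–10 synthetic strides, $10^3$–$10^4$ circular
  samples, 1000+1000 mixtures) are the package's chosen validation scale:
  large enough that stochastic properties concentrate, small enough to run
  a full suite in well under a minute per module.

## Known limitations

- Single-chart gait distances at large separations (above), and Ward on
  non-Euclidean distances (above).
- Phase estimation assumes one oscillation per stride per leg; behaviors
  like double-stepping or mid-trial gait reversal smear the phase rather
  than segmenting it (no continuous unwrapping across stumbles).
- Static stability is quasi-static; dynamically stable gaits can run at
  SSM < 0.
- The allometric helper (`predicted_length_exponent`) only propagates
  first-order errors through a product of power-law exponents; it does not
  fit the underlying regressions.
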