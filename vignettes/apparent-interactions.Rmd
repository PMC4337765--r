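---
title: "Apparent interaction rules from fixed mutual positions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Apparent interaction rules from fixed mutual positions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockdual)
```

## The model

`flockdual` simulates the null situation in which co-moving individuals
do not interact: they hold fixed target positions on one shared random
trajectory, and everything an interaction-inference analysis reports
about them is a consequence of that imposed geometry plus positional
noise.

**Common path.** The path is a sequence of `n_steps` steps. Speeds are
`S(t) = S0 + s · ε1(t)/max|ε1|` and turning angles
`T(t) = a · ε2(t)/max|ε2|`, where ε1, ε2 are independent sequences of
i.i.d. uniform values on [−0.5, 0.5] passed through a Gaussian spectral
low-pass filter. The max-abs normalization bounds speed in
`[S0 − s, S0 + s]` and turnings in `[−a, a]` while preserving the
filter's smoothness, so any linear rescaling of the filtered sequence
would cancel; none is applied. Headings accumulate turnings and
positions integrate speed along heading.

**Placement.** At each step a segment is drawn through the path point at
angle `configuration_angle` to the current step direction (0 =
front–back, π/2 = side by side); individuals occupy equally spaced
points `spacing` apart, centred on the path (±r/2 for two individuals,
{−r, 0, +r} for three). Centring keeps all individuals statistically
interchangeable with respect to the common path — the left/right and
front/back symmetries the analyses rely on — which is why we prefer it
over anchoring one individual on the path. Which individual takes which
offset is drawn once per flight and never changes, so roles are constant
within a flight and balanced across flights. The final step reuses the
preceding step direction, because the defining step `t → t+1` does not
exist at the boundary. Initial heading is 0 and the initial position the
origin: all analyses are relative, so the absolute pose is irrelevant.

**Recording noise.** Each individual's recorded track adds an
independent displacement per component: i.i.d. standard-normal values,
low-pass filtered with cut-off `displacement_cutoff`, then rescaled to
sample standard deviation `displacement_std` (default `spacing/2`).
Rescaling happens after filtering, per flight and per component, which
is the only option when flights are generated independently; pooled
displacement spread is then exact by construction. There is no
cross-correlation between individuals.

## The spectral filter

The filter multiplies the discrete Fourier spectrum by
`exp(−ω²/(2σ²))` with `σ = n / cutoff_period` and ω on the two-sided
index grid `{0, 1, …, ⌊n/2⌋, −(⌈n/2⌉−1), …, −1}`. This is the one
convention under which `σ = n/C` makes the output vary on a time scale
of order `C` steps. The envelope is symmetric, so the output is real;
the gain at ω = 0 is 1, so means are preserved. Filtering acts on the
raw series with circular boundary handling and no detrending or
windowing — trajectories (4096 steps) are long relative to the cut-offs
(300 and 20–100 steps), so wrap-around leakage is negligible. The fast
path is checked against a brute-force O(n²) DFT oracle to 1e−10 in the
test suite.

All randomness in a flight descends from one seed, with sub-streams
consumed in a fixed documented order (path speed noise, path turning
noise, offset assignment, then per-individual x and y displacement
series); an experiment derives per-flight seeds from one master seed.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `n_steps` | 4096 | steps | flight length |
| `base_speed` (S0) | 5 | a.u./step | mean step length |
| `speed_amplitude` (s) | 0.2 | a.u./step | speed modulation; must stay below S0 |
| `turn_amplitude` (a) | 0.02 | rad/step | curvature of the common path |
| `path_cutoff` (C_T) | 300 | steps | correlation time of speed/turning |
| `displacement_cutoff` (C_D) | 20 (alt. 100) | steps | correlation time of recording noise |
| `spacing` (r) | 5 | a.u. | target inter-individual distance |
| `displacement_std` | r/2 = 2.5 | a.u. | per-component noise amplitude |
| `dt` | 0.2 | s/step | 5 steps per second of time |

These defaults are the study conditions under which all the package's
documented behaviours were established; the qualitative patterns are
stable over wide parameter ranges. Experiments use 100 flights per
condition (120 for the leadership experiment), pooling roughly 8×10⁵
pairwise observations per condition.

## The analysis layer

Kinematics are computed from *recorded* displacements, never from the
ideal path — exactly what an observer of real tracks can do. Speed and
heading at `t` use the displacement from `t−1` to `t`; tangential
acceleration and turning rate attributed to `t` are forward differences
(`t → t+1`), so a response always follows the configuration it is
binned against. A response must follow, not precede, its stimulus; the
alternative indexing (binning the change `t−1 → t` against the
configuration at `t`) would make the "response" partially determine the
configuration. Heading differences are wrapped to (−π, π]. A zero-length
step leaves the heading undefined; the previous value is carried forward
and the step flagged, and flagged or boundary steps are dropped from the
observation table.

Internally angles follow the mathematical convention
(counter-clockwise positive). The reporting convention of the field's
force-map figures is right-positive — ϑ = 0 dead ahead, positive to the
focal's right; φ positive when the neighbour is oriented to the right —
and the conversion (a negation) happens once, in the pairwise
observation layer. The turning response column is negated with it, so
"turning toward a neighbour on the right" is positive against positive
ϑ.

**Grids and reliability.** Polar maps use 12 angular × 8 radial bins out
to 20 a.u.; (ϑ, φ) maps 12 × 12 bins over (−π, π]²; front–back profiles
and two-neighbour maps 1 a.u. bins over [−15, 15] (the shared 1 a.u.
grid is what lets the pairwise profile serve directly as the prediction
kernel). At ~8×10⁵ observations these resolve the map structures while
keeping per-cell standard errors well below the response amplitudes.
Cells with fewer than `min_count = 100` observations are flagged
unreliable and excluded from every summary — never silently averaged —
because the rare extreme-noise configurations they contain carry large
apparent responses that would otherwise masquerade as structure.
Observations outside a grid are dropped and counted, so cell counts plus
drops always reconcile with the input.

**Sign crossing.** The repulsion-to-attraction boundary is located on
the neighbour-ahead branch of the acceleration profile by linear
interpolation between the first adjacent pair of reliable bins with
opposite-sign means: standard, and independent of bin resolution. A
profile without a sign change reports the boundary as absent rather
than erroring, since the side-by-side condition genuinely has none.

**Modulation indices.** The modulation of the (ϑ, φ) turning map along
an axis is measured *conditionally*: within each bin of the other axis,
the range of reliable cell means along the axis of interest,
count-weighted-averaged over bins. Conditioning matters because the φ
response inverts sign between neighbour-ahead and neighbour-behind rows,
so a plain marginal cancels real alignment structure. Comparisons across
noise regimes use `phi_share` — the φ index as a fraction of the ϑ
index — because the overall amplitude of apparent responses scales with
how fast the noise reverts: at `C_D = 100` every response is roughly an
order of magnitude weaker than at `C_D = 20`, yet the alignment *share*
of the modulation rises sharply (≈ 0.10 → ≈ 0.54 at the defaults), which
is what a per-panel-normalized map view shows.

**Delays.** τ\* maximizes the mean cosine of heading differences over
lags in [−`max_lag`, `max_lag`], averaging only over the overlapping
index range (no wrapping or padding, which would manufacture correlation
across the flight boundary). `max_lag` defaults to 50 steps (10 s), far
beyond the displacement correlation scales studied. Ties break toward
the smallest |τ|, then toward positive τ — deterministic, and relevant
mainly for degenerate equal series. The leadership experiment computes
τ\* for both individuals of each flight and labels values by the focal's
role; the two values are antisymmetric whenever the argmax is unique, so
this reproduces the role-wise distributions regardless of which single
focal another implementation might have picked.

**Two-neighbour maps.** The focal is drawn uniformly per flight among
the three positions. Axis assignment of the two neighbours defaults to
nearest-by-|d_fb| at each observation; a `"random"` ordering is exposed
as well, and the axis-exchange symmetry property is stated under that
ordering. The pairwise-average prediction is
`(profile(d1) + profile(d2)) / 2` on identical bins.

## What the generator does and does not emulate

It emulates: a coherently moving pair or triplet with persistent speed
and heading fluctuations, fixed mutual arrangement, and tracking-like
positional noise with controllable temporal autocorrelation — the
minimal conditions for apparent interactions to arise from geometry
alone. It deliberately omits: any actual interaction rule, role
switching within a flight (real animals do exchange sides, which turns
banded repulsion zones into the circular ones seen empirically),
three-dimensional motion, occlusion or identity-swap tracking errors,
and speed–turning coupling. Passing tests therefore demonstrate
properties of the null model, not of real animal data; with real tracks
the package's analysis layer applies unchanged, but the generator's
guarantees do not.

## Known limitations

- The pairwise-average prediction indexes the profile by raw front–back
  distance, so in three-individual groups it implicitly treats every
  neighbour as if its target were the pair spacing ±r. At cells where
  the *far* neighbour (target ±2r) appears at an extreme distance this
  overstates the implied displacement and inflates the predicted range;
  the observed-exceeds-predicted modulation contrast is therefore clean
  for turning but can be marginal for acceleration at the default
  conditions. This is a property of the prediction procedure itself,
  not of the simulator.
- Heading is undefined at stalls; the carry-forward rule is a pragmatic
  choice and stalls are vanishingly rare at the default speeds
  (S ≥ 4.8 a.u./step).
- The filter's circular boundary handling injects a small amount of
  wrap-around correlation for cut-offs approaching the series length;
  keep `cutoff_period ≪ n`.

## Problem sizes

The documented experiments — and the package's acceptance checks — use
the full study conditions: 100 flights × 4096 steps per map condition,
120 flights for delay experiments, 10 × 2048 steps for the
regression-to-the-mean diagnostic. A complete condition simulates and
analyses in well under a minute on a single core; unit tests use shorter
flights (256–2048 steps) that exercise identical code paths.
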