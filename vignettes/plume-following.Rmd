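---
title: "Modelling olfactory plume-following in displaced migratory birds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling olfactory plume-following in displaced migratory birds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the modelling strategy

Displaced migratory birds sometimes find their way back to their usual
migration route, and birds with intact olfaction do so more reliably than
birds whose olfactory nerves have been sectioned. One candidate mechanism
is plume-following: volatiles emitted along the familiar migratory
corridor are carried downwind, and a displaced bird that smells
corridor-borne air could turn into the arriving airstream and follow it
back toward the route.

`plumetrack` operationalises that hypothesis as a testable pipeline. For
every (hourly interpolated) position along a bird's track it runs a
backward Lagrangian particle simulation: notional massless tracer
particles are released at the bird's location during a short reception
window in the lowest air layer and transported backward in time through a
gridded wind field. Binning the particles' residence times on an output
grid, under the assumption of a spatially uniform and constant surface
emission rate, yields a *source-contribution raster* (a footprint): how
strongly each upwind cell could have contributed odour to the air the
bird just received. Everything downstream — the information-persistence
correlogram, the per-bird accumulated-particle score, the
corridor-exposure classification and the reorientation statistics —
consumes these rasters and the tracks.

Because the pipeline's purpose is methodological validation rather than
reanalysis of any particular field data set, the package ships a
first-class synthetic-data module: seeded wind fields, corridor/goal
geometries, and behavioural agents that either do or do not react to
plume exposure. Every stage can therefore be exercised end-to-end with
known ground truth.

## The dispersion model

The simulator is a deliberately simple Lagrangian stochastic model:

* **Advection.** Each particle is stepped backward with the local
  interpolated wind, displacement $-(u, v)\,\Delta t$. Wind fields are
  multilinearly interpolated in longitude, latitude, height and time, and
  reproduce grid-node values exactly.
* **Turbulence.** A constant-diffusivity Gaussian random walk: per
  horizontal axis an increment of standard deviation
  $\sqrt{2 K_h \Delta t}$, vertically $\sqrt{2 K_z \Delta t}$ with
  reflection at the ground. There is no boundary-layer parametrization;
  a constant-$K$ model keeps the source-attribution semantics while
  remaining fully controllable and seedable.
* **Geometry.** Metres convert to degrees with the local per-latitude
  metric (111,195 m per degree of latitude, scaled by $\cos\varphi$ in
  longitude), adequate for the sub-kilometre per-step displacements the
  default time step produces. Particles terminate on leaving the wind
  domain; positions are binned into half-open cells whose centres sit at
  $(k + \tfrac12)\,\mathrm{res}$ from the domain origin.
* **Source attribution.** Each backward step deposits
  $\Delta t \times \text{emission rate}$ into the cell containing the
  particle; layers up to the highest configured top are summed. The
  raster total therefore equals the emission rate times the ensemble's
  total residence time exactly — a bookkeeping identity the tests check
  to floating precision.

Key knobs (see `dispersion_config()`): particle count (reference
configuration 100,000 per receptor; desk-scale runs use a few hundred to
a few thousand), maximum backward travel time (reference 72 h), time
step (600 s by default, a Courant-style compromise for 10–20 m/s winds
on 0.2° output cells), diffusivities ($K_h$ in m²/s dominates the
footprint width; $K_z$ is nearly irrelevant because the altitude layers
are summed), the 0.2° output resolution, the 5-minute reception window
and the 0–30 m receptor release layer.

Two independent routes validate the transport core. Closed forms: with
diffusion off, a uniform wind displaces every particle by exactly
$u\,\tau$; with wind off, the positional variance after age $\tau$ is
$2K\tau$ and the crosswind profile under a uniform wind is Gaussian.
Duality: a separately implemented *forward* simulator
(`simulate_forward()`) releases particles from an emitting cell and
accumulates residence time in the receptor's cell; on a closed domain the
backward source contribution must match it. The check is run at a
diffusivity where the spread comfortably resolves the grid cell, because
the residual difference between a point-release backward run and a
cell-averaged forward run is second order in (cell width / plume width).

## The raster statistics

**Correlogram.** For each bird and each lag of 1–48 h, up to 50 randomly
sampled (without replacement) ordered raster pairs separated by exactly
that lag are correlated (Pearson, over all cells) and averaged; the
per-bird means are summarised by a grand mean ± SD across birds.
Zero-variance rasters are skipped — the correlation is undefined there
and substituting any value would bias lag means. Two synthetic regimes
bracket the behaviour: under a frozen (time-constant) wind with
stationary receptors, rasters differ only by Monte-Carlo noise and the
correlogram sits near 1 at every lag; under a wind whose direction
rotates 15°/h over migrating receptors, the correlogram decays toward
zero within a day. The moving receptor matters in the second regime: a
pure constant-rate rotation is 24-h periodic, so a stationary receptor
would see its footprint repeat at lags 24 and 48, which is a property of
that idealised wind, not of real olfactory landscapes.

**Accumulated-particle score.** For each hourly raster at time $t$ the
raster is sampled (bilinearly; nearest-cell available for conservation
checks) at all track positions *later* than $t$ that pass the 2 m/s
activity filter; the grand sum is divided by the bird's number of track
locations. Sampling future active positions reads the score as "how much
of the modelled plume does the bird's subsequent active path intersect";
a current-position variant and an active-only denominator are provided
as options because the definition admits both readings. Group scores are
compared with a two-sided Wilcoxon rank-sum test (exact null for
combined n ≤ 20 without ties).

## Exposure, turns, and the reorientation statistics

A receptor counts as *exposed* when the fraction of its raster mass in
cells whose centres fall inside the corridor polygon reaches a threshold
(default 0.05 — the notion of "received corridor air" needs an explicit
cut-off to be testable, and the threshold is config-exposed for
sensitivity sweeps). The first exposure anchors the analysis for a bird;
later exposures are not re-analysed.

The *plume-arrival bearing* is measured from the backward trajectories:
for each particle, its position when it was last at least 30 km from the
receptor along its approach, and the circular mean of the bearings from
the receptor to those positions — i.e. the direction the arriving air
travelled its final approach from. This trajectory-based reading is
preferred to the instantaneous wind at the receptor because it is what
the particles actually did; the resultant length of the per-particle
bearings is reported as a confidence measure (it drops toward zero for
stagnant, purely diffusive air). Because this is a scalar direction
estimate, the pipeline runs the bearing ensembles at a higher particle
count than the rasters.

Turns are summarised by endpoint bearings: the bearing from the start of
the 500 km (along-path) window before the event to the event position,
and from the event position to the end of the 200 km window after, with
the signed turn `delta` wrapped to (−180°, 180°], positive clockwise.
Endpoint bearings are robust to positional jitter; both window lengths
are parameters (the before/after analysis is reported in the literature
with both 500/500 and 500/200 variants, so neither is hard-coded as
truth). A bird is classified *reoriented* when it was exposed and its
after-bearing is closer to the plume-arrival bearing than its
before-bearing was, by a configurable margin (default 8°, chosen to
exceed bearing-measurement noise plus great-circle drift on the window
legs).

The inferential layer implements the field's standard circular
statistics directly:

* `v_test()` — concentration around a prespecified direction,
  $V = n r \cos(\bar\alpha - \mu_0)$, $u = V\sqrt{2/n}$, one-sided
  normal upper-tail p. Its p-values are uniform under the circular
  uniform null (checked by simulation).
* `hotelling_paired()` — paired test on unit-vector differences
  $d_i = (\cos a_i - \cos b_i,\ \sin a_i - \sin b_i)$,
  $T^2 = n\,\bar d^\top S^{-1} \bar d$,
  $F = \frac{n-2}{2(n-1)} T^2 \sim F_{2,\,n-2}$. All-zero differences
  are reported as "no change" with p = 1 by convention; any other
  singular covariance is an error. Note this is a *mean-vector* test: a
  rigid rotation applied to directionally uniform before-angles leaves
  the mean difference at zero and is intentionally invisible to it; its
  power case is concentrated bearings, which is what migratory flight
  directions are.
* `chi_square_contingency()` — plain Pearson $X^2$ with no continuity
  correction by default; zero margins are an error. When a pipeline run
  produces a degenerate reorientation column (no bird, or every bird,
  reoriented), the pipeline reports p = 1 with a note rather than a test
  statistic: a column with no variation carries no evidence of
  association.
* `angle_turn_relation()` — OLS of the signed turn on the signed
  plume-relative arrival angle (both wrapped to (−180°, 180°]), with the
  Pearson correlation and its t-test p. A constant response returns
  slope 0 / correlation 0 rather than an error.

## The synthetic study and its design choices

`demo_scenario_spec()` defines the package's reference experiment, built
so the behavioural signal the pipeline must recover is present by
construction while everything else stays realistic in scale:

* A ~1600 × 2700 km domain at 0.5° wind resolution, with a steady
  southerly flow (air arriving from the south at 8 m/s) plus a small
  travelling sinusoidal perturbation (0.8 m/s amplitude, 6° wavelength,
  30 h period). The perturbation exists to make the wind — and hence the
  measured plume bearings — vary by a few degrees, as real winds do.
* A narrow north–south corridor strip in mid-domain and a goal area at
  its southern end. Agents are released in the north flying fixed
  compass headings fanned ±18–34° around due south: displaced birds
  holding courses offset from the route, migrating into a headwind. The
  smallest offset exceeds the reorientation margin plus the wind's
  directional variability plus bearing noise, so every reactive turn is
  classifiable; each start is placed (by integrating the hold-course
  kinematics) so the track crosses the corridor meridian inside the band
  where corridor air is within the model's look-back range.
* Reactive agents (labelled ION, the intact-olfaction group), once the
  exposure oracle fires, rotate toward the plume-arrival bearing by a
  gain of 0.8 per hourly step; non-reactive agents (ONS, the anosmic
  group) never respond. Any agent entering the corridor lands and stays
  put — the displaced leg of its journey is over — while hold-course
  agents drift past the narrow strip and keep flying. Track generation
  uses a cheap kinematic exposure oracle (a single pure-advection
  back-trace) whose arrival bearing is the same last-30-km reading the
  analysis later measures on particle trajectories, so the behaviour and
  the measurement refer to the same quantity.
* The landing rule is what gives the accumulation score its expected
  direction: a plume-follower resolves its displacement and stops
  collecting modelled plume material, while an anosmic bird keeps
  actively flying — and keeps sampling — for the whole study window.
  Because the score is normalised by *all* track locations (landed,
  inactive positions count in the denominator but contribute nothing to
  the numerator), reactive agents end with systematically lower scores.

Desk-scale problem sizes keep the full demonstration to a few minutes on
one CPU: 44-h tracks for 10 + 10 agents, 350 particles per raster
receptor (2000 for bearing ensembles), an 8-h look-back at a 15-min step,
and a strongly diffusive $K_h = 10^5$ m²/s so footprints are smooth at
those counts. The validation scenarios use their own sizes (4000
particles for the frozen-wind correlogram, 50,000 for the duality check).

What the generator does *not* emulate: mesoscale meteorology and fronts,
land–sea contrasts, altitude-dependent winds, wind drift of the birds
themselves, stopover behaviour, odour chemistry and perception
thresholds. Passing the synthetic recovery test therefore shows the
*pipeline* is sound — that the statistics detect plume-following when it
is present and report nothing when it is absent — not that real birds
follow plumes.

## Degenerate inputs and conventions

* Wind queries outside the spatial axes clamp to the boundary; times more
  than one step outside the time axis are an error naming the timestamp.
* Track rows with duplicate timestamps collapse to the first occurrence
  with a warning; out-of-range coordinates error with the row number.
* Receptors whose look-back window leaves the wind record are skipped
  with a warning, not an error, so a track series degrades gracefully.
* Per-receptor and per-agent seeds are derived deterministically from
  the top-level seed and the item index, making results independent of
  execution order; identical configuration and seed reproduce identical
  tables byte for byte.
* An undefined plume bearing (no particle ever 30 km away), an undefined
  raster correlation (zero variance), and an undefined bearing for
  coincident points are reported as `NA`/errors rather than silently
  substituted.

## Reproducing the validation

`scripts/acceptance.R` re-runs the whole validation from scratch against
the installed package — the closed-form physics checks, the duality
check, both correlogram regimes, the sampling-distribution checks of the
circular statistics, the exact rank-sum tail, and the full synthetic
experiment with its null variant — and writes the resulting numbers to a
JSON file. The same checks run as the package's test suite under
`tests/testthat/`.
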