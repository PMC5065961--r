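# plumetrack

Could a displaced migratory bird find its way back to its migration route
by smell? If volatiles emitted along the route are carried downwind, a
bird with intact olfaction that is exposed to route-borne air could turn
into the arriving airstream and follow it home — while an anosmic bird
could not. `plumetrack` implements the full analysis pipeline needed to
test this plume-following hypothesis on GPS-tracked birds and gridded
winds, plus a seeded synthetic-data module so the entire method can be
validated end-to-end with known ground truth. It is aimed at movement
ecologists and animal-navigation researchers.

## What it computes

**Backward dispersion footprints.** For each hourly track position
(receptor), massless tracer particles are released during a short
reception window in the 0–30 m layer and advected backward in time:

    dx = -(u, v) dt + N(0, 2 K_h dt)   (per horizontal axis)
    dz = -w dt      + N(0, 2 K_z dt)   (reflected at the ground)

Binning residence times on a 0.2° grid under a spatially uniform,
constant emission rate yields the source-contribution raster
S(cell) = emission_rate × Σ residence time — how strongly each upwind
cell could have contributed odour to the air arriving at the bird.

**Raster statistics.** A time-lag correlogram (mean Pearson correlation
of up to 50 random raster pairs per lag of 1–48 h, per bird, summarised
across birds) measures how long the olfactory landscape stays
informative; a per-bird accumulated-particle score (raster values
sampled at the bird's future actively-moving positions, summed and
divided by the number of locations) measures how much modelled plume
material a bird's path intersects, compared between groups with a
Wilcoxon rank-sum test.

**Reorientation statistics.** Corridor exposure (fraction of raster mass
inside the corridor polygon), the plume-arrival bearing (circular mean
direction of the particles' last 30 km of approach), before/after turn
analysis over along-path windows, and the field's standard tests:

- V test: `V = n r cos(ᾱ − μ₀)`, `u = V √(2/n)`, normal upper tail;
- paired Hotelling test on unit-vector differences
  `dᵢ = (cos aᵢ − cos bᵢ, sin aᵢ − sin bᵢ)`,
  `F = (n−2)/(2(n−1)) · n d̄ᵀS⁻¹d̄ ~ F(2, n−2)`;
- Pearson X² contingency of reorientation by treatment group;
- OLS of the signed turn on the signed plume-relative arrival angle.

## Worked example

The package's reference experiment: 10 reactive ("ION", intact
olfaction) and 10 non-reactive ("ONS", anosmic) agents displaced from a
north–south migratory corridor, migrating into a southerly headwind that
carries corridor air to them.

```r
library(plumetrack)
demo <- make_demo(seed = 1)
```

```
Demo study: 10 ION (intact) + 10 ONS (anosmic) agents, seed 1
  ION: 10 exposed, 9 reoriented (of 10)
  ONS: 10 exposed, 0 reoriented (of 10)
Reorientation-by-group contingency: X^2 = 16.36, p = 5.228e-05
Turn vs plume-arrival angle: slope = 1.001, p = 1.014e-11 (n = 9)
V test toward the plume direction: u = 4.240, p = 1.117e-05
Paired Hotelling before/after: F = 26.26, p = 0.0005581
Median accumulation score: ION = 3.474e+05, ONS = 4.56e+05
Accumulation Wilcoxon rank-sum: W = 8, p = 0.0007253
```

Reading the output: every agent received corridor air, but only the
smell-capable group turned toward it — 9 of 10 reactive agents are
classified as reoriented against 0 of 10 anosmic ones, an association
the contingency test finds far from random. The turn magnitude tracks
the angle at which the plume arrived relative to the flight direction
with slope ≈ 1 (each bird turns fully onto the arriving airstream), the
after-bearings concentrate on the plume direction (V test), and the
before/after bearing change is significant (paired Hotelling). Reactive
agents accumulate *less* modelled plume material than anosmic ones
(median score 3.5e5 vs 4.6e5): having followed the plume home, they land
and stop sampling, while anosmic agents keep flying. Re-running with
`turn_gain = 0` (no behavioural response anywhere) yields no reoriented
birds in either group and a null contingency result.

Individual stages are ordinary tibble-in/tibble-out functions:

```r
scen <- gen_scenario(demo_scenario_spec(seed = 1)$spec)
rasters <- run_receptor_series(track, wind, dispersion_config())
autoplot(rasters[[10]])                    # footprint map
cg <- correlogram(list(bird1 = rasters))   # lag correlogram
autoplot(cg)
tidy(v_test(c(350, 3, 12, 355), mu0 = 0))  # tidy one-row test summary
```

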