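---
title: "From Atlantic inflow to chick growth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From Atlantic inflow to chick growth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`larvadrift` simulates how interannual variability in the Atlantic Water
(AW) inflow to the Barents Sea propagates, through the drift of cod eggs
and larvae, into the food supply of a guillemot colony and ultimately into
chick body size. This vignette explains the model at each stage, the
parameters that matter, what the synthetic world does and does not emulate,
and the design choices made where the design was genuinely open.

## 1. The synthetic ocean

The stage is a regular lon/lat grid with fixed z-levels (default 0–300 m)
and daily time steps, carrying temperature, salinity, horizontal currents
and vertical diffusivity. Two along-coast jets are built in coast-following
coordinates, where the coastline is a smoothed polyline from Møre to
Varanger and every point has an along-coast arc `s` (km) and a signed
cross-shore distance `d` (km, positive seaward):

* a **coastal jet** (Coastal Water analogue): core 20–25 km offshore,
  Gaussian cross-shore profile, fresh at the surface nearshore with
  salinity increasing with depth (stratification), salinity < 34.9 at the
  core;
* an **Atlantic jet** (Norwegian Atlantic Current analogue): core ~85–110
  km offshore, warm (core > 3 °C at depth) and salty (> 34.9).

Velocities come from a streamfunction, for three reasons: the flow is
exactly non-divergent on the grid, the cross-shore Gaussian integrates in
closed form (σ = width/√(2π), so jet transport is exactly
`core_speed × width × effective depth` — the oracle used by the transport
tests), and any future structural change (e.g. a meandering core) remains
mass-conserving. The streamfunction is lightly smoothed (3×3 binomial,
two passes) before differencing because the distance-to-polyline field has
kinks at concave coastline vertices that would otherwise alias into
spurious velocities; physically, the smoothed current rounds capes.

Vertical structure is uniform over the top 50 m with an exponential taper
below (a sharp cutoff stores a half-value at the boundary level so the
gridded depth integral is exact). The seasonal cycle multiplies both jets
by `1 + 0.25·cos(2π(doy − 15)/365.25)` — a winter maximum, so the summer
(chick-rearing) inflow is weaker than the annual mean, as observed.
Interannual variability multiplies only the Atlantic jet. Background water
(2.5 °C, S = 34.95) is deliberately placed just above the AW salinity
threshold but below its temperature threshold, so the classifier resolves
all three water masses. Optional eddy perturbations (random Gaussian
streamfunction bumps) are off by default: no quantitative eddy statistics
were available to calibrate them, so they are exploratory knobs only.

The default full-coast scenario (`coastal_drift_scenario`) uses a 15-km
grid and 50-m levels — desk-scale stand-ins for the 4-km archive being
emulated. 25 km was tried and rejected: it under-resolves the 50-km-wide
coastal jet and the finite-difference noise strands nearshore particles.
An earlier design also migrated the Atlantic core onto the shelf downstream
(a Tromsøflaket-split analogue); it was removed because the migrating
streamlines squeeze the nearshore flow onto the coast and beach the
coastal-jet particles, and because the spawning banks already lie within
the foraging box's cross-shore span, so no migration is needed to deliver
offshore larvae into the box.

What the synthetic ocean does **not** emulate: real bathymetry, tides,
wind forcing, fjords and the Lofoten archipelago (the coastline is
smoothed), mesoscale variability, and the actual 1996–2011 hydrography. A
green test therefore establishes that the *mechanism* — supply of southern
larvae scaling with Atlantic inflow — operates in a physically coherent
stated world, not that any particular historical year is reproduced.

## 2. Water-mass transport

`section_transport` samples the fields along the straight section at the
native grid spacing, projects velocity on the section normal and sums
`v_n × Δs × Δz` per water-mass class. Classification uses strict
inequalities with the printed defaults (AW: T > 3 °C and S > 34.9; CW:
S < 34.9 south of 72.5° N); values exactly at a threshold are OTHER. All
thresholds are configurable because the 34.9 salinity cut is itself a
bias-adjusted value. Net transport is accumulated by default with an
`inflow_only` switch (the choice between net and inflow-only accumulation
was left open; net is the more common diagnostic). Layer thicknesses are
midpoint-split, with half-cells at the surface and bottom.

## 3. The egg/larva IBM

**Release.** 4500 eggs every third day from 1 March to 30 April — 21
events, 94 500 eggs — split equally across the 15 grounds (300 each),
since only the total is documented; the allocation rule accepts arbitrary
weights and conserves eggs by largest-remainder rounding. Ground
coordinates are approximate digitisations adjusted to sit ≥ 20 km off the
smoothed coastline (the real banks are offshore features and the smoothed
polyline cuts corners); the Finnmark grounds (13–15) are nearshore, where
those banks hug the coast.

**Egg stage.** Fixed 21-day duration. Each egg draws a neutral-buoyancy
salinity from N(31.25, 0.69) once at release. Vertical position follows a
buoyancy-drift random walk: terminal velocity is linear in (ambient −
neutral) salinity (default 4·10⁻⁴ m s⁻¹ per psu, capped at 2 mm s⁻¹ —
Stokes-scale values for 1.4-mm cod eggs), plus the standard correction for
spatially varying diffusivity (gradient drift, diffusivity evaluated at
the offset midpoint), with reflecting boundaries. With constant
diffusivity and constant upward velocity this scheme converges to the
exponential boundary-layer profile `p(z) ∝ exp(−wz/K)`, which is the
analytic oracle in the tests; the random-walk form was chosen over the
analytic steady state because it handles arbitrary stratification.

**Larval stage.** Larvae hatch at 4 mm / 0.06 mg dry weight and swim
toward a preferred isolume: light decays exponentially (0.12 m⁻¹) and the
preferred level (0.09 of surface light) puts the target near 20 m. Surface
light is held constant — polar day at 70° N in the drift season — so no
diel cycle is modelled; the cited behavioural parameters live in a
reference we do not reproduce, and these defaults are stated placeholders.
Swimming is capped at one body length per second and is deterministic
(behaviour dominates turbulence at larval sizes in this scheme).

**Growth.** Dry weight grows by `exp(SGR/100 · dt)` with the published
cod-larva polynomial in temperature and log weight (the source text cites
the growth model without printing coefficients, so the canonical published
values are the configured default); the rate is floored at zero and
temperature clamped to 0–14 °C. The update is midpoint (RK2) in log
weight, which keeps a daily step and 24 hourly steps consistent to ~10⁻⁵.
Length scales as the fourth root of the weight gain (power-law
length–weight with exponent 4, anchored at hatch) and never decreases.
Food is unlimited and mortality absent, as in the workflow being
reproduced: counts are *potential* supply indices.

**Advection.** 4th-order Runge–Kutta on bilinear-in-space,
nearest-in-time velocities at the particle's depth; inner step 1 h by
default (6 h in the desk-scale scenarios — the currents are smooth at
those scales). Particles touching land are shelved as `beached`, particles
leaving the grid as `left_domain`; both remain in the bookkeeping so
active + beached + left_domain always equals the number released.

## 4. Accumulation around the colony

The foraging box is an axis-aligned 100-km square in a local equidistant
projection about the colony (70°23′ N, 31°10′ E) — the colony-to-edge
distance (50–71 km) brackets the documented guillemot foraging ranges.
Counting is by *state*: a larva present on k days contributes k daily
counts. Only active larvae count (eggs and beached particles do not).
`fraction_south` is the window-summed southern share over the 9 June –
7 July chick-rearing window and is undefined (NA with a warning), not
silently zero, when the box is empty. `arrival_curves` provides per-year
cumulative arrivals with upper/lower-quartile flagging by an external
body-size series (4 + 4 years at n = 16). Daily counts stand in for
densities: the box area is constant, so they are proportional.

## 5. Statistical linkage

The linkage stage mirrors a two-stage screen-then-refit workflow:

* **Trends.** Each yearly series is OLS-tested for a linear trend;
  series with p < 0.05 are replaced by their regression residuals
  (population size is deliberately passed through untransformed — its
  near-perfect linear growth makes residuals meaningless).
* **Diet fractions** enter as arcsin(√p). The plain `asin(p)` variant is
  available (`sqrt = FALSE`) because the transform's square root is
  conventionally implied rather than stated; √ is the default.
* **Backward AICc selection** removes, at each step, the covariate whose
  removal most reduces the small-sample corrected AIC
  (`AIC + 2k(k+1)/(n−k−1)`, k counting coefficients plus the error
  variance — essential at n = 16) and stops when no removal helps,
  recording a ledger of step, removed covariate, parameter count, AICc,
  adjusted R² and the removal p-value. Rank-deficient designs error with
  the offending covariates named.
* **AR(2)-error regression** refits the selected relationship by maximum
  likelihood (`stats::arima` with a regression term). With order 0 it
  reduces exactly to OLS. Explained variance is the squared correlation
  between one-step fitted values and observations (a
  predicted-vs-observed reading). An ARCH Lagrange-multiplier screen at
  lags 1–2 is reported but never gates anything.

The synthetic colony generator is the statistical twin of these
assumptions: wing length = intercept + trend·t + β·covariate + AR(2)
noise; diet fractions follow a Dirichlet scheme whose herring weight rises
and capelin weight falls with the inflow index (the documented signs;
magnitudes are free parameters); stationarity of the AR polynomial is
enforced at construction. Monte-Carlo tests confirm β recovery within 2 SE
in ≥ 90% of replicates at n = 500 and retention of a single strong
covariate among 7 noise covariates in ≥ 80% of replicates at n = 16.

## 6. The coupled experiment

`coupled_fraction_south` runs one season end-to-end at a given
Atlantic-jet multiplier. The designed mechanism: southern offshore banks
(Lofoten/Helgeland, 600–1400 km upstream) sit on the inshore flank of the
Atlantic jet, so their larvae's northward progress scales with the
multiplier — in weak years they are still en route when the chick-rearing
window closes, in strong years they arrive in time; the nearshore southern
grounds and the northern Finnmark grounds ride the multiplier-independent
coastal jet and provide a steady baseline (northern arrivals, being close,
partly overshoot *earlier* in strong years). The fraction-from-south is
therefore monotone non-decreasing in the multiplier — the acceptance
property — and rises smoothly (≈ 0.36 → 0.78 over multipliers 0.6 → 1.4
at the default seed). Southern-origin larvae in the box are systematically
older and longer than northern-origin ones (≈ 100 d / 21 mm vs 68 d /
13 mm), since they grow en route for weeks longer: this is the emergent
size-quality contrast, tested as an ordering, never as a numeric target.

## Numerical and degenerate-input choices

* Axes are strictly monotone; time steps exactly one day; interpolation
  clamps at grid boundaries.
* Zero-amplitude jets produce an exactly still ocean; zero velocities
  leave particles exactly in place.
* A constant series has trend slope 0 with p = 1 by convention; detrending
  is idempotent and exactly mean-zero.
* All generators are deterministic under a fixed seed; pipeline stages
  derive their seeds as `10·seed + offset` so stages are independently
  reproducible.
* Desk-scale defaults (15-km grid, 150 eggs/event, 6-h step) keep a
  five-level multiplier scan under a minute per level; they are stated
  stand-ins for the emulated 4-km/94 500-egg/1-h configuration, and the
  physics and bookkeeping are identical at both scales.

## Known limitations

The coastline is a smoothed polyline (no Vestfjorden interior, no
islands); larvae cannot re-suspend after beaching; there is no horizontal
diffusion, so plume arrivals are sharper than in eddy-rich reality; growth
is food-unlimited and mortality-free, so accumulation counts are supply
indices rather than abundances; the transport diagnostic reports the
synthetic jets, not the observed ~1.8 Sv AW / 0.9 Sv CW climatology, which
would require the original ocean archive.
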