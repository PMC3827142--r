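# larvadrift

Climate-driven bottom-up forcing of seabird breeding success, as a testable
simulation pipeline. In the southern Barents Sea, common guillemot
(*Uria aalge*) chicks grow better in years when more — and larger — cod
(*Gadus morhua*) larvae drift into the waters around the colony. The supply
of those larvae is set upstream: eggs spawned on banks along the Norwegian
coast ride the Norwegian Coastal Current and the Norwegian Atlantic Current
north, and the strength of the warm Atlantic inflow through the western
entrance of the Barents Sea decides how much of the southern spawning
production arrives during the chick-rearing weeks.

`larvadrift` implements that chain end to end on synthetic ocean fields, so
every stage is testable without any external archive:

1. **Synthetic ocean** (`generate_ocean_fields`) — daily temperature,
   salinity, currents and vertical diffusivity on a regular lon/lat/depth
   grid: a fresh nearshore coastal jet and a warm, salty offshore Atlantic
   jet along a smoothed Norwegian coastline, with a winter-peaked seasonal
   cycle and per-year Atlantic multipliers. Velocities derive from a
   streamfunction, so jet transport matches the closed form
   `core_speed x width x depth` and supports exact oracle tests.
2. **Water-mass transport** (`section_transport`) — volume transport
   through a hydrographic section (the Fugløya–Bjørnøya analogue),
   classified as Atlantic Water (T > 3 °C and S > 34.9), Coastal Water
   (S < 34.9 south of 72°30′ N) or other, in Sverdrup (1 Sv = 10⁶ m³ s⁻¹),
   with June–July (chick-rearing season) means via `period_mean`.
3. **Egg/larva drift IBM** (`run_ibm`) — 4500 eggs released every third day
   through March–April (94 500 in total) at 15 spawning grounds; each egg
   carries a neutral-buoyancy salinity drawn from N(31.25, 0.69) and is
   positioned vertically by buoyancy plus a turbulent random walk; after a
   fixed three-week egg stage, larvae swim toward a preferred isolume and
   grow by a temperature- and size-dependent specific growth rate
   (SGR% = 1.08 + 1.79 T − 0.074 T ln w − 0.0965 T (ln w)² + 0.0112 T (ln w)³,
   w = dry weight in mg); horizontal drift is 4th-order Runge–Kutta through
   the daily currents; daily state recording; no mortality.
4. **Foraging-box accumulation** (`daily_accumulation`, `fraction_south`) —
   daily counts of larvae inside a 100 × 100 km box around the colony
   (70°23′ N, 31°10′ E), split by origin (grounds 1–12 = southern of the
   section, 13–15 = northern), summarised over the 9 June – 7 July
   chick-rearing window.
5. **Statistical linkage** (`backward_aicc_select`, `ar_error_fit`) — trend
   tests and detrending, arcsin(√p) diet transforms, GLMSELECT-style
   backward elimination on small-sample corrected AIC, and a final
   regression with AR(2) errors of chick wing length on southern larval
   density.

`run_pipeline` chains all five stages with per-stage seeds derived from one
global seed and writes CSVs plus a checksummed manifest.

## Worked example

A 12-year desk-scale run (15 km grid, 150 eggs per release event, 6 h inner
step):

```r
library(larvadrift)
res <- run_pipeline(pipeline_config(years = 1996:2007, seed = 1))
print(res$per_year, digits = 3)
```

```
   year jet_multiplier aw_jj_sv cw_jj_sv fraction_south south_density
1  1996          0.863    1.083    0.150          0.514          3664
2  1997          1.007    1.239    0.162          0.634          4830
3  1998          0.684    0.897    0.136          0.423          2724
...
7  2002          1.392    1.648    0.194          0.766          6662
```

Each row is one simulated year: the Atlantic-jet multiplier drawn for that
year, the June–July mean AW and CW inflow through the entrance section (Sv),
and the fraction and window-summed count of southern-origin larvae in the
foraging box. Stronger Atlantic years deliver more southern larvae
(`pairwise_r2(res$per_year$aw_jj_sv, res$per_year$fraction_south)` gives
R² = 0.98 here — the synthetic world is much cleaner than nature).

```r
print(res$selection)
#> Backward AICc selection
#>  step         removed np     aicc    adj_r2 removal_p
#>     0    (full model)  7 86.53035 0.9332156        NA
#>     1    capelin_diet  6 64.90474 0.9425826 0.7070111
#>     2    herring_diet  5 56.01434 0.9295199 0.1584945
#>     3 population_size  4 50.19712 0.9209275 0.2026827
#>     4    sandeel_diet  3 45.80146 0.9177235 0.2763595
#> Selected: aw_inflow, cod_larvae

print(res$ar_fit)
#> AR(2)-error regression (n = 12)
#>   beta = 3.012 +/- 0.2649 (SE)
#>   explained variance = 0.924
```

The backstep ledger removes the noise covariates and keeps the southern
cod-larvae density — the variable that actually generated the synthetic
wing lengths (true β = 3; the AR(2) refit recovers 3.01 ± 0.26).

In the drifting population itself, southern-origin larvae reaching the box
are older and longer than northern-origin ones (about 100 d / 21 mm vs
68 d / 13 mm in the default scenario) because they have been growing en
route for weeks longer — the size-quality contrast that makes the southern
supply matter to the birds.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline from scratch at the given seed (4 synthetic years:
ocean generation, transport diagnostic, drift IBM, accumulation, linkage
inputs) and writes the results JSON.
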