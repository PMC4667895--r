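# onager

Space-use analysis of hourly GPS telemetry for large herbivores in
heterogeneous (typically arid) landscapes: displacement rhythms, habitat
selection, water-point visits, and recursion movements, with a synthetic
landscape-and-trajectory generator so the whole pipeline runs and is
testable without field data.

The package grew out of the analysis style used for GPS-collared desert
equids: five animals relocated every hour over 50-day seasonal windows,
moving between high ground by day and vegetated streambeds (thalwegs) by
night, with near-daily visits to a handful of permanent water points in
summer.

## What it computes

**Displacement.** Distances between successive hourly locations, binned
by hour of day (`hourly_mean_distance()`); cross-animal summaries use the
mean ± SE of the individual means (`period_mean_distance()`); Spearman
rank correlation between behavioural-scan activity and hourly distance
(`activity_distance_correlation()`).

**Home ranges.** A simplified movement-based kernel utilization
distribution (`movement_kernel_ud()`): steps of duration ≤ T_max and
length ≥ L_min are densified every τ hours and an isotropic Gaussian
kernel of bandwidth h_min is placed at every observed and interpolated
point (defaults T_max = 2.5 h, τ = 0.1 h, L_min = 50 m, h_min = 100 m).
The x% home range is the smallest cell set holding x% of the mass
(`isopleth_mask()`).

**Habitat selection.** Five raster variables — thalweg (25-m stream
buffer), NDVI, elevation, slope, and northern exposure
E_N = sin θ · cos α (θ slope, α aspect clockwise from north; −1 for a
south-facing vertical slope, +1 north-facing) — sampled at the animal's
in-range locations per hour of day (use) and at the nodes of a 30-m
lattice over the range (availability), contrasted by the selection
coefficient

    SC = (location mean − node mean) / node SD.

**Water visits.** Passing series (runs of ≥3 consecutive locations whose
interior lies within 50 m of a water point) give the local mean hourly
travel distance; the visit radius is half that mean rounded up to the
nearest 10 m (879 m → 440 m, 408 m → 210 m, 1633 m → 820 m); any maximal
run of locations inside the radius is one visit, timed at the closest
location.

**Recursion.** For every location, a 200-m focal circle yields the
residence time (consecutive hours inside), recursion time (hours away
before the next return; right-censored at the window end) and number of
visits (`recursion_table()`). Median recursion times come from
Kaplan-Meier curves (`km_curve()`). 24-h periodicity is tested by fitting
Poisson GLMs to the duration counts, log λ = a₀ + a₁t + a₂log t plus a
cosine (or log-cosine) term of 24-h period with integer phase k scanned
over 0-23, ranked by AIC (`fit_poisson_periodicity()`); with a₃ > 0 the
best-k model peaks every 24 − k hours. The mean number of visits per
location ñ is modelled against home-range size A by eight Gaussian
random-intercept models (including the offset models log ñ = a₀ − log A
encoding strict inverse proportionality), ranked by AICc
(`fit_visits_vs_hr()`).

**Recursion sites.** The 20% most-visited locations per animal-season,
clustered wherever 200-m circles overlap (≥15 locations), characterized
by habitat means/SDs and diel histograms (`main_recursion_sites()`).

## Worked example

```r
library(onager)
cfg  <- sim_config("summer", seed = 1, n_individuals = 1)
land <- generate_landscape(cfg)
tr   <- simulate_trajectory(cfg, land, "594")

ud <- movement_kernel_ud(tr, ud_params(), land$elevation)
isopleth_mask(ud, 0.95)
#> <home_range> 95% isopleth: 13.20 km2 (14667 cells @ 30 m)
isopleth_mask(ud, 0.50)
#> <home_range> 50% isopleth: 2.33 km2 (2587 cells @ 30 m)

rt <- recursion_table(tr)
attr(rt, "mean_visits")            # ñ, mean visits per location
#> [1] 14.6
km_curve(rt$recursion_h, rt$censored)
#> <km_curve> 372 event times; median 88 h
fit_poisson_periodicity(recursion_durations(rt))
#> <periodicity_scan> 51 fitted models
#>   best: M5 (k = 3)  AIC = 816.1  (df 4)
```

The simulated animal concentrates half its use in 2.3 of its 13.2 km²
range; recursion times have a Kaplan-Meier median of 88 h, and the AIC
scan selects a periodic model with k = 3 — intensity peaks every
24 − 3 = 21 h, the signature of returning to the same places at the same
time of day (here driven by the dusk water-visit schedule of the
generator). The diel selection contrast shows the built-in habitat
switching: at 12:00 the elevation SC is +2.59 with NDVI/thalweg near
zero, while at 00:00 thalweg and NDVI SCs are +7.06 and +6.25.

The full pipeline — both seasons, all stages, CSV/GeoJSON/ASCII-grid
artifacts plus a manifest — is one call:

```r
b <- run_pipeline(run_config("synthetic", out_dir = "run1", seed = 1))
summarize_run(b)
```

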