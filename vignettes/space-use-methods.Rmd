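---
title: "Methods: displacement, habitat selection and recursion analysis of hourly GPS telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: displacement, habitat selection and recursion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(onager)
```

This vignette is the package's own account of the science it implements:
the models and procedures, the assumptions they rest on, the parameters
that matter, what the synthetic generator does and does not emulate, and
the numerical and design choices made where the methodology was open.

## The setting and the data model

The package targets hourly GPS relocation series of large free-ranging
herbivores, analysed within bounded seasonal windows (50 days by
default). All coordinates are planar metres in one projected CRS: every
statistic downstream is a Euclidean distance, an area, or a raster
lookup, so geographic (lon/lat) input is rejected at ingest rather than
silently mangled. Collar schedules drift by seconds to minutes, so a
cadence tolerance of ±5 minutes around the hour is applied when clock
hours are assigned; fixes missing from the nominal schedule are recorded
as gaps and never interpolated at the trajectory level — each analysis
decides its own gap semantics (below).

## Displacement

Step lengths between successive fixes are assigned to the clock hour of
the step's *start* fix (the end-fix convention is available via
`bin_by`), and steps that span a recorded gap are flagged and excluded
from the hourly means — a 2-h step is not an hourly displacement.
Cross-animal summaries are always two-stage (mean ± SE of the individual
means), never pooled steps, so animals with more complete records do not
dominate. Within an animal, the period mean over a set of hours weights
each hour bin by its step count, which makes the recombination over all
24 bins equal the animal's overall mean step length exactly.

## Home ranges: a simplified movement-based kernel

Classical kernel home ranges ignore the serial correlation of hourly
fixes. The estimator here carries that correlation by smoothing along
steps: every step with duration ≤ `T_max` and length ≥ `L_min` is
densified by linear interpolation every `tau` hours, and an isotropic
Gaussian kernel of bandwidth `h_min` is centred at every observed *and*
interpolated point; the summed surface is normalized to integrate to 1
over the grid. Defaults are `T_max` = 2.5 h, `tau` = 0.1 h, `L_min` =
50 m, `h_min` = 100 m. `T_max` acts as a bridging cutoff: a step longer
than 2.5 h is a data gap, and interpolating across it would invent
movement, so such steps contribute endpoint kernels only, as do steps
shorter than `L_min` (sub-noise movement). The time-dependent bandwidth
of the full movement-based estimator (its diffusion parameter `b`) is
deliberately **not** reproduced; `b` is retained in `ud_params()` for
provenance but unused. This is a documented simplification, not an
approximation claim: fixed-bandwidth along-path smoothing captures the
step-correlation structure that motivates movement-based kernels, while
keeping the estimator a closed-form Gaussian sum that tests can verify
against direct evaluation.

The x% home range is built greedily: cells are added in descending
density order (ties broken in row-major order, for determinism) until
the summed probability reaches the level. A threshold-sweep oracle in
the tests confirms the greedy set is the minimal one.

## Habitat selection

Five raster variables describe the landscape: thalweg membership (1
inside a 25-m buffer of the drainage network), NDVI, elevation (m),
slope (degrees), and northern exposure

$$E_N = \sin\theta \cos\alpha,$$

the projection of the terrain unit normal on the south-north axis
(θ slope, α aspect clockwise from north; −1 south-facing vertical, +1
north-facing vertical, 0 flat). Slope and aspect come from Horn's 3×3
finite differences, the standard DEM convention; flat cells get aspect 0
plus an explicit flag so E_N is 0 there by construction rather than by
accident of atan2.

Use is the set of habitat values at the animal's fixes inside its 95%
range, grouped by hour of day; availability is the habitat at the nodes
of a 30-m square lattice anchored at the minimum corner of the mask's
bounding box (the anchor matters slightly and is therefore fixed and
documented). The selection coefficient per variable × hour is the
standardized contrast `(mean use − mean availability) / SD availability`
with the sample (n−1) SD — the denominator convention is configurable
since field descriptions often omit it. A zero availability SD (e.g. a
uniform variable over the range) makes SC *undefined*: it propagates as
`NA`, never as 0, and cross-animal averages skip it with a count. All
in-range fixes of an hour are pooled across the window; hours with no
in-range fixes yield an undefined record rather than being dropped, so
the 5 × 24 profile shape is stable.

## Water-point visits

Visit detection needs a radius that scales with how fast animals move
near the point. The passing-series construction estimates that: every
series of ≥3 consecutive locations whose interior (all but the first and
last) lies within 50 m of the point contributes its steps, and the
pooled mean step length is the local mean hourly travel distance. The
visit radius is **half that mean, rounded up to the nearest 10 m** —
the only rounding rule consistent with all three published
mean-to-radius pairs (879→440, 408→210, 1633→820); it is inferred, so it
is overridable per point. Any maximal run of locations within the radius
(closed boundary, for determinism at exact distances) is one visit,
timed at the run's closest location (earliest on ties). A cadence gap
inside a run does not split the visit when both flanking fixes are
in-radius — the animal plausibly stayed — with a strict mode available.

## Residence, recursion and periodicity

For each location, a 200-m focal circle (chosen in relation to median
and mean hourly displacement of the study system) is evaluated against
every fix of the window: residence time is the span of the maximal
in-circle run containing the focal fix; recursion time is the number of
hours beyond the radius between that run's end and the next in-circle
fix, right-censored at the window end; the number of visits is the count
of in-circle runs. An unobserved hour flanked by in-circle fixes does
not break a run (mirroring the visit rule); flanked by out-of-circle
fixes it counts as time away. Each focal fix contributes *one* recursion
duration — the first return after its run ("before returning", in the
singular); the pooled histogram of all inter-visit gaps is available as
an option, but model fitting uses the per-focal first recursions of all
fixes and animals of the season, uncensored only. Censored durations
enter only the Kaplan-Meier analysis, where the median is the smallest
time with survival ≤ 0.5 (undefined when the curve never reaches it).
The Kaplan-Meier computation itself is delegated to the survival
package's product-limit estimator, with a hand-computed oracle in the
tests.

Periodicity is a model-selection question: do recursion-time counts
oscillate with a 24-h period? Counts per integer hour t over 1–168 h
(7 days, the display range; configurable, zero bins included) are fitted
by Poisson GLMs with log link:

* M1: log λ = a₀ + a₁ t
* M2: log λ = a₀ + a₁ log t
* M3: log λ = a₀ + a₁ t + a₂ log t
* M4-k: M3 + a₃ cos(2π(t+k)/24)
* M5-k: M3 + a₃ log(cos(2π(t+k)/24) + 2)

with k scanned over the integers 0–23 and models ranked by
AIC = 2·df − 2·logL (df = 2, 2, 3, 4, 4). Two numerical points matter.
First, the cosine model is exactly invariant under
(k, a₃) → (k+12, −a₃), so the raw scan would report two
indistinguishable phases; M4 fits are canonicalized to a₃ ≥ 0 before
ranking, making the reported phase unique and placing the intensity
maxima at t ≡ (24−k) mod 24 — "peaks every 24 minus k hours". The
log-cosine variant is not sign-symmetric and needs no canonicalization.
Second, AIC ties (within 10⁻⁶, which is where the k/k+12 duplicates
land) break toward fewer parameters, then smaller k, so the ranking is
deterministic. Non-converged fits are excluded from ranking with a
warning rather than silently kept.

## Visit rate versus home-range size

If locations were spread uniformly over a range of size A, the mean
number of visits per location ñ would scale as 1/A — a log-log slope of
exactly −1. The eight-model family formalizes departures from that
premise: season-specific intercepts and/or slopes, free slopes versus
the −1 offset, with the individual as a random intercept (each animal
contributes one row per season, so rows are paired). Fitting is direct
maximum likelihood over (fixed coefficients, intercept variance,
residual variance): the fixed part is profiled out by GLS and the two
log-variances optimized by L-BFGS-B, with variances floored at 10⁻⁸ so
degenerate (noise-free) constructions still return a finite fit instead
of a convergence failure. With n = 10 animal-season rows, the
small-sample correction matters; models are ranked by
AICc = AIC + 2p(p+1)/(n−p−1) with p the full parameter count including
both variances (6, 5, 5, 4, 4, 4, 3, 3 for R1–R8). The tests cross-check
the likelihoods against nlme's mixed-model fitter on well-conditioned
data; the in-package optimizer is the implementation because it is
robust exactly where small-sample model families need it to be.

## Main recursion sites

Per animal-season, the top 20% of locations by visit count are selected
(ties at the cutoff included — deterministic and slightly conservative),
and any connected cluster of ≥15 locations whose 200-m circles overlap
(centre distance ≤ 400 m, tangency counts) is a main recursion site.
Sites shared by several animals are recovered by a second clustering
pass over the union of all animals' selected locations with the same
rule — single-animal components of that pass reproduce the per-animal
sites, multi-animal components are flagged common. The
alternative (spatially intersecting per-animal sites) is a
straightforward variation but the union pass is the one implemented and
tested. Each site is characterized by habitat means and SDs over its
member locations (thalweg as a proportion), a 24-bin diel histogram, and
flags marking variables whose site mean exceeds the animal's 95%-range
mean.

## The synthetic generator: what it emulates, and what it does not

`generate_landscape()` builds the study system's structure on one shared
30-m grid (field data often mix 25-m DEMs with 30-m NDVI; one grid
avoids resampling semantics): a smoothed Gaussian elevation field scaled
to the 470–1037 m relief of a rocky desert highland, drainage lines
traced by steepest descent, the thalweg mask as their 25-m buffer, NDVI
around 0.10 with a configured elevation inside thalwegs (sparse dryland
vegetation concentrated along streambeds; contrast higher in the summer
configuration), and 1–3 water points on the network.

`simulate_trajectory()` is a biased correlated random walk at hourly
cadence. Candidate steps (24 headings drawn around the previous heading
with wrapped-normal turns, gamma step lengths with mean 400 m) are
scored by hour-specific weights on standardized elevation, NDVI, thalweg
and a quadratic territory pull, and one is chosen by softmax — a bounded
runtime alternative to continuous rejection sampling. The default
schedule attracts to high elevation from 08:00 to 16:00 and to
NDVI/thalweg from 20:00 to 04:00, reproducing the diel habitat
switching the selection analysis is meant to detect. On water days
(Bernoulli per day; probability 1 in summer, 0.1 in winter, matching
near-daily summer drinking and rare winter visits), the walk is steered
to the nearest water point during 19:00–23:00 (the dusk visit peak)
until within 50 m, and holds position for the hour once there. All
randomness flows from one base seed through named substreams (landscape,
per-animal walk, water days), so stages are independently reproducible.

The generator deliberately does **not** emulate GPS positional error or
failed fixes, behavioural states beyond the diel schedule, social
interaction or explicit territoriality (the territory pull is a
soft spatial prior, not an interaction model), energetics, or seasonal
vegetation dynamics within a window. Passing tests therefore demonstrate
that the *analyses* recover the structure the generator encodes — diel
selection signs, near-daily water visits, 24-h recursion periodicity,
ñ ∝ 1/A under uniform use — not that real telemetry is this clean; on
field data, gap handling and GPS error will matter more than they do
here.

A note on emergent behaviour: with the default summer configuration the
periodicity scan typically selects a periodic model with k ≈ 3 (maxima
every ~21 h), although the generator never encodes recursion times —
the phase emerges from the dusk water-steering window, which is the
mechanism the analysis was designed to reveal.

## Problem sizes and numerical tolerances

Defaults reflect the emulated study: 5 individuals, 50-day windows,
hourly cadence, 150×150 cells at 30 m. The test suite exercises reduced
sizes chosen for coverage rather than realism — oracle-equivalence
trajectories of 80–260 fixes (the brute-force rescan is quadratic),
two-animal 10-day pipelines for byte-level determinism, 60×60 landscape
grids for generator properties — while the statistical acceptance
checks (phase recovery at n = 5000 durations, diel selection signs over
10 full 50-day simulations) run at the study scale stated above. UD
normalization is asserted to 10⁻⁶ of unit mass; kernel evaluation is
truncated at 4 bandwidths (relative error < 10⁻¹³ against the untruncated
closed form in the tests); GLM convergence uses a deviance tolerance of
10⁻¹⁰; Poisson AIC ties are grouped at 10⁻⁶.

## Known limitations

* The home-range estimator is a fixed-bandwidth simplification; absolute
  areas differ from time-dependent-bandwidth estimators, so comparisons
  should stay within one estimator.
* Availability lattices anchored differently shift SC values slightly;
  the anchor is fixed (mask bounding-box minimum corner) but real
  analyses comparing packages should align anchors.
* Linear mixed-effect hypothesis tests on SC and displacement profiles
  (hour/season effects) are out of scope; profiles and records are
  exported as tidy CSV for external inference.
* The visit-radius rounding rule is inferred from three published pairs;
  it is exact for them but should be overridden when a study defines its
  own radius.
* Discovering *unknown* attraction points from trajectory convergence is
  not implemented; water points must be supplied (or simulated).
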