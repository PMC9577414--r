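---
title: "Simulating seed dispersal by migratory herbivores: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating seed dispersal by migratory herbivores: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedrain)
```

seedrain predicts where a migratory herbivore population deposits the seeds
it ingests, by chaining four models that can each be calibrated from field
data: seasonal ranges from telemetry, migratory connectivity by optimal
transport, individual trajectories by an empirical random trajectory
generator (eRTG), and a daily foraging/gut-retention/excretion process.
This vignette explains each model, its assumptions and tunable parameters,
the numerical choices behind the implementation, and what the synthetic
island used for testing does and does not demonstrate.

## Spatial foundation

All computation happens in a local tangent-plane (equirectangular)
projection in metres, anchored at a configurable lon/lat origin. At island
scale (tens of km) the scale distortion of this projection is far below the
GPS error of tracking collars, which is why no full cartographic projection
library is required. Space is discretized into flat-topped hexagons of
equal area (default 1.18 km²), the cell size at which seasonal presence /
absence, energy supply, propagule sources, and seed deposition are
bookkept. Points map to cells by axial-coordinate cube rounding, which is
exact for hexagonal Voronoi assignment.

## Seasonal ranges

Each individual's seasonal utilization distribution (UD) is a bivariate
normal kernel density estimate of its fixes; the seasonal range of the
population is the convex hull around the per-individual 95% isopleths,
converted to cells by centroid-in-hull membership.

* **Isopleth level** (default 0.95): the conventional home-range isopleth.
  The isopleth polygon is the level set enclosing the requested fraction of
  estimated density mass, found by sorting grid densities. For an isopleth
  of 1 the level set degenerates to the whole evaluation window; the
  implementation returns the (data-padded) window rectangle in that case.
* **Bandwidth**: the normal-reference ("plug-in ad hoc") bandwidth per
  axis. No bandwidth was stated for the original analysis; the reference
  rule is the standard default and its oversmoothing bias at n ≈ 30–2000
  fixes inflates the 95% area by well under the 15% tolerance our tests
  allow against the analytic Gaussian ellipse.
* **Fewer than 30 fixes** make a kernel estimate unreliable; the function
  warns and falls back to the convex hull of the fixes. Identical fixes are
  a degenerate kernel and an error.
* **Pooling**: all individuals' UDs are pooled per season into one
  population hull. Whether the original construction pooled per
  individual-year instead is not documented; pooling per season is the
  simpler reading and the one implemented.

Interactive migration segmentation (clicking on net-squared-displacement
plots) is inherently irreproducible, so the package accepts pre-segmented
tracks and offers `flag_migration_windows()`, which flags runs of at least
`min_days` consecutive NSD increases whose cumulative rise exceeds a
threshold (default 1 km² of displacement), as a reproducible helper.

## Migratory connectivity as optimal transport

Energy available to the population in each seasonal range is taken
proportional to max(NDVI, 0) × cell area (on an equal-area grid this equals
mean NDVI up to a constant) and rescaled so each side sums to the
population size (default 1000). Rescaling *both* sides makes the grand
total of the optimal flow exactly the configured population, so constraint
(4) of the transportation problem doubles as the population count. The
relocation cost between sites is the planar centroid distance in km —
distance is the natural proxy for the energetic cost of moving, and no
distance threshold is applied.

The solver is an exact successive-shortest-augmenting-path algorithm with
node potentials (the classic min-cost-flow construction): Dijkstra on
reduced costs over the bipartite residual graph, potential updates that
keep reduced costs non-negative, and augmentation by the bottleneck
residual. Problem sizes here (tens to hundreds of sites per side) are
trivial for an exact method, so no approximate or thresholded variant is
used; the test suite certifies optimality against an independent LP solver
on 200 random instances and checks the no-improving-2-swap property on
island-sized instances.

Fractional optimal flows become whole migrants by largest-remainder
rounding (deterministic, each count within 1 of its flow, total exact); a
multinomial alternative is available behind a flag for users who prefer
integerization noise over determinism.

## The trajectory generator

The eRTG simulates a migrant's path between its assigned origin and
destination in a fixed number of daily steps while preserving the movement
geometry of a randomly chosen empirical template track. From each
daily-thinned template we estimate: step-length bins (Freedman–Diaconis
width), 36 fixed turning-angle bins on (−π, π], lag-1 conditional
transition matrices for both, and the step–turn joint distribution
expressed as a lightly smoothed likelihood-ratio lift over independence.
Fixed angular bins keep the circular topology simple; FD binning adapts to
the template's step-length scale.

Candidate (step, turn) pairs at each simulation step are drawn from the
lag-1 conditionals and weighted by the product of the step–turn lift and a
feasibility *pull*: the probability density that the remaining steps can
cover the remaining distance, read from pre-simulated unconstrained walks
of the same kernel (500 walks, tabulated mean and sd of the k-step
displacement, computed under a seed derived from the template id so kernel
fitting stays deterministic). Three numerical choices matter:

* **Schedule tracking.** The pull uses one tenth of the unconstrained
  displacement sd (floored at half the median step). A wide pull lets
  random heading diffusion accumulate kilometre-scale deficits that no
  late correction can recover (the closing speed is bounded by one step
  per day); tracking the displacement schedule tightly corrects deviations
  while they are still small, which simultaneously guarantees convergence
  over long routes *and* avoids the step-length distortion of desperate
  final corrections. The trade-off was measured: tight tracking improved
  both convergence (30/30 vs 24/30 at 17 km) and step-distribution
  fidelity (KS D 0.07 vs 0.12).
* **The final two steps.** With one step left, the pull switches to the
  empirical step-length density at the remaining distance, so the last
  step stays inside the kernel support (this is also what lets closed
  loops end where they began, provided the template's turning support
  includes reversals). The very last step is chosen among candidates
  landing within the convergence tolerance ε, or the attempt fails.
* **Step count.** The number of daily steps is the smallest horizon whose
  unconstrained displacement schedule matches the origin–destination
  distance, bounded above by distance divided by the template's own net
  daily progress. The bound matters: resampled unconstrained walks are
  diffusive in the long run, so for short templates the schedule alone
  badly overestimates the duration of what is empirically a directed
  migration, producing weeks of spurious wandering; the template's
  realized progress rate is the honest duration scale for directed legs.

Convergence means the pre-snap endpoint lies within ε = half the template's
median daily displacement of the destination; the endpoint is then snapped
exactly. No tolerance is documented for the original implementation; half a
median step makes the snap smaller than a typical day's movement.
Non-converging runs (30 restarts per template) signal the caller, which
redraws a template uniformly at random, as the reference procedure
describes, up to a global cap of 100 draws per individual. Coastlines and
other barriers are *not* enforced during simulation; off-grid stops are
skipped with a warning during the dispersal stage instead.

Per-individual RNG substreams (derived from one base draw) make population
runs reproducible and order-independent.

## Foraging, gut retention, excretion

Gut retention time is modeled as a right-skewed normal — the two-piece
(Fernandez–Steel) construction with skewness ξ, standardized so the stated
mean (12 d) and sd are the distribution's actual moments. The daily
excretion weight R_d is this density *evaluated at integer d* (not
integrated over the day), truncated to zero beyond d_max = 28 d. Two
published parameter statements conflict (sd 4 in one section, sd 8 in
another); sd 8 is adopted because only it reproduces the published worked
value R₅ = 0.05378286 under this parameterization — the package's unit
tests pin that value to 10⁻⁶.

Daily excretion probability is the history-weighted fraction
P_g = Σ R_d F_d / Σ R_d over the last 28 days. Consequences of this
formula, all tested: P_g is 0 for an empty history, 1 for a saturated one,
and strictly monotone in every feeding flag; excretion does *not* deplete
the history (the formula conditions on feeding only), so a single feeding
produces an excretion-day distribution proportional to R_d with its mode at
day 5. Histories are initialized Bernoulli(0.21) per day — the source
plant's coverage fraction of the highland range. Seed counts per event are
truncated-normal (mean 1443, sd 2057), sampled by inverse CDF, rounded, and
floored at 1; the truncation bound and rounding convention are
implementation choices (no bound was documented).

With multiple stops per day (1, 2 or 4, by interpolating the day's
displacement), the day index still advances once per day: feeding at any
stop sets that day's flag, and each stop gets an independent excretion
draw. After arrival, individuals remain at the destination for
`settle_days` (default d_max = 28) under the same daily rules, so seeds
ingested late in the migration remain depositable; setting it to 0
reproduces a strict migration-only reading, since the original text does
not say whether simulation continued after arrival.

## Validation statistics

`ks_compare()` evaluates both empirical CDFs at every pooled jump point
(exact, verified to 10⁻¹² against an exhaustive double-loop oracle and
against the standard library implementation) and reports the asymptotic
two-sample p-value from the Kolmogorov distribution, using the
Jacobi-theta series form for small λ where the alternating series loses
accuracy. Exact small-sample p-values are deliberately not implemented:
the published comparisons are consistent with asymptotics on pooled
samples. Deposition summaries (landcover, park/agricultural zone,
elevation histograms per repeat) are plain tallies, cross-checked in tests
by independent recounts.

## The synthetic island

`generate_island()` builds the entire study system so the pipeline is
testable offline. Its structure, chosen once and then frozen:

* **Relief**: a concave shield-volcano profile, elevation =
  peak·(1 − r/R)^1.3 (+5 m noise), peak 860 m over a 24 km domain — steep
  near the summit, a long gentle coastal apron, so elevation decreases
  monotonically in expectation from the centre. NDVI decreases linearly
  with elevation plus noise (greener lowlands).
* **Seasonal ranges**: the migratory population occupies the *southern
  flank* (real partially-migratory island populations occupy one flank,
  not a ring around the summit). The highland range is the convex-hull
  fill of the 250–450 m belt within a southern arc; the lowland range the
  hull fill of the 0–150 m coastal sector. Hull fills are used as the
  truth regions because the downstream range construction is also a convex
  hull — recovery is then a like-for-like comparison (Jaccard ≥ 0.8 at
  default settings, tested).
* **Source plants** cover 21% of the highland range, always confined to
  the elevation belt.
* **Tracks** (default 17): gamma daily steps (shape 5, scale 80 m — mean
  400 m/day, a realistic giant-tortoise migration pace), headings mixing
  the previous heading with the bearing to the target (weight 0.4) plus
  wrapped-normal noise (sd 0.5) — a downslope-biased correlated random
  walk with serially correlated headings. Migration legs are bracketed by
  35 highland and 32 lowland residency days of range-confined localized
  wander, which supply the ≥ 30 fixes a kernel UD needs. Residency sites
  are stratified by bearing (tagging spread across the range) and
  start–destination pairs closer than 5.5 km are re-paired, so every
  migration leg yields at least the 10 steps kernel fitting requires.
* **Dung piles**: one small dispersal simulation at the bundle's seed,
  subsampled to ~101 source-containing events plus ~121 excretion-free
  stops — a synthetic "observed" data set with realistic spatial
  structure for the validation stage.

Fixed seed implies byte-identical bundles; all generator parameters are
recorded in the bundle for parameter-recovery tests.

What passing tests on this island *do* show: every algorithmic contract
(optimality, conservation, pinning, distributional fidelity, monotonicity)
and the qualitative downslope-displacement signature — deposition density
unimodal with its mode below the source belt's lower edge, reaching
elevations the source plant never occupies. What they do *not* show:
agreement with any real landscape's numbers. Real NDVI seasonality,
coastline barriers, GPS error, and behavioral heterogeneity are all absent,
so quantities like the observed-vs-simulated KS statistic on the synthetic
island do not transfer to field data.

For mode-counting on the event-elevation density, the tests smooth at twice
the Silverman bandwidth: at the data-driven bandwidth, sampling noise
produces spurious shoulder maxima, and doubling the bandwidth is the usual
remedy when the question is modality rather than density estimation.

## Problem sizes and determinism

The shipped tests and the acceptance script run the pipeline at reduced
scale — population 200, 5 repeats for the stop-frequency and elevation
analyses; population 60–100 for pipeline smoke tests — sizes chosen so the
full suite completes in a couple of minutes while leaving every statistical
check well-powered (thousands of pooled events). The reference settings
(population 1000, 25 repeats, 1 stop/day) remain the defaults of
`pipeline_config()`. A master seed drives per-stage substreams
(synthetic-island generation, range estimation, per-repeat
trajectory+dispersal), so a fixed seed reproduces every artifact and the
manifest byte-for-byte, and the stop-frequency sensitivity analysis can
share trajectories and seeds across the 1/2/4-stop variants.

## Known limitations

* The eRTG's conditional sampling is a two-part approximation (lag-1
  kernels × feasibility pull), not an exact bridge of the unconstrained
  walk; its fidelity is certified distributionally (KS on pooled steps and
  turns), not path-wise.
* Energy is NDVI-proportional and static; no phenology, no competition
  beyond the transport constraints, no intra-seasonal movement.
* The establishment mask is a binary input; fitting the underlying species
  distribution model is out of scope.
* Trajectories ignore barriers; on landscapes with hard coastlines a
  masking step would be needed before the dispersal stage.
* The seed-count model treats every excretion event as independent of gut
  load history; seed number and excretion probability are uncoupled.
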