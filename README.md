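# seedrain

**seedrain** simulates how migratory herbivores move propagules across a
landscape. It was built for endozoochory on volcanic islands — giant
tortoises carrying invasive guava seeds downslope during their seasonal
migration — but every stage is generic: any system with GPS tracks, a
productivity surface, a propagule source map and a gut-retention curve fits.

The package is aimed at movement ecologists and invasion biologists who want
a *data-calibrated*, individual-based prediction of where seeds land ("seed
rain") and where they can establish ("seed fate"), together with the
statistics to validate that prediction against field records of dung piles.

## The model

The pipeline couples three components on an equal-area hexagonal grid
(~1.18 km² cells):

1. **Migratory connectivity (optimal transport).** Seasonal ranges are the
   convex hulls of per-individual 95% kernel utilization distributions,
   converted to presence/absence on the grid. NDVI within each range,
   rescaled so the population totals *N* migrants, gives the energy
   distributions *H* (highland) and *L* (lowland). The flow
   *f<sub>ij</sub>* ≥ 0 between sites minimizes total relocation cost
   Σ c<sub>ij</sub> f<sub>ij</sub> (c = centroid distance) subject to
   row sums ≤ k<sub>hi</sub>, column sums ≤ k<sub>lj</sub>, and grand total
   = min(Σ k<sub>hi</sub>, Σ k<sub>lj</sub>) — the Monge–Kantorovich
   transportation problem, solved exactly by successive shortest augmenting
   paths. Largest-remainder rounding turns the optimal flow into whole
   origin–destination assignments.

2. **Trajectories (empirical random trajectory generator).** For each
   migrant a template track is drawn at random from the empirical tracks;
   its daily step-length and turning-angle distributions, their lag-1
   transition structure and the step–turn joint distribution drive a
   conditional correlated random walk pinned to the assigned origin and
   destination with a fixed number of daily steps. A feasibility "pull",
   tabulated from unconstrained walks of the same kernel, keeps the
   remaining distance coverable; non-converging templates are redrawn.

3. **Foraging and gut retention.** Retention time follows a right-skewed
   (two-piece) normal with mean 12 d, sd 8 d, skewness 2, truncated at
   d<sub>max</sub> = 28 d; the daily excretion weight R<sub>d</sub> is the
   density at integer day *d* (R₅ = 0.05378286). Each day a migrant stops
   (1, 2 or 4 stops), eats if its cell holds the source plant, and excretes
   with probability

   P<sub>g</sub> = Σ<sub>d=1..dmax</sub> R<sub>d</sub>·F<sub>d</sub> / Σ<sub>d</sub> R<sub>d</sub>,

   where F<sub>d</sub> flags feeding *d* days before. Excreted seed counts
   come from a truncated normal (mean 1443, sd 2057, minimum 1). Events
   accumulate into per-cell seed rain; multiplying by a binary
   establishment-suitability mask gives seed fate. Two-sample
   Kolmogorov–Smirnov tests compare simulated and observed dung-pile
   elevations and the sensitivity to stop frequency.

A fully synthetic island generator (`generate_island()`) emulates the whole
study system — concave shield-volcano relief, NDVI gradient, a highland
source-plant belt, migration tracks with known movement parameters, and a
subsampled "observed" dung-pile set — so the complete pipeline runs and is
tested without any external data.

## Worked example

```r
library(seedrain)

gut <- retention_model()
gut
#> Gut-retention model: skew-normal(mean = 12 d, sd = 8 d, xi = 2), horizon 28 d
#>   R_1..R_28 sum to 0.9354; mode at day 5
retention_probability(gut, 5)
#> [1] 0.05378286

# excretion probability after a random 21%-feeding month
h <- init_history(0.21)
excretion_probability(gut, h)
#> [1] 0.2307

# end-to-end synthetic run: 100 migrants, 2 stochastic repeats
res <- run_pipeline(pipeline_config(population_size = 100, repeats = 2,
                                    rng_seed = 7L))
res$flow
#> Optimal transport flow: 54 routes, total flow 100.000, total cost 507.84
res$seed_rain
#> Seed rain: 1330546 seeds in 580 events over 81 occupied cells (2 repeats)
res$validation
#>    statistic   p.value  n1  n2
#> 1 0.09400819 0.4326736 101 580
```

The flow object says the 100 migrants were routed over 54 origin–destination
pairs at a mean relocation distance of ≈5.1 km; the two repeats deposited
1.33 million seeds in 580 excretion events over 81 grid cells; and the
elevation distribution of simulated events is statistically indistinguishable
from the synthetic "observed" guava-containing dung piles (KS D = 0.094,
p = 0.43). `autoplot(res$seed_rain, res$bundle$grid)`,
`plot_trajectories()` and `plot_deposition_elevation()` draw the maps and
the per-repeat elevation envelope; `apply_fate_mask()` restricts the rain to
establishment-suitable cells.

A thin CLI wraps the same pipeline:

```sh
Rscript inst/cli/seedrain all --synthetic --seed 7 --out run1
```

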