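# pairforage

Coordination of parental care from paired GPS tracks of central-place
foragers.

## The problem

In biparental seabirds such as large gulls, both parents alternate between
guarding the nest and foraging trips that last hours and run far out of the
partner's sight. Do pair members *coordinate* — does a bird leave the colony
only once its partner has returned — and do they match each other's
investment? Raw overlap cannot answer this: two birds that are each often at
the nest will meet there frequently by chance. `pairforage` implements the
analysis chain for simultaneously GPS-tracked breeding pairs:

1. **Segmentation** — per-fix tracks are spliced into foraging trips (from
   the last fix inside the colony boundary to the first fix back inside)
   and nest bouts, clipped to the chick-rearing window (hatch day 0 to
   day 30 or failure), with 30-min/1-km trip filters.
2. **Coordination test** — for each pair, the proportion of departures with
   the partner present (per sex and pooled) and nest attendance (fraction
   of time with ≥ 1 parent in the colony) are compared against a
   randomisation null that permutes each bird's trip- and bout-duration
   multisets while preserving alternation: `p = (1 + #{null ≥ obs})/(R+1)`,
   one-tailed, `R = 999`, with exhaustive enumeration when the arrangement
   space is small.
3. **Behaviour classification** — rest / commute / forage from step length,
   signed turning angle, ground speed, accelerometer class and habitat;
   12 candidate input structures (4 stream sets × windows of 1/3/5 points),
   random-forest tuning by individual-grouped cross-validation, validation
   on held-out individuals; accuracy, Cohen's κ, precision/recall.
4. **Co-adjustment models** — gamma (log link) mixed models of trip
   duration on the partner's preceding trip and of nest-bout duration on
   offspring age; beta (logit) mixed model of daily nest attendance on age.
5. **Within-pair similarity** — a from-scratch MRPP
   (`delta = Σ (n_g/N) · mean within-pair dissimilarity`, 999 label
   permutations, one-tailed low, per colony) on five per-trip investment
   parameters: distance, duration, resting/flying/foraging hours.

A seeded generator of paired synthetic tracks (gamma trips with mean 4.4 h,
age-declining gamma bouts, a tunable probability `w` that a departure waits
for the partner's return, behaviour-dependent movement, accelerometer and
habitat emissions) makes every stage testable without field data.

## Worked example

```r
library(pairforage)

cfg <- sim_config(days = 30)                 # study-scale defaults
sim <- simulate_pair(cfg, pair_id = "P01", seed = 42, fixes = FALSE)
ps  <- pair_schedule(sim$truth)
ps
#> <pair_schedule P01: window 720.0 h>
#>   P01-F (female): 82 trips, 83 bouts
#>   P01-M (male): 80 trips, 80 bouts

set.seed(1)
randomisation_test(ps, n_rep = 999)
#> <randomisation_result P01 (sampled, 999 replicates)>
#>              male female partner attendance
#> observed   0.7595 0.7439  0.7516     0.8762
#> expected   0.4721 0.5455  0.5093     0.7588
#> difference 0.2874 0.1984  0.2423     0.1174
#> p          0.0010 0.0010  0.0010     0.0010
```

With the default waiting probability (`coordination_w = 0.65`) about 75% of
departures happen with the partner in the colony, against a null expectation
near 0.5 (the partner's share of time in the colony): the pair is
significantly coordinated (p = 0.001) on all four statistics.

The bundled reference table of 25 GPS-tracked lesser black-backed gull
pairs reproduces the published population summary:

```r
summarise_population(example_pair_table())
#>    statistic mean_observed mean_expected mean_difference n_significant n_pairs
#> 1       male       0.81524       0.47388         0.34144            22      25
#> 2     female       0.83488       0.41168         0.42304            23      25
#> 3    partner       0.82256       0.44000         0.38232            24      25
#> 4 attendance       0.93044       0.79548         0.13492            25      25
```

MRPP on a worked line example (three well-separated pairs of points):

```r
mrpp(c(0, 1, 10, 11, 20, 21), c("a", "a", "b", "b", "c", "c"))
#> <mrpp: observed delta 1.0000, expected 10.8667, within 1.0000, between 13.3333, p = 0.06667 (720 perms)>
```

The full pipeline (simulate → segment → coordination → models → MRPP) runs
from one configuration: `run_pipeline(list(simulate = list(n_pairs = 4,
days = 10)), out_dir = "out", seed = 1)`.

See `vignettes/pairforage-methods.Rmd` for the model and design decisions.

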