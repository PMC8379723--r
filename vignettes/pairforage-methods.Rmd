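---
title: "Methods: coordination of parental care from paired GPS tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coordination of parental care from paired GPS tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pairforage)
```

## The problem

In biparental central-place foragers such as large gulls, both parents
alternate between attending the nest and foraging trips that can last hours
and take place far out of the partner's sight. Whether the pair *coordinates*
-- one bird leaving only once the other has returned -- cannot be decided
from raw attendance fractions: two birds that each spend half their time at
the nest will often overlap by chance. `pairforage` implements the full
analysis chain for simultaneously GPS-tracked pairs: track segmentation,
a randomisation test of temporal coordination, behaviour classification from
trajectory features, regression models of trip and bout durations, and a
permutation test of within-pair similarity in investment.

## Segmentation

A foraging trip starts at the **last fix inside the colony boundary** before
an out-of-colony run and ends at the **first fix inside** after it; nest
bouts are the complementary in-colony intervals. Consequences of this splice
rule, and the choices made where a convention was needed:

* **Colony boundary.** Field deployments rarely publish an explicit
  boundary, so both a circle (centre + radius, default 500 m -- generous
  enough to absorb GPS scatter around a nest, small enough that a commuting
  bird leaves it within one 3-minute fix interval) and a simple polygon are
  supported. Membership is by great-circle distance or by point-in-polygon
  with boundary points counted inside.
* **Trip filters.** Trips shorter than 30 min *or* covering less than 1 km
  are excluded: resources that close to a colony are scarce and such
  excursions are unlikely to be foraging. The source sentence listing the
  two criteria is ambiguous about the combiner; the stricter either-fails
  reading is the default and the conjunctive reading is available via
  `filter_trips(combine = "both")`.
* **Censoring.** A track that begins or ends mid-trip yields a trip clipped
  at the window edge, flagged `censored_start`/`censored_end`. Censored
  intervals are excluded from duration models (their true duration is
  unknown) but kept for attendance, which only needs the observed portion.
* **Degenerate bouts.** When a single in-colony fix separates two trips, a
  zero-duration bout is emitted so trips and bouts keep alternating and tile
  the window exactly; duration models drop zero-length bouts.
* **Time and distance.** All timestamps are UTC; offspring age is
  `floor((t - hatch) / 1 day)` with hatch day = day 0. Distances are
  haversine on a sphere of radius 6371.0088 km; no map projection is used,
  and gaps are never interpolated (membership changes only at observed
  fixes). Trips spanning darkness are retained.

## The coordination statistics and their null

For each pair, on the common observation window:

* `male` / `female`: the proportion of the focal bird's departures at which
  the partner was inside the colony;
* `partner`: both sexes pooled;
* `attendance`: the fraction of the window with at least one parent inside
  the colony (the measure of the union of both birds' in-colony intervals).

At a departure instant the partner's in-colony interval is treated as
closed on the left: a partner returning at exactly that instant counts as
present, a partner departing simultaneously does not.

The null of uncoordinated care randomises each bird's schedule by
independently permuting its trip-duration and bout-duration multisets while
preserving the alternation order and the starting state. Because the
intervals tile the window, the rebuilt timeline spans exactly the same
window, so each bird's total trip time and total bout time are preserved --
the null destroys only the between-mate timing dependence. Both pair members
are re-randomised in every replicate by default (`randomise = "focal"`
restricts to one, since the source description is ambiguous on this point).

With `n_rep = 999` replicates the one-tailed p-value uses the add-one
estimator `(1 + #{null >= observed}) / (n_rep + 1)`; at 999 replicates the
decision at alpha = 0.05 coincides with "observed above the 95th percentile
of the null" and p is never exactly zero. When the arrangement space is
small (at most `exact_cap = 5000` joint permutations) the null is
enumerated exhaustively instead of sampled -- the standard exact-permutation
refinement -- which also lets tests compare the implementation against
brute-force oracles without Monte-Carlo slack.

Pairs in which a bird has fewer than two trips are flagged untestable rather
than tested.

## Attendance and duration models

* **Attendance vs age:** attendance is computed per pair-day (the source
  does not state the unit of observation; the day is the natural block for
  a quantity defined as a time fraction), shrunk from the 0/1 boundary by
  `(y(n-1) + 0.5)/n`, and fitted with a logit-link beta mixed model with
  pair and colony random intercepts.
* **Nest-bout duration vs age** and **trip duration vs the partner's
  preceding trip**: gamma mixed models with log link (durations are strictly
  positive), `age * sex` and `partner_prev * sex` fixed effects, and
  couple/bird/colony random intercepts. "Preceding trip" means the
  partner's most recent trip that *ended* before the focal departure; a trip
  still in progress is not "preceding" (`rule = "started"` gives the
  alternative reading).

Full models are always reported; there is no term selection. When a mixed
fit fails to produce a positive-definite Hessian with finite standard
errors, the random structure is simplified one term at a time, and as a last
resort a fixed-effects GLM with cluster-robust (by couple) standard errors
is fitted; every simplification or fallback is recorded in the returned
`model_fit`, never silent.

## Behaviour classification

Three behaviours are distinguished -- rest, commute, forage -- from up to
three feature streams: path geometry (step length; signed turning angle,
left turn positive, from the change of initial bearings), body movement
(ground speed and the accelerometer class, consumed as a ready-made input
column), and habitat class. Combined with symmetric input windows of 1, 3 or
5 points this yields 12 candidate input structures. For each candidate the
number of trees and the tree depth of a random forest are tuned by
cross-validation grouped by individual (default 5 folds) on the training
half only; the structure with the highest internal Cohen's kappa is selected
and refitted. Validation individuals are chosen by an individual-level
split, so no bird contributes fixes to both sides. Categorical features are
one-hot encoded with the level sets frozen at training time; unseen levels
at prediction time encode as all zeros with a warning. Rows lacking full
window context at track ends are dropped.

Reported metrics: accuracy, Cohen's kappa `(p_o - p_e)/(1 - p_e)`,
and per-class precision (column-correct / column total), recall
(row-correct / row total) and specificity.

The published headline numbers for this protocol (83.2% accuracy, kappa
0.712) come from an expert-annotated field dataset that is not bundled;
the package's tests instead verify the protocol end-to-end on simulated
tracks whose behaviours are separable by construction, where validation
accuracy above 0.90 is expected.

## Within-pair similarity (MRPP)

The Multiple Response Permutation Procedure is implemented from scratch (the
`vegan` implementation serves only as an independent cross-check in the test
suite). For a grouping into pairs, `delta` is the weighted mean of
within-group mean pairwise dissimilarities with the common `n_g/N` weights
(`(n_g-1)`-style weights available). The null reassigns observations to
groups of the original sizes; the test is one-tailed low, since a smaller
delta than expected means within-pair similarity. With at most 7
observations the permutation space is enumerated exactly, as for the
coordination test. Five per-trip investment parameters are tested, each
univariate with Euclidean distance and separately per colony: total
distance (km), trip duration (h), and resting/flying/foraging hours
obtained by counting annotated fixes within the trip and multiplying by the
fix interval. Per-trip rows are the default unit; the alternative (per-day
aggregation) can be built by aggregating the investment table before
calling `mrpp()`.

## The synthetic generator

Every downstream stage is testable without field data via a seeded generator
of paired tracks. Its defaults are the study conditions the package targets:

* 25 pairs over a 30-day chick-rearing window, fixes every 180 s;
* trip durations gamma with mean 4.4 h (shape 4 -- a realistic coefficient
  of variation of 0.5 for gull foraging trips);
* nest bouts gamma (shape 2.5) with age-0 mean 3.6 h, chosen so that the
  stationary in-colony fraction (~0.45) matches the null-expected partner
  presence around 0.44 seen in field estimates, and a log-linear age slope
  of -0.0142 per day, the field point estimate for this species;
* coordination as **departure-gating**: with probability `w` a departing
  bird waits until its partner has returned (plus an exponential lag, mean
  15 min), re-checked at the deferred instant so that `w = 1` forces the
  partner to be present at every departure. The default `w = 0.65`
  reproduces observed presence proportions around 0.8 given the ~0.45
  baseline. Gating coordinates *timing only* -- trip durations remain
  independent between mates, mirroring the empirical finding of coordinated
  timing without trip-to-trip duration co-adjustment;
* each bird holds 1-3 persistent foraging sites (optionally shared within
  the pair, which makes within-pair similarity a tunable property); trips
  run commute-out, area-restricted foraging (short tortuous steps within
  2 km of the site), an optional rest phase, and a straight commute back;
* per-fix emissions: true behaviour, noisy ground speed, an accelerometer
  class drawn through a row-stochastic confusion matrix (default 0.9
  diagonal), and a habitat label from the site map.

Pairs get child seeds derived deterministically from the master seed, so a
colony regenerates bit-identically. The generator runs continuously with no
diel gating (dark-hour trips were included in the field protocol it
emulates).

**What it does not emulate:** weather, tides and prey dynamics; device
outages and irregular fix intervals; real land-cover rasters (habitat is a
site-label map); 20-Hz accelerometer waveforms (only the class label); and
behavioural heterogeneity beyond the three-state repertoire. Passing tests
on simulated data therefore demonstrate the correctness and calibration of
the *methods*, not field-data effect sizes: the published per-pair
statistics are not reproducible without the deposited tracks, and the
package does not attempt that.

## Numerical choices and problem sizes

* Earth radius fixed at 6371.0088 km everywhere.
* Tie-breaks: structure selection keeps the first candidate within 1e-12 of
  the best kappa; `which.min` resolves simultaneous schedule events by
  individual order (a measure-zero event with continuous durations).
* Float comparisons in permutation counting use a 1e-12 guard so that
  regenerated identical arrangements count as `>=` the observed value.
* The test suite exercises calibration at 200 simulated pairs (999
  replicates each), parameter recovery at 50 pairs x 30 days, zero-effect
  coverage over 20 seeded runs at 20 pairs, and the classifier protocol on
  16 birds x 1 day of 3-minute fixes; these sizes give stable Monte-Carlo
  margins for the assertions they support.
* Recovery experiments for the bout-age slope simulate with the waiting
  probability set to zero. Departure-gating extends bouts by an additive,
  age-independent waiting time, which attenuates the *marginal* age slope
  by roughly 40% at the default `w`; the generative slope is a property of
  the bout-duration law, so that law is what recovery runs simulate from.
  (This attenuation is worth remembering when interpreting fitted bout
  models on strongly coordinated field data, too.)

## Known limitations

* The randomisation scheme permutes durations within the observed
  alternation; alternative nulls (e.g. rotation of one timeline) are not
  implemented, though the scheme is isolated behind `randomise_schedule()`.
* Attendance modelling assumes the pair-day as the exchangeable unit;
  autocorrelation within days is absorbed only by the random intercepts.
* Point-in-polygon treats lon/lat as planar, adequate for colony-scale
  polygons but not for polygons spanning degrees.
* The robust-error fallback for the beta model uses a quasi-binomial GLM
  for its point estimates, which matches the mean structure but not the
  beta variance function.
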