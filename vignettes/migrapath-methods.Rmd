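---
title: "Models and methods in migrapath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in migrapath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`migrapath` analyses the annual migration schedule of satellite-tagged
long-distance migrants — the motivating system is male common cuckoos
(*Cuculus canorus*) tagged in the UK and tracked to central Africa and
back — and asks what determines the timing of arrival at the breeding
grounds, how repeatable individual timing is, and whether timing predicts
stage-wise mortality. This vignette documents the models, the tunable
parameters, the synthetic-data generator, and the numerical and design
choices, in that order.

## From fixes to stopovers

Solar-powered satellite tags run a duty cycle of 10 h transmitting and 48 h
charging, so locations arrive in bursts ("transmission cycles") separated
by roughly 58 h. Segmentation proceeds in four steps:

1. **Cycle assignment** (`assign_cycles`). Fixes more than 10 h apart are
   assigned to different transmission cycles; the split is strict (a gap of
   exactly 10 h stays in one cycle).
2. **Best location per cycle** (`cycle_best_fixes`). One representative fix
   per cycle: best Argos quality class, ties broken by smallest haversine
   distance to the cycle's coordinate-wise median, remaining ties by
   earliest time. The exact quality criterion used for the original field
   data is not reproducible here, so the class ranking is a declared,
   configurable stand-in.
3. **Stopover detection** (`detect_stopovers`). Greedy left-to-right
   chaining: a cycle joins the open stopover if its best location lies
   within 50 km (inclusive) of the running centroid. Chains need at least
   two member cycles and at least one day (24 h elapsed between the first
   and last member best fix). Centroid linkage — rather than pairwise
   "all within 50 km of each other" — was chosen because it is insensitive
   to the order in which members arrive and stable under one noisy member.
4. **Gap extension** (`extend_through_gaps`). Tags commonly go quiet during
   a stopover (shade, battery depletion) and resume when the bird moves.
   When one or more whole cycles are missing before the bird is next seen
   somewhere else (more than 50 km away), the stopover's end is moved to
   the expected on-window of the last missed cycle, computed from the duty
   schedule anchored on the last received cycle. If the next observed
   location is at the same place, the missing cycles are simply bridged
   inside the stopover and nothing is flagged.

All distances are haversine on a sphere of radius 6371.0088 km; no
projection is ever used, and polygon membership (ray casting on lon/lat) is
boundary-inclusive.

## Six milestones and their uncertainty

The annual cycle is summarised by six milestones: departure from the
breeding grounds, completion of the southbound Sahara crossing, arrival to
and departure from the wintering grounds, departure from the West African
pre-Sahara stopover, and arrival at the breeding grounds. The operational
definitions (in `extract_milestones`) are stated in the function
documentation; two choices deserve comment. The breeding-site disc used for
departure and arrival has radius 50 km, matching the stopover radius, since
no independent value is available. And because every region is crossed
twice a year, "southbound" and "northbound" are disambiguated by a calendar
window — the post-breeding window runs 1 June–31 December of the cycle, the
pre-breeding window January onwards — combined with the latitude trend.
Cycle time is counted in continuous days since 1 June of the cycle's
starting year, so milestones never wrap at New Year; Julian days are
derived for reporting (`cycle_days_to_julian`).

Each milestone's uncertainty is the time gap from its basis fix to the next
fix (departure-type milestones) or the previous fix (arrival-type). A
West-Africa departure witnessed only by a fix already inside the Sahara
gets a fixed 2-day uncertainty — little time is spent on the crossing, so
the wide fix gap overstates the dating error. Milestones with uncertainty
above 5 days are excluded (the threshold is kept, not dropped, at exactly
5). Milestones whose uncertainty cannot be computed (no neighbouring fix,
typically at tag failure) are excluded too, which is the conservative
reading. The *full dataset* is what survives this filter; the *repeat
dataset* keeps bird-milestone combinations observed in more than one year
and carries the within-individual anomaly (date minus the bird's
across-year mean, summing to zero per bird and milestone).

## Repeatability

Per-milestone timing variance uses the ordinary sample variance; its 95%
interval comes from the closed-form posterior of a normal model with an
inverse-gamma(0.001, 0.001) prior, keeping variance intervals and
variance-components intervals in the same Bayesian currency. Consecutive
milestones are compared with two-sided F-tests.

Repeatability is estimated from the one-way random-intercept model
`date = mu + bird + error`, fitted by a conjugate Gibbs sampler with
inverse-gamma(0.001, 0.001) priors on both variances and a Normal(0,
1000² days) prior on the grand mean. R = between / (between + within),
computed draw-wise so its posterior interval is exact. Conventions: 4
chains, 2000 burn-in iterations discarded, 4000 retained, convergence
declared only if split-chain Rhat < 1.1 for every parameter;
non-convergence flags the fit rather than erroring. The split-chain Rhat is
clamped at 1 from below, since finite chains can push the ratio
fractionally under 1.

One sampling subtlety: duplicating every record does *not* leave the
posterior exactly unchanged. Doubling records halves the shrinkage
correction applied to observed bird means, lifting the between-bird
variance by roughly `s2_within / (2 * n_per_bird)`. The effect is small at
realistic designs (+0.03 on R at four records per bird and R = 0.5) but it
is a real property of the estimator, not sampler error.

## The timing path model

The path model is a system of linear structural equations over observed
variables: each milestone is regressed on its DAG parents, all variables
standardized (sample SD; binary covariates coded 0/1 first, then
standardized identically so that the squaring rule below applies to them
too). The default DAG (`default_timing_dag`) links habitat and route to
every milestone; breeding coordinates to breeding departure and arrival;
the latitude of the last European pre-Sahara stopover to the southbound
crossing; the longitude of the last West African stopover to West Africa
departure; every milestone to the next and to breeding arrival; and — the
one structure-learning step — a direct edge from the southbound Sahara
crossing to West Africa departure, which replaces the initial
wintering-arrival link after tests of directed separation
(`default_timing_dag(revised = FALSE)` reproduces the pre-revision DAG).

Fitting is a joint Gibbs sampler: conjugate normal draws for each node's
coefficients (Normal(0, 10²) priors), inverse-gamma(0.001, 0.001) residual
variances, and — the reason for fitting jointly — imputation of missing
entries from their full conditionals. A missing value sees its own node
equation and the equations of all its children, so imputation uncertainty
propagates into every coefficient posterior. Missing exogenous covariates
get a normal marginal model, or a posterior Bernoulli with a beta prior
when the column is binary. The same model runs on absolute dates (full
dataset) and on within-individual anomalies (repeat dataset).

Outputs follow the probability-of-direction convention: an edge's support
is `p = max(P(draws > 0), P(draws < 0))`, tiered at 0.80 (likely), 0.90
(well-supported) and 0.95 (very well-supported); edges below 0.80 are
suppressed from the headline table but kept in the full output. A
standardized coefficient squared is the percentage of the child's variance
carried by that direct path (so 0.883 explains 78.0%); the share carried
along a multi-edge path is the product of its stage shares; and a node's
"unexplained" remainder is reported both as 100 minus the printed direct
shares and, separately, via the node's residual variance.

`dsep_test` implements the union basis set: every non-adjacent ordered node
pair (pairs of exogenous covariates excluded, their association being
unconstrained), each tested by the partial coefficient of the earlier node
in a linear fit of the later node on it plus both nodes' parents; Fisher's
C = −2Σlog p on 2k degrees of freedom.

## The mortality model

For each milestone except wintering departure (too few certain events in
the following stage), mortality during the next migration stage is a
Bayesian logistic regression on standardized timing, habitat, route and
the habitat × timing interaction, alongside a linear sub-model of timing
on habitat and route. Priors are Normal(0, 5²) on all logistic
coefficients — weakly informative, and wide enough for the ±2-to-±4
log-odds effects such data produce while preventing separation blow-up at
small n. The sampler is random-walk Metropolis with a proposal covariance
taken from the ML fit and step size adapted during burn-in; an
all-survivor (or all-death) outcome yields a flagged, prior-dominated fit
with a warning rather than an error. The combined analysis pools the three
milestones following the stages that most positively impact breeding
arrival (Sahara crossing, West Africa departure, breeding arrival) with
milestone-specific intercepts and a shared timing slope, timing having been
standardized within milestone before pooling. Tag-failure adjudication is
out of scope; deaths carry a per-event certainty flag and uncertain events
are dropped with a count.

## The synthetic cohort

Every stage is testable offline because the package generates its own
cohorts (`simulate_cohort`). Design:

* **Schedules.** Milestone dates are generated on a standardized latent
  scale from the declared DAG. Residual variances are solved against the
  running joint covariance so every node has exactly unit marginal
  variance — the configured edge coefficients therefore *are* the true
  standardized path coefficients, which is what makes oracle-recovery
  tests meaningful. Default coefficients echo the magnitudes this system
  produces (0.883 for West Africa departure → arrival, 0.516 for the
  crossing → West Africa edge, 0.653 for breeding longitude → departure,
  and so on). A per-bird random intercept per milestone sets true
  repeatability; by default it takes 35% of each node's residual variance,
  the middle of the low-to-moderate range such data show. Dates are
  `mean + sd * z` with means staging the cycle from early July (breeding
  departure) to early May (arrival) and SDs largest for wintering-ground
  movements (25 days) and smallest at West Africa departure (9 days).
  Rows violating within-cycle monotonicity are resampled (rare at the
  default scales).
* **Mortality.** After each milestone a Bernoulli death draw with log-odds
  `intercept + slope * z`; the first success sets the death stage, the
  death time is uniform within the stage (the data only localise mortality
  to a stage), the track truncates there and the bird contributes no later
  cycles. Defaults produce no deaths; studies switch slopes on explicitly.
* **Tracks.** Piecewise great-circle movement at 50 km/h between fixed
  corridor waypoints (southwest via Iberia or southeast via Italy
  southbound; everyone returns via the west), holds at stopovers, fixes
  only inside on-windows of the duty cycle, whole cycles dropped with the
  configured probability, isotropic Gaussian positional noise in a local
  tangent plane, and a constant best quality class. Two rendering details
  matter for fidelity: the duty schedule runs on one continuous per-bird
  clock across years (tags do not re-phase annually), and each on-window
  emits a tight mid-window burst of three fixes so that every transmission
  cycle has a well-defined location even when the bird departs mid-window.
  With noise and missed cycles disabled, every extracted milestone then
  falls within one full duty cycle (58 h) of its true date.

What the generator does *not* emulate: wind and weather, refuelling
dynamics, Argos class heterogeneity, irregular extra transmissions on good
battery days, and real coastline-shaped regions (the packaged GeoJSON is a
synthetic, simplified rectangle set). Passing tests therefore demonstrate
the pipeline's correctness under the stated observation model, not
robustness to every artefact of real Argos data.

## Problem sizes and numerical choices

Single fits use the full MCMC conventions (4 chains × (2000 + 4000)).
Replicate studies scale down to keep whole-suite runtimes in minutes:
interval-coverage studies run 30–60 datasets at the field scale of 87
birds / 137 cycles with 10–30% missingness under 1 chain × (300 + 700);
repeatability recovery uses 20–40 datasets of 87 birds × 3 years;
directed-separation calibration uses 60–100 datasets; mortality null
calibration 80–100 replicates. These sizes were chosen so that binomial
and Monte-Carlo error on each summary is comfortably below the margin
being asserted. One calibration note: "strong support" (p ≥ 0.95)
corresponds to a 90% interval excluding zero, so under a true null it
occurs in about 10% of replicates by construction; the acceptance checks
treat that 10% as the reference rate within binomial error, not as a bound
the rate should sit far below.

Degenerate inputs are handled explicitly: constant columns refuse to
standardize; a constant date vector yields variance zero with a flagged
degenerate interval; nodes with more parents than observations are
rejected by name; zero flight speed with distinct waypoints is an error;
single-class mortality outcomes are flagged prior-dominated.

## Known limitations

Milestones that fall outside their cycle's 1 June–31 May window (a very
late arrival sliding past 31 May) are not recovered — about 1% of
bird-years at the default scales. Route classification approximates
chord–polygon intersection by sampling the great circle every 20 km, which
is exact for the packaged region sizes but could miss a sliver of a very
small polygon. The d-separation test conditions on parents only, which is
valid for DAGs without latent confounders; none are modelled. The
independence of repeated bird-cycles within one milestone's mortality
dataset is assumed, matching the data structure available.
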