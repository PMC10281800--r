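# migrapath

Migration-timing analysis for duty-cycled satellite telemetry: from raw
Argos-style fixes to stopovers, annual-cycle milestones, repeatability,
Bayesian path analysis of what determines breeding-grounds arrival, and
timing-dependent mortality. The motivating system is long-distance migrant
birds (the common cuckoo, *Cuculus canorus*) tagged in the UK and tracked
through West and central Africa, but every stage is parameterised and runs
end-to-end on the package's own synthetic cohorts, so no field data are
required.

## What it computes

Solar satellite tags transmit 10 h on / 48 h off, so tracks arrive as
bursts of fixes ("transmission cycles"). The pipeline:

1. **Segmentation** — cycles split at gaps > 10 h; one best location per
   cycle; stopovers as chains of consecutive cycles within 50 km of the
   running centroid, at least 2 cycles and 1 day long; stopover ends
   extended through whole missed cycles when the tag next reports from
   somewhere else.
2. **Milestones** — six events per annual cycle (departure from the
   breeding grounds, completion of the southbound Sahara crossing, arrival
   to and departure from the wintering grounds, departure from the West
   African stopover, arrival at the breeding grounds), each with an
   uncertainty equal to the neighbouring fix gap (fixed at 2 days for
   desert-crossing-based West Africa departures); milestones with
   uncertainty above 5 days are excluded.
3. **Repeatability** — per-milestone variance with Bayesian intervals,
   F-tests between consecutive milestones, and the variance-components
   model `date = mu + bird + error` fitted by a conjugate Gibbs sampler;
   repeatability `R = s2_between / (s2_between + s2_within)` draw-wise.
4. **Timing path model** — Bayesian piecewise structural equations over a
   declared DAG with MCMC imputation of missing entries. Standardized
   coefficients; an edge's variance share is its squared coefficient
   (`0.883^2` → 78.0%), multi-edge shares multiply, and edges are tiered
   by probability of direction (0.80 / 0.90 / 0.95). Directed-separation
   (Fisher's C) testing supports the single structure revision the model
   carries.
5. **Mortality model** — per-milestone Bayesian logistic regression of
   death in the following stage on standardized timing, habitat, route and
   habitat × timing, plus a pooled three-milestone fit with a shared slope.
6. **Synthetic cohorts** — schedules drawn from a linear-Gaussian DAG with
   unit-variance nodes (so configured coefficients are true standardized
   path coefficients), per-bird random intercepts setting true
   repeatability, stage-wise Bernoulli mortality, and tracks rendered
   along great-circle corridors through the actual duty cycle with missed
   cycles and positional noise.

## Worked example

```r
library(migrapath)

cfg <- run_config(seed = 11,
                  sim = sim_config(n_birds = 40, n_years = 3, seed = 11),
                  mcmc = mcmc_settings(chains = 2, burnin = 500,
                                       draws = 1000, seed = 11))
res <- run_pipeline("all", cfg)
```

The log for this run prints, among other lines:

```
[simulate] 36371 fixes, 96 bird-years
[segment] 12124 cycles -> 532 stopovers
[milestones] 501 milestones from 91 migratory cycles for 38 birds retained (1 excluded)
[repeatability] mean R = 0.377
[path-timing] 18 supported edges; converged: TRUE
```

which reads: 96 simulated bird-years produced 36,371 duty-cycled fixes;
segmentation found 12,124 transmission cycles and 532 stopovers; 501
milestones survived the 5-day uncertainty filter; mean repeatability
across the six milestones is 0.38 (individuals are moderately consistent);
and the path model converged with 18 edges at or above the 0.80
probability tier. Individual results are tibbles and fitted objects with
`tidy()`, `glance()` and `autoplot()` methods:

```r
tidy(res$path_timing)                       # per-edge posterior summary
summarize_paths(res$path_timing)            # the headline table
autoplot(res$repeatability$fits$depart_west_africa)
variance_explained(0.883)                   # 77.97 -> "78.0%"
chain_variance_share(c(15.8, 26.6, 78.0))   # 3.3% of arrival variance
```

A thin command-line wrapper lives at `inst/cli/migrapath.R`
(`Rscript migrapath.R all --config run.yaml`).

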