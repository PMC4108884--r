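# flowgraphsurv

Semi-Markov flowgraph modelling of the recurrence–progression process in
non-muscle-invasive bladder cancer.

After transurethral resection of a superficial bladder tumour, a patient may
stay disease-free, suffer a recurrence at a similar stage, or progress to
muscle-invasive disease. The package models this as a three-state
illness–death process (0 = disease-free, 1 = first recurrence,
2 = progression) in the semi-Markov sense — arbitrary waiting-time laws per
transition, not just exponentials — and answers the clinical question
*"what is the probability of being free of progression at time t?"*
parametrically. It is written for biostatisticians working with
multistate event-history data under heavy right censoring.

## Method

Each branch of the flowgraph carries a transmittance
`p_ij · LT_ij(s)`: the transition probability times the Laplace transform of
the branch waiting-time density. Waiting times are modelled as mixtures of
three Erlang distributions,

    G(t) = p1 F1(t) + p2 F2(t) + p3 F3(t),   shapes (r1, r2, r3) = (1, 3, 5),

which are phase-type distributions `(α, T)`, so CDF, density, hazard and
Laplace transform all have matrix closed forms. Per transition, the
empirical waiting-time CDF is estimated by Kaplan–Meier (competing exits
treated as censoring), and the mixture is fitted by minimizing the Euclidean
norm `‖F̂_ij(t) − G_ij(t)‖` over the KM jump times, with weights initialized
by non-negative least squares (Lawson–Hanson). The series/parallel flowgraph
rules combine the branch transforms into the normalized first-passage
transform from disease-free to progression,

    LT(s) = [p01·p12·LT01(s)·LT12(s) + p02·LT02(s)] / (p01·p12 + p02),

which is inverted numerically (Abate–Whitt EULER algorithm) into density,
survival and hazard curves. A homogeneous continuous-time Markov chain with
occurrence/exposure intensities serves as the baseline the flowgraph model
is contrasted with. Because the motivating hospital series is not public, a
seeded synthetic-cohort generator reproduces its structure (957 patients,
branch probabilities p01 = 0.3967742, p02 = 0.02507837, p12 = 0.03252033,
roughly half the cohort censored while disease-free).

## Worked example

The `analysis/` directory holds the narrative drivers; running them in
order reproduces the whole analysis from scratch:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_fit_transitions.R
Rscript analysis/03_flowgraph_survival.R
Rscript analysis/04_markov_comparison.R
```

The first script simulates the cohort and prints its event structure:

```
Simulated 957 patients (1323 sojourn records):
  first recurrences observed:      366
  direct progressions (0 -> 2):    24
  progressions after recurrence:   8
  censored in disease-free state:  567  (59%)
```

The third runs the full pipeline (`run_flowgraph_analysis()`):

```
Flowgraph analysis of the recurrence-progression process
  branch probabilities: p01 = 0.38245  p02 = 0.025078  p12 = 0.021858
  overall 0->2 passage probability: 0.033438
  transition 01 fit objective: 0.525
  transition 02 fit objective: 0.006833
  transition 12 fit objective: 0.001718
  sup|S_flowgraph - S_markov| = 0.05216
  sup|S_flowgraph - S_KM| = 0.03695
progression-free survival: 5y 0.9990, 10y 0.9980
```

Reading this: the cohort-derived branch probabilities give an overall
probability of ever progressing of about 3.3%; the per-transition fit
objectives are the Euclidean CDF discrepancies at the KM jump times; the
two sup-distances compare the model's progression-free survival with the
Markov baseline and with the empirical Kaplan–Meier curve on the same
grid; and the headline clinical output is the parametric progression-free
survival at 5 and 10 years. The fourth script contrasts the two models on
strongly non-exponential (Erlang-5-dominated) sojourns, where the
flowgraph curve lands at less than half the Markov baseline's distance
from the analytic truth:

```
sup-distance to the analytic progression-free survival:
  flowgraph (Erlang-mixture) model: 0.1003
  homogeneous Markov baseline:      0.2314
```

Programmatic use mirrors the scripts:

```r
library(flowgraphsurv)
cohort <- simulate_cohort(paper_like_profile(seed = 1))
res <- run_flowgraph_analysis(cohort)
head(res$curve)   # t_years, pdf, survival, hazard, survival_uncond
```

See `vignettes/flowgraph-methods.Rmd` for the model, the estimation and
inversion choices, and what the synthetic benchmarks do and do not show.

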