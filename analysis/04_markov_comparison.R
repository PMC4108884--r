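#!/usr/bin/env Rscript
# Contrast benchmark: on a cohort with strongly non-exponential
# (Erlang-5-dominated) sojourn times, measure how far the flowgraph model
# and the homogeneous Markov baseline each land from the analytic
# progression-free survival of the generating process.  The design is fully
# transient (every patient leaves state 0, every recurrence progresses) so
# the per-branch estimates are identified and the contrast isolates the
# distributional assumption.  Writes results/markov_comparison.json.

suppressPackageStartupMessages(library(flowgraphsurv))
dir.create("results", showWarnings = FALSE)

specs <- list(
  s01 = erlang_mixture_spec(c(0.03, 0.07, 0.90), c(0.4, 1.5, 2.0)),
  s02 = erlang_mixture_spec(c(0.05, 0.05, 0.90), c(0.3, 1.0, 1.6)),
  s12 = erlang_mixture_spec(c(0.04, 0.06, 0.90), c(0.5, 1.2, 2.2)))
p01 <- 0.95; p02 <- 0.05; p12 <- 1.0

cfg <- cohort_config(4000, p01, p02, p12, specs,
                     censor_law = list(dropout_rate = 0.02, horizon = 30),
                     seed = 801L)
res <- run_flowgraph_analysis(simulate_cohort(cfg))

truth <- first_passage_phase_type(specs$s01, specs$s12, specs$s02,
                                  p01, p02, p12)
S_true <- 1 - (p01 * p12 + p02) * ph_cdf(truth, res$curve$t_years)
d_flow <- max(abs(res$curve$survival_uncond - S_true))
d_markov <- max(abs(res$markov_curve$survival - S_true))

message(sprintf("sup-distance to the analytic progression-free survival:"))
message(sprintf("  flowgraph (Erlang-mixture) model: %.4f", d_flow))
message(sprintf("  homogeneous Markov baseline:      %.4f", d_markov))
message(if (d_flow < d_markov)
  "the semi-Markov flowgraph model tracks the truth more closely"
  else "the Markov baseline was closer on this draw")

jsonlite::write_json(
  list(sup_flowgraph = d_flow, sup_markov = d_markov,
       n_patients = cfg$n_patients),
  "results/markov_comparison.json", auto_unbox = TRUE, digits = NA)
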