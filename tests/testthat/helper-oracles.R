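# Independent oracles used across the suite.

# Gamma-based mixture CDF/PDF oracle (closed form, independent of the
# phase-type matrix route).
gamma_mix_cdf <- function(w, mu, r, t) {
  w[1] * pgamma(t, r[1], rate = mu[1]) +
    w[2] * pgamma(t, r[2], rate = mu[2]) +
    w[3] * pgamma(t, r[3], rate = mu[3])
}
gamma_mix_pdf <- function(w, mu, r, t) {
  w[1] * dgamma(t, r[1], rate = mu[1]) +
    w[2] * dgamma(t, r[2], rate = mu[2]) +
    w[3] * dgamma(t, r[3], rate = mu[3])
}

# Simulate absorption times of the Markov chain underlying (alpha, T) by
# walking the embedded jump chain with exponential holding times; vectorized
# over walkers, one sweep per jump.
r_phase_type <- function(n, ph) {
  m <- ph$m
  rates <- -diag(ph$T)
  # jump probabilities: to transient j or to absorption (state m + 1)
  P <- cbind(ph$T / rates, ph$T0 / rates)
  diag(P) <- 0
  state <- sample.int(m + 1L, n, replace = TRUE,
                      prob = c(ph$alpha, ph$alpha_abs))
  t_acc <- numeric(n)
  while (any(state <= m)) {
    for (s in unique(state[state <= m])) {
      idx <- which(state == s)
      t_acc[idx] <- t_acc[idx] + rexp(length(idx), rates[s])
      state[idx] <- sample.int(m + 1L, length(idx), replace = TRUE,
                               prob = P[s, ])
    }
  }
  t_acc
}

# sup |empirical CDF of x - F| evaluated on a fine grid (adequate for smooth F)
ks_grid <- function(x, F_fun, grid = NULL) {
  if (is.null(grid)) grid <- seq(0, max(x) * 1.02, length.out = 4096)
  Fe <- ecdf(x)
  max(abs(Fe(grid) - F_fun(grid)))
}

# small three-patient cohort used by bookkeeping tests:
# patient 1: 0 -> 1 at 2.0y, then 1 -> 2 at 1.5y (absolute 3.5y)
# patient 2: censored in state 0 at 4y
# patient 3: 0 -> 2 at 1.2y
toy_cohort <- function() {
  data.frame(
    id = c(1L, 1L, 2L, 3L),
    origin = c(0L, 1L, 0L, 0L),
    dest = c(1L, 2L, NA_integer_, 2L),
    duration_years = c(2.0, 1.5, 4.0, 1.2),
    status = c("event", "event", "censored", "event"))
}

# sojourn mixtures shared by the end-to-end benchmarks
bench_specs <- function() default_sojourn_specs()

erlang5_specs <- function() list(
  s01 = erlang_mixture_spec(c(0.03, 0.07, 0.90), c(0.4, 1.5, 2.0)),
  s02 = erlang_mixture_spec(c(0.05, 0.05, 0.90), c(0.3, 1.0, 1.6)),
  s12 = erlang_mixture_spec(c(0.04, 0.06, 0.90), c(0.5, 1.2, 2.2)))
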