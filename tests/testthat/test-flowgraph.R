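exp_lt <- function(lam) function(s) lam / (s + lam)

test_that("series composition convolves exponential branches", {
  a <- transmittance(1, exp_lt(0.8))
  b <- transmittance(1, exp_lt(2.0))
  ser <- tm_series(a, b)
  s <- seq(0, 8, length.out = 30)
  expect_equal(ser$p, 1)
  expect_lt(max(abs(ser$lt(s) - 0.8 * 2.0 / ((s + 0.8) * (s + 2.0)))), 1e-14)
  # degenerate instantaneous second branch leaves the first unchanged
  ident <- transmittance(1, function(s) rep(1, length(s)) + 0 * s)
  ser2 <- tm_series(a, ident)
  expect_equal(ser2$p, a$p)
  expect_equal(ser2$lt(s), a$lt(s))
  expect_equal(Re(ser$lt(0)), 1)
})

test_that("parallel composition mixes transmittances and guards mass", {
  a <- transmittance(0.5, exp_lt(1))
  b <- transmittance(0.5, exp_lt(3))
  par <- tm_parallel(a, b)
  s <- seq(0, 5, length.out = 20)
  expect_equal(par$p, 1)
  expect_lt(max(abs(par$lt(s) - 0.5 * (exp_lt(1)(s) + exp_lt(3)(s)))), 1e-14)
  expect_equal(Re(par$lt(0)), 1)
  expect_error(tm_parallel(transmittance(0.7, exp_lt(1)),
                           transmittance(0.5, exp_lt(2))), "> 1")
  expect_error(transmittance(0.5, function(s) 2 / (s + 2) + 0.1), "lt\\(0\\)")
})

test_that("first-passage transform is a proper normalized mixture of paths", {
  p01 <- 0.3967742; p02 <- 0.02507837; p12 <- 0.03252033
  model <- flowgraph_model(transmittance(p01, exp_lt(0.9)),
                           transmittance(p02, exp_lt(0.4)),
                           transmittance(p12, exp_lt(1.7)))
  fp <- first_passage_lt(model, 0, 2)
  expect_equal(fp$p, p01 * p12 + p02, tolerance = 1e-15)
  expect_equal(Re(fp$lt(0)), 1, tolerance = 1e-12)
  # symbolic equivalence for exponential branches: weighted mixture of a
  # two-fold convolution and a single exponential
  s <- seq(0.01, 10, length.out = 40)
  wA <- p01 * p12 / (p01 * p12 + p02)
  oracle <- wA * (0.9 / (s + 0.9)) * (1.7 / (s + 1.7)) +
    (1 - wA) * (0.4 / (s + 0.4))
  expect_lt(max(abs(fp$lt(s) - oracle)), 1e-14)
  # completely monotone: strictly inside (0, 1) and decreasing for real s > 0
  expect_true(all(fp$lt(s) > 0 & fp$lt(s) < 1))
  expect_true(all(diff(fp$lt(s)) < 0))
  # vanishing via-path probability collapses to the direct branch
  model2 <- flowgraph_model(transmittance(p01, exp_lt(0.9)),
                            transmittance(p02, exp_lt(0.4)),
                            transmittance(1e-14, exp_lt(1.7)))
  fp2 <- first_passage_lt(model2, 0, 2)
  expect_lt(max(abs(fp2$lt(s) - 0.4 / (s + 0.4))), 1e-10)
  expect_error(first_passage_lt(model, 1, 2), "supported")
  # unnormalized transform remains accessible for composition
  un <- first_passage_lt(model, 0, 2, normalize = FALSE)
  expect_equal(Re(un$lt(0)), un$p, tolerance = 1e-12)
})

test_that("first-passage transform agrees with semi-Markov path simulation", {
  set.seed(300)
  specs <- bench_specs()
  p01 <- 0.3967742; p02 <- 0.02507837; p12 <- 0.03252033
  x <- r_first_passage(2e4, p01, p02, p12, specs)
  model <- flowgraph_model(
    transmittance(p01, function(s) em_laplace(specs$s01, s)),
    transmittance(p02, function(s) em_laplace(specs$s02, s)),
    transmittance(p12, function(s) em_laplace(specs$s12, s)))
  fp <- first_passage_lt(model, 0, 2)
  # analytic CDF of the conditional first-passage law via its explicit
  # phase-type form
  truth <- first_passage_phase_type(specs$s01, specs$s12, specs$s02,
                                    p01, p02, p12)
  grid <- seq(0, max(x), length.out = 512)
  expect_lt(ks_grid(x, function(u) ph_cdf(truth, u), grid), 0.02)
  # and the transform itself matches the empirical Laplace transform
  for (sv in c(0.3, 1, 3))
    expect_lt(abs(Re(fp$lt(sv)) - mean(exp(-sv * x))), 0.01)
})

test_that("transition probabilities are at-risk ratios with overrides allowed", {
  co <- toy_cohort()
  p <- estimate_transition_probs(co)
  expect_equal(unname(p), c(1 / 3, 1 / 3, 1))
  expect_error(estimate_transition_probs(co[co$origin == 0, , drop = FALSE]),
               "state 1")
})
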