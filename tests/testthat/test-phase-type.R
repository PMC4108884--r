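test_that("Erlang constructor matches gamma closed forms and validates input", {
  t <- seq(0.1, 20, length.out = 41)
  for (lam in c(0.8, 2.0)) for (r in c(1L, 3L, 5L)) {
    ph <- make_erlang(r, lam)
    expect_lt(max(abs(ph_cdf(ph, t) - pgamma(t, r, rate = lam))), 1e-10)
    expect_lt(max(abs(ph_pdf(ph, t) - dgamma(t, r, rate = lam))), 1e-10)
  }
  # exponential special case: 1x1 representation
  ph1 <- make_erlang(1, 0.7)
  expect_identical(ph1$alpha, 1)
  expect_identical(drop(ph1$T), -0.7)
  expect_identical(ph1$T0, 0.7)
  expect_error(make_erlang(0, 1.0), "positive integer")
  expect_error(make_erlang(2.5, 1.0), "positive integer")
  expect_error(make_erlang(3, -1), "positive")
})

test_that("mixture representation has the canonical block structure", {
  p <- c(0.25, 0.45, 0.30); mu <- c(0.5, 1.3, 2.1)
  mix <- make_erlang_mixture(erlang_mixture_spec(p, mu))
  expect_identical(mix$alpha, c(p[1], p[2], 0, 0, p[3], 0, 0, 0, 0))
  expected_T <- matrix(0, 9, 9)
  expected_T[1, 1] <- -mu[1]
  for (k in 2:4) expected_T[k, k] <- -mu[2]
  expected_T[2, 3] <- expected_T[3, 4] <- mu[2]
  for (k in 5:9) expected_T[k, k] <- -mu[3]
  for (k in 5:8) expected_T[k, k + 1] <- mu[3]
  expect_equal(mix$T, expected_T)
  expect_equal(-as.numeric(mix$T %*% rep(1, 9)), mix$T0)
})

test_that("representation invariants hold for every constructed object", {
  specs <- list(erlang_mixture_spec(c(0.6, 0.3, 0.1), c(0.4, 1, 2)),
                erlang_mixture_spec(c(1/3, 1/3, 1/3), c(2, 2.5, 0.3),
                                    c(2, 4, 1)))
  phs <- c(lapply(specs, make_erlang_mixture),
           list(make_erlang(1, 1.5), make_erlang(5, 0.9)))
  for (ph in phs) {
    expect_equal(-as.numeric(ph$T %*% rep(1, ph$m)), ph$T0, tolerance = 1e-14)
    expect_equal(sum(ph$alpha) + ph$alpha_abs, 1, tolerance = 1e-14)
    expect_true(all(diag(ph$T) < 0))
  }
  expect_error(new_phase_type(c(0.5, 0.4), rbind(c(-1, 1), c(0, -2))),
               "sum")
  expect_error(new_phase_type(c(1, 0), rbind(c(-1, 2), c(0, -2))),
               "row sums")
  expect_error(erlang_mixture_spec(c(0.5, 0.5, 0.1), c(1, 1, 1)), "sum to 1")
  expect_error(erlang_mixture_spec(c(0.5, 0.5, 0), c(1, 1, 1)), "positive")
})

test_that("mixture CDF equals the weighted gamma CDFs and collapses correctly", {
  w <- c(0.5, 0.3, 0.2); mu <- c(0.5, 1.5, 2.5); r <- c(1, 3, 5)
  mix <- make_erlang_mixture(erlang_mixture_spec(w, mu, r))
  t <- seq(0, 15, length.out = 31)
  expect_lt(max(abs(ph_cdf(mix, t) - gamma_mix_cdf(w, mu, r, t))), 1e-9)
  expect_lt(max(abs(ph_pdf(mix, t[-1]) - gamma_mix_pdf(w, mu, r, t[-1]))),
            1e-9)
  expect_equal(ph_cdf(mix, 0), 0)
  # near-degenerate weights collapse to the first Erlang component
  eps <- 1e-12
  mix1 <- make_erlang_mixture(
    erlang_mixture_spec(c(1 - 2 * eps, eps, eps), mu, r))
  expect_lt(max(abs(ph_cdf(mix1, t) - pgamma(t, r[1], rate = mu[1]))), 1e-9)
})

test_that("cdf/survival are monotone, complementary and normalized", {
  mix <- make_erlang_mixture(erlang_mixture_spec(c(0.2, 0.5, 0.3),
                                                 c(0.6, 1.4, 2.2)))
  t <- seq(0, 25, length.out = 60)
  F <- ph_cdf(mix, t); S <- ph_survival(mix, t)
  expect_true(all(diff(F) >= -1e-12))
  expect_true(all(diff(S) <= 1e-12))
  expect_true(all(F >= 0 & F <= 1) && all(S >= 0 & S <= 1))
  expect_lt(max(abs(F + S - 1)), 1e-12)
  expect_equal(stats::integrate(function(u) ph_pdf(mix, u), 0, 100,
                                subdivisions = 400L)$value, 1,
               tolerance = 1e-6)
  expect_error(ph_cdf(mix, -0.1), "non-negative")
})

test_that("pdf agrees with the numerical derivative of the cdf", {
  mix <- make_erlang_mixture(erlang_mixture_spec(c(0.4, 0.4, 0.2),
                                                 c(0.8, 1.2, 2.0)))
  h <- 1e-4
  t <- seq(0.5, 10, length.out = 20)
  num <- (ph_cdf(mix, t + h) - ph_cdf(mix, t - h)) / (2 * h)
  expect_lt(max(abs(num - ph_pdf(mix, t))), 1e-6)
})

test_that("hazard matches gamma oracle, is constant for exponentials, errors on underflow", {
  t <- seq(0.2, 10, length.out = 15)
  expect_equal(ph_hazard(make_erlang(1, 1.3), t), rep(1.3, length(t)),
               tolerance = 1e-10)
  ph3 <- make_erlang(3, 0.9)
  oracle <- dgamma(t, 3, rate = 0.9) / pgamma(t, 3, rate = 0.9,
                                              lower.tail = FALSE)
  expect_equal(ph_hazard(ph3, t), oracle, tolerance = 1e-8)
  expect_error(ph_hazard(make_erlang(1, 2), 500), "underflow")
})

test_that("Laplace transform matches closed forms and mixture linearity", {
  s <- seq(0.01, 10, length.out = 25)
  for (lam in c(0.8, 2)) for (r in c(1L, 3L, 5L)) {
    expect_lt(max(abs(ph_laplace(make_erlang(r, lam), s) -
                        (lam / (s + lam))^r)), 1e-12)
  }
  w <- c(0.3, 0.5, 0.2); mu <- c(0.4, 1.1, 2.3); r <- c(1, 3, 5)
  mix <- make_erlang_mixture(erlang_mixture_spec(w, mu, r))
  lt_oracle <- w[1] * (mu[1] / (s + mu[1]))^r[1] +
    w[2] * (mu[2] / (s + mu[2]))^r[2] + w[3] * (mu[3] / (s + mu[3]))^r[3]
  expect_lt(max(abs(ph_laplace(mix, s) - lt_oracle)), 1e-10)
  expect_equal(ph_laplace(mix, 0), 1, tolerance = 1e-12)
  # complex arguments agree with the closed form too
  sc <- complex(real = c(0.5, 2), imaginary = c(3, -7))
  lt_c <- w[1] * (mu[1] / (sc + mu[1]))^r[1] +
    w[2] * (mu[2] / (sc + mu[2]))^r[2] + w[3] * (mu[3] / (sc + mu[3]))^r[3]
  expect_lt(max(Mod(ph_laplace(mix, sc) - lt_c)), 1e-12)
})

test_that("Monte-Carlo chain simulation reproduces the analytic CDF", {
  set.seed(401)
  mix <- make_erlang_mixture(erlang_mixture_spec(c(0.5, 0.3, 0.2),
                                                 c(0.5, 1.5, 2.5)))
  x <- r_phase_type(1e5, mix)
  grid <- seq(0, max(x), length.out = 1024)
  expect_lt(ks_grid(x, function(u) ph_cdf(mix, u), grid), 0.01)
})

test_that("serialization round-trips decimal literals exactly", {
  spec <- erlang_mixture_spec(c(0.3967742, 0.5781474, 0.02507837),
                              c(0.4, 1.1, 2.3))
  f <- tempfile(fileext = ".json")
  write_spec_json(spec, f)
  back <- read_spec_json(f)
  expect_identical(back$weights, spec$weights)
  expect_identical(back$rates, spec$rates)
  expect_identical(back$shapes, spec$shapes)
  ph <- make_erlang_mixture(spec)
  f2 <- tempfile(fileext = ".json")
  write_spec_json(ph, f2)
  back2 <- read_spec_json(f2)
  expect_identical(back2$T, ph$T)
  expect_identical(back2$alpha, ph$alpha)
  unlink(c(f, f2))
})
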