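# closed-form battery: exponential, Erlang r in {1,3,5}, two-phase
# hypoexponential, three-component Erlang mixture
inversion_battery <- function() {
  w <- c(0.5, 0.3, 0.2); mu <- c(0.5, 1.5, 2.5); r <- c(1, 3, 5)
  list(
    exponential = list(
      lt = function(s) 1 / (s + 1),
      pdf = function(t) dexp(t, 1)),
    erlang3 = list(
      lt = function(s) (2 / (s + 2))^3,
      pdf = function(t) dgamma(t, 3, rate = 2)),
    erlang5 = list(
      lt = function(s) (1.4 / (s + 1.4))^5,
      pdf = function(t) dgamma(t, 5, rate = 1.4)),
    hypoexp = list(
      lt = function(s) (0.8 / (s + 0.8)) * (2.2 / (s + 2.2)),
      # difference-of-exponentials closed form
      pdf = function(t) 0.8 * 2.2 / (2.2 - 0.8) *
        (exp(-0.8 * t) - exp(-2.2 * t))),
    mixture = list(
      lt = function(s) w[1] * (mu[1] / (s + mu[1]))^r[1] +
        w[2] * (mu[2] / (s + mu[2]))^r[2] + w[3] * (mu[3] / (s + mu[3]))^r[3],
      pdf = function(t) gamma_mix_pdf(w, mu, r, t)))
}

battery_error <- function(t, ...) {
  max(vapply(inversion_battery(), function(case)
    max(abs(euler_invert(case$lt, t, ...) - case$pdf(t))), numeric(1)))
}

test_that("EULER inversion matches closed-form densities below 1e-6", {
  t <- seq(0.1, 20, length.out = 80)
  expect_lt(battery_error(t), 1e-6)
  # named spot checks from the closed forms
  expect_equal(euler_invert(function(s) 1 / (s + 1), 1), exp(-1),
               tolerance = 1e-7)
  expect_equal(euler_invert(function(s) (2 / (s + 2))^3, 1.5),
               dgamma(1.5, 3, rate = 2), tolerance = 1e-6)
  expect_error(euler_invert(function(s) 1 / (s + 1), -1), "positive")
})

test_that("inversion is consistent with the phase-type density", {
  mix <- make_erlang_mixture(erlang_mixture_spec(c(0.4, 0.35, 0.25),
                                                 c(0.6, 1.2, 2.4)))
  t <- seq(0.25, 15, length.out = 20)
  inv <- euler_invert(function(s) ph_laplace(mix, s), t)
  expect_lt(max(abs(inv - ph_pdf(mix, t))), 1e-6)
})

test_that("Euler-summation refinement does not degrade the battery error", {
  t <- seq(0.1, 20, length.out = 40)
  e_default <- battery_error(t, m_euler = 11L, n_base = 15L)
  e_more <- battery_error(t, m_euler = 13L, n_base = 25L)
  e_most <- battery_error(t, m_euler = 15L, n_base = 40L)
  # errors sit at the exp(-A) discretization floor; refinement must not
  # leave it
  expect_lte(e_more, e_default + 1e-9)
  expect_lte(e_most, e_more + 1e-9)
})

test_that("survival curve from a density matches closed forms and clips", {
  grid <- seq(0, 10, length.out = 256)
  S <- survival_from_pdf(function(t) dexp(t, 0.7), grid)
  expect_lt(max(abs(S - exp(-0.7 * grid))), 1e-6)
  expect_equal(S[1], 1)
  expect_true(all(diff(S) <= 1e-12))
  # length-1 grid at the origin
  expect_equal(survival_from_pdf(function(t) dexp(t, 1), 0), 1)
  # proper fitted density: negligible mass beyond 50 years
  spec <- erlang_mixture_spec(c(0.3, 0.45, 0.25), c(0.7, 1.8, 2.2))
  S50 <- survival_from_pdf(function(t) euler_invert(
    function(s) em_laplace(spec, s), pmax(t, 1e-8)),
    seq(0, 50, length.out = 512))
  expect_lt(S50[512], 0.02)
})

test_that("hazard curves follow f/S with masking below the floor", {
  t <- seq(0.5, 8, length.out = 30)
  h_exp <- hazard_from_curves(dexp(t, 1.3), exp(-1.3 * t))
  expect_equal(h_exp, rep(1.3, 30), tolerance = 1e-12)
  h_gam <- hazard_from_curves(dgamma(t, 3, rate = 1),
                              pgamma(t, 3, rate = 1, lower.tail = FALSE))
  expect_true(all(diff(h_gam) > 0))  # Erlang(3) hazard increases
  masked <- hazard_from_curves(c(0.1, 0.1), c(0.5, 1e-9))
  expect_true(is.na(masked[2]) && !is.na(masked[1]))
})

test_that("transmittance curve tabulation has the declared schema", {
  spec <- erlang_mixture_spec(c(0.5, 0.3, 0.2), c(0.5, 1.5, 2.5))
  tm <- transmittance(1, function(s) em_laplace(spec, s))
  curve <- transmittance_curves(tm, tmax = 12, n_grid = 128)
  expect_named(curve, c("t_years", "pdf", "survival", "hazard"))
  expect_equal(nrow(curve), 128)
  expect_equal(curve$survival[1], 1)
  expect_lt(max(abs(curve$survival - (1 - em_cdf(spec, curve$t_years)))),
            1e-5)
  f <- tempfile(fileext = ".csv")
  write_curve(curve, f)
  expect_equal(nrow(utils::read.csv(f)), 128)
  unlink(f)
})
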