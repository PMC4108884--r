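#' Numerical Laplace-transform inversion (EULER algorithm)
#'
#' Abate-Whitt EULER inversion of a density transform: the Bromwich integral
#' is discretized by the trapezoidal rule on the vertical line
#' `Re(s) = A / (2t)`, giving a nearly alternating series whose convergence
#' is accelerated by Euler summation with binomial weights over `m_euler`
#' partial sums beyond `n_base` base terms.  The discretization error is of
#' order `exp(-A)`.
#'
#' @param lt evaluable transform: a vectorized function of complex `s`.
#' @param t positive evaluation time(s) (years).
#' @param a_param discretization control `A`; the default 18.4 puts the
#'   discretization error near 1e-8.
#' @param m_euler number of Euler-summation terms.
#' @param n_base number of base partial sums before acceleration.
#' @return real density approximation(s) at `t` (1/years).
#' @export
euler_invert <- function(lt, t, a_param = 18.4, m_euler = 11L,
                         n_base = 15L) {
  if (!is.function(lt)) stop("lt must be a function of s")
  if (any(!is.finite(t)) || any(t <= 0)) stop("t must be strictly positive")
  w <- choose(m_euler, 0:m_euler) / 2^m_euler
  vapply(t, function(ti) {
    k <- 0:(n_base + m_euler)
    s <- (a_param + 2i * pi * k) / (2 * ti)
    vals <- Re(lt(s))
    terms <- c(vals[1] / 2, (-1)^k[-1] * vals[-1])
    psums <- cumsum(terms)[(n_base + 1):(n_base + m_euler + 1)]
    exp(a_param / 2) / ti * sum(w * psums)
  }, numeric(1))
}

#' Survival curve from a density by composite quadrature
#'
#' `S(t) = 1 - integral of f over [0, t]`, computed by composite Simpson
#' quadrature on a 4-fold refinement of `grid`.  `S(0) = 1`; the result is
#' clipped to `[0, 1]` and a warning is logged if it rises by more than
#' `1e-4` anywhere before clipping (a sign of inversion noise).
#'
#' @param density evaluable density function of `t`.
#' @param grid increasing evaluation times starting at or above 0.
#' @return numeric survival values along `grid`.
#' @export
survival_from_pdf <- function(density, grid) {
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (grid[1] < 0) stop("grid must be non-negative")
  n <- length(grid)
  full <- if (grid[1] > 0) c(0, grid) else grid
  S <- numeric(length(full))
  S[1] <- 1
  if (length(full) > 1L) {
    tiny <- 1e-9 * max(full)
    inc <- vapply(seq_len(length(full) - 1L), function(j) {
      a <- full[j]; b <- full[j + 1L]
      x <- seq(a, b, length.out = 5L)
      fx <- density(pmax(x, tiny))
      (b - a) / 12 * sum(c(1, 4, 2, 4, 1) * fx)
    }, numeric(1))
    S[-1] <- 1 - cumsum(inc)
  }
  if (any(diff(S) > 1e-4))
    warning("survival curve rises by more than 1e-4 before clipping")
  S <- pmin(pmax(S, 0), 1)
  if (grid[1] > 0) S[-1] else S
}

#' Hazard curve from density and survival values
#'
#' Pointwise `f / S` where the survival exceeds `s_floor`; values beyond are
#' masked as `NA` rather than returned as unstable ratios.
#'
#' @param density_vals,survival_vals aligned numeric curves.
#' @param s_floor survival threshold below which the hazard is masked.
#' @export
hazard_from_curves <- function(density_vals, survival_vals, s_floor = 1e-6) {
  if (length(density_vals) != length(survival_vals))
    stop("density and survival curves must be aligned")
  h <- density_vals / survival_vals
  h[survival_vals < s_floor] <- NA_real_
  h
}

#' Tabulate density, survival and hazard of a transmittance
#'
#' Inverts the waiting-time transform of `tm` by [euler_invert()] on a
#' uniform grid and derives the survival and hazard curves.
#'
#' @param tm a `"transmittance"` (e.g. from [first_passage_lt()]).
#' @param tmax grid endpoint (years).
#' @param n_grid number of uniform grid points on `[0, tmax]`.
#' @param ... passed on to [euler_invert()].
#' @return data frame with columns `t_years, pdf, survival, hazard`.
#' @export
transmittance_curves <- function(tm, tmax, n_grid = 512L, ...) {
  stopifnot(inherits(tm, "transmittance"))
  if (tmax <= 0) stop("tmax must be positive")
  grid <- seq(0, tmax, length.out = n_grid)
  tiny <- 1e-9 * tmax
  f <- function(t) euler_invert(tm$lt, pmax(t, tiny), ...)
  pdf_vals <- f(grid)
  surv <- survival_from_pdf(f, grid)
  data.frame(t_years = grid, pdf = pdf_vals, survival = surv,
             hazard = hazard_from_curves(pdf_vals, surv))
}

#' Write a survival/hazard curve as CSV
#'
#' Schema: `t_years, pdf, survival, hazard` (hazard may be empty where
#' masked).
#'
#' @param curve data frame as produced by [transmittance_curves()].
#' @param path file path.
#' @export
write_curve <- function(curve, path) {
  need <- c("t_years", "pdf", "survival", "hazard")
  if (!is.data.frame(curve) || !all(need %in% names(curve)))
    stop("curve must have columns ", paste(need, collapse = ", "))
  utils::write.csv(curve[, need], path, row.names = FALSE, na = "")
  invisible(path)
}
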