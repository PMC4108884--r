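#' Non-negative least-squares initialization of mixture weights
#'
#' Solves, by the Lawson-Hanson NNLS algorithm, the stacked linear system
#' `F = p1 F1 + p2 F2 + p3 F3` together with the row `1 = p1 + p2 + p3`,
#' where the `Fi` are Erlang CDFs evaluated at the empirical jump times.
#' The solution is floored at `eps` and renormalized so the returned weights
#' lie on the open simplex.
#'
#' @param emp an `"empirical_cdf"`.
#' @param shapes,rates length-3 Erlang shapes (positive integers) and rates.
#' @param eps weight floor honoring the strict positivity constraint.
#' @return length-3 weight vector, positive, summing to 1.
#' @export
nnls_init <- function(emp, shapes, rates, eps = 1e-6) {
  stopifnot(inherits(emp, "empirical_cdf"))
  if (length(shapes) != 3L || length(rates) != 3L)
    stop("shapes and rates must have length 3")
  if (any(rates <= 0)) stop("rates must be strictly positive")
  if (any(shapes < 1 | shapes %% 1 != 0))
    stop("shapes must be positive integers")
  basis <- vapply(1:3, function(i)
    stats::pgamma(emp$jump_times, shape = shapes[i], rate = rates[i]),
    numeric(length(emp$jump_times)))
  basis <- matrix(basis, ncol = 3)
  for (i in 1:2) for (j in (i + 1):3)
    if (max(abs(basis[, i] - basis[, j])) < 1e-10)
      stop("degenerate design: components ", i, " and ", j,
           " are indistinguishable on this grid")
  A <- rbind(basis, rep(1, 3))
  b <- c(emp$values, 1)
  w <- pracma::lsqnonneg(A, b)$x
  w <- pmax(w, eps)
  w / sum(w)
}

#' Moment-style rate initialization
#'
#' `rate_i = shape_i / t_med` with `t_med` the Kaplan-Meier median of the
#' empirical CDF, falling back to the restricted mean when the median is not
#' reached (plateau below 0.5).
#'
#' @param emp an `"empirical_cdf"`.
#' @param shapes length-3 positive integers.
#' @return length-3 rate vector (1/years).
#' @export
init_rates <- function(emp, shapes) {
  stopifnot(inherits(emp, "empirical_cdf"))
  if (any(shapes < 1 | shapes %% 1 != 0))
    stop("shapes must be positive integers")
  tc <- km_median(emp)
  if (is.na(tc)) tc <- km_restricted_mean(emp)
  if (!is.finite(tc) || tc <= 0)
    stop("cannot derive a positive central time from the empirical CDF")
  shapes / tc
}

# Euclidean-norm discrepancy between the empirical CDF and the mixture CDF,
# evaluated on the empirical jump times (the step function's support).
fit_objective <- function(emp, spec) {
  sqrt(sum((emp$values - em_cdf(spec, emp$jump_times))^2))
}

#' Fit an Erlang mixture to an empirical CDF
#'
#' Minimizes the Euclidean norm of `F_hat(t_k) - G(t_k)` over the empirical
#' jump times, subject to positive weights summing to one and positive rates.
#' The constraints are enforced by reparameterization (softmax over the
#' weights, log over the rates) so every iterate is feasible; the returned
#' spec is guaranteed feasible with objective no worse than at `init`.
#'
#' @param emp an `"empirical_cdf"`.
#' @param shapes length-3 positive integer shape triple.
#' @param init a valid `"erlang_mixture_spec"` starting point (its shapes
#'   must equal `shapes`).
#' @param maxit iteration cap passed to the optimizer.
#' @return an object of class `"mixture_fit"`: fields `spec`, `objective`,
#'   `init_objective`, `converged`, `n_grid`, `plateau`, `plateau_flag`
#'   (defective empirical plateau below 0.9, where a proper fitted CDF must
#'   overshoot the tail).
#' @export
fit_mixture <- function(emp, shapes, init, maxit = 500L) {
  stopifnot(inherits(emp, "empirical_cdf"),
            inherits(init, "erlang_mixture_spec"))
  if (!identical(as.integer(shapes), init$shapes))
    stop("init shapes must match the requested shape triple")
  init <- erlang_mixture_spec(init$weights, init$rates, init$shapes)
  theta0 <- c(log(init$weights[1] / init$weights[3]),
              log(init$weights[2] / init$weights[3]),
              log(init$rates))
  to_spec <- function(theta) {
    w <- exp(c(theta[1], theta[2], 0) - max(theta[1], theta[2], 0))
    w <- pmax(w / sum(w), 1e-6)
    erlang_mixture_spec(w / sum(w), exp(theta[3:5]), shapes)
  }
  fn <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 50)) return(1e10)
    fit_objective(emp, to_spec(theta))
  }
  opt <- stats::optim(theta0, fn, method = "BFGS",
                      control = list(maxit = maxit))
  init_obj <- fit_objective(emp, init)
  cand <- to_spec(opt$par)
  cand_obj <- fit_objective(emp, cand)
  if (cand_obj <= init_obj) {
    spec <- cand; obj <- cand_obj
  } else {
    spec <- init; obj <- init_obj
  }
  structure(list(spec = spec, objective = obj, init_objective = init_obj,
                 converged = opt$convergence == 0,
                 n_grid = length(emp$jump_times), plateau = emp$plateau,
                 plateau_flag = emp$plateau < 0.9),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Erlang-mixture fit on", x$n_grid, "grid points\n")
  print(x$spec)
  cat("  objective:", format(x$objective, digits = 5),
      "(start", format(x$init_objective, digits = 5), ")",
      if (x$converged) "converged" else "NOT converged", "\n")
  if (x$plateau_flag)
    cat("  note: defective empirical plateau",
        format(x$plateau, digits = 3), "- proper CDF overshoots the tail\n")
  invisible(x)
}

#' Multi-start mixture fit for one transition
#'
#' Runs [fit_mixture()] from NNLS-initialized starts over a small
#' deterministic grid of multiplicative rate perturbations around the
#' moment-style rates of [init_rates()]; the best final objective wins
#' (ties resolved to the first start).
#'
#' @param emp an `"empirical_cdf"`.
#' @param shapes length-3 shape triple, default `c(1, 3, 5)`.
#' @param restart_factors multiplicative perturbations of the base rates.
#' @return a `"mixture_fit"`.
#' @export
fit_transition <- function(emp, shapes = c(1, 3, 5),
                           restart_factors = c(1, 0.6, 0.8, 1.25, 1.6)) {
  base <- init_rates(emp, shapes)
  best <- NULL
  for (f in restart_factors) {
    rates <- base * f
    w <- tryCatch(nnls_init(emp, shapes, rates), error = function(e) NULL)
    if (is.null(w)) next
    fit <- fit_mixture(emp, shapes, erlang_mixture_spec(w, rates, shapes))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("all mixture-fit starts failed")
  best
}

#' Write a per-transition fit report
#'
#' @param fit a `"mixture_fit"`.
#' @param path JSON file path.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "mixture_fit"))
  jsonlite::write_json(
    list(shapes = fit$spec$shapes, weights = fit$spec$weights,
         rates = fit$spec$rates, objective = fit$objective,
         init_objective = fit$init_objective, grid_size = fit$n_grid,
         converged = fit$converged, plateau = fit$plateau,
         plateau_flag = fit$plateau_flag),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
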