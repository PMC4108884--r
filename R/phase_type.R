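#' Construct a phase-type representation
#'
#' A phase-type distribution is the law of the time to absorption of a finite
#' continuous-time Markov chain with `m` transient states, sub-generator `T`
#' and initial distribution `(alpha, alpha_abs)`, where `alpha_abs` is the
#' probability of starting in the absorbing state (an atom at zero).  The exit
#' rate vector is `T0 = -T e` with `e` the all-ones vector.
#'
#' Validation happens here once; all `ph_*` operations assume a valid object.
#'
#' @param alpha numeric row vector of initial probabilities over the `m`
#'   transient states (dimensionless).
#' @param T m-by-m sub-generator matrix (rates in 1/years): strictly negative
#'   diagonal, non-negative off-diagonal, non-singular.
#' @param alpha_abs initial absorption probability (atom at `t = 0`).
#' @return an object of class `"phase_type"` with fields `alpha`, `alpha_abs`,
#'   `T`, `T0` and `m`.
#' @examples
#' ph <- new_phase_type(c(1, 0), rbind(c(-2, 2), c(0, -2)))
#' ph_cdf(ph, 1.5)  # Erlang(2, 2) CDF
#' @export
new_phase_type <- function(alpha, T, alpha_abs = 0) {
  alpha <- as.numeric(alpha)
  T <- as.matrix(T)
  m <- length(alpha)
  if (m < 1L) stop("alpha must have at least one entry")
  if (!is.numeric(T) || nrow(T) != m || ncol(T) != m)
    stop("T must be a numeric ", m, "x", m, " matrix matching length(alpha)")
  if (any(!is.finite(alpha)) || any(!is.finite(T)))
    stop("alpha and T must be finite")
  if (any(diag(T) >= 0))
    stop("diagonal entries of T must be strictly negative")
  off <- T; diag(off) <- 0
  if (any(off < -1e-12))
    stop("off-diagonal entries of T must be non-negative")
  if (any(alpha < -1e-12))
    stop("entries of alpha must be non-negative")
  alpha <- pmax(alpha, 0)
  if (!is.numeric(alpha_abs) || length(alpha_abs) != 1L || alpha_abs < 0)
    stop("alpha_abs must be a single non-negative number")
  if (abs(sum(alpha) + alpha_abs - 1) > 1e-8)
    stop("sum(alpha) + alpha_abs must equal 1")
  T0 <- -as.numeric(T %*% rep(1, m))
  if (any(T0 < -1e-10))
    stop("row sums of T must be non-positive (-T e >= 0 required)")
  T0 <- pmax(T0, 0)
  if (qr(T)$rank < m) stop("T must be non-singular")
  structure(list(alpha = alpha, alpha_abs = alpha_abs, T = T, T0 = T0, m = m),
            class = "phase_type")
}

#' @export
print.phase_type <- function(x, ...) {
  cat("Phase-type representation with", x$m, "transient states\n")
  cat("alpha:", format(x$alpha, digits = 5), "\n")
  if (x$alpha_abs > 0) cat("alpha_abs:", format(x$alpha_abs, digits = 5), "\n")
  invisible(x)
}

# exp(T t) via Matrix::expm (Higham scaling-and-squaring); T may be defective
# (Erlang blocks are), so no eigendecomposition.
ph_expm <- function(T, t) {
  as.matrix(Matrix::expm(Matrix::Matrix(T * t)))
}

check_times <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) stop("t must be finite numeric")
  if (any(t < 0)) stop("t must be non-negative")
  t
}

#' Phase-type distribution function
#'
#' `F(t) = 1 - alpha exp(T t) e`, right-continuous with `F(0) = alpha_abs`.
#'
#' @param ph a `"phase_type"` object.
#' @param t non-negative times (years); vectorized.
#' @return probabilities in `[0, 1]`.
#' @export
ph_cdf <- function(ph, t) {
  check_times(t)
  e <- rep(1, ph$m)
  vapply(t, function(ti)
    min(max(1 - drop(ph$alpha %*% ph_expm(ph$T, ti) %*% e), 0), 1),
    numeric(1))
}

#' Phase-type survival function
#'
#' `S(t) = alpha exp(T t) e` (so `S(0) = 1 - alpha_abs`).
#'
#' @inheritParams ph_cdf
#' @export
ph_survival <- function(ph, t) {
  check_times(t)
  e <- rep(1, ph$m)
  vapply(t, function(ti)
    min(max(drop(ph$alpha %*% ph_expm(ph$T, ti) %*% e), 0), 1),
    numeric(1))
}

#' Phase-type density
#'
#' `f(t) = alpha exp(T t) T0` (1/years); integrates to `1 - alpha_abs`.
#'
#' @inheritParams ph_cdf
#' @export
ph_pdf <- function(ph, t) {
  check_times(t)
  vapply(t, function(ti)
    max(drop(ph$alpha %*% ph_expm(ph$T, ti) %*% ph$T0), 0),
    numeric(1))
}

#' Phase-type hazard function
#'
#' Ratio `f(t) / S(t)`.  Errors (rather than returning NaN) once the survival
#' has underflowed to the point the ratio is meaningless.
#'
#' @inheritParams ph_cdf
#' @param s_min underflow threshold on the survival function.
#' @export
ph_hazard <- function(ph, t, s_min = 1e-300) {
  check_times(t)
  S <- ph_survival(ph, t)
  if (any(S < s_min))
    stop("survival function underflow: hazard undefined at t = ",
         paste(t[S < s_min], collapse = ", "))
  ph_pdf(ph, t) / S
}

#' Phase-type Laplace transform
#'
#' `L(s) = alpha_abs + alpha (sI - T)^{-1} T0`, evaluated by solving the
#' linear system (no explicit inverse).  Accepts complex `s` with
#' `Re(s) >= 0`; `L(0) = 1` for a proper distribution.
#'
#' @param ph a `"phase_type"` object.
#' @param s numeric or complex argument(s) with non-negative real part.
#' @return numeric (for real `s`) or complex values.
#' @export
ph_laplace <- function(ph, s) {
  if (any(Re(s) < 0)) stop("Re(s) must be non-negative")
  I <- diag(ph$m)
  one <- function(si) {
    x <- tryCatch(solve(si * I - ph$T, ph$T0),
                  error = function(e) stop("singular system at s = ", si,
                                           call. = FALSE))
    ph$alpha_abs + drop(ph$alpha %*% x)
  }
  out <- vapply(s, one, if (is.complex(s)) complex(1) else numeric(1))
  out
}

#' Erlang distribution as a phase-type representation
#'
#' The Erlang distribution E\[r, rate\] (sum of `r` i.i.d. exponentials) is the
#' chain of `r` sequential states: `alpha = (1, 0, ..., 0)` and a bidiagonal
#' sub-generator with `-rate` on the diagonal and `+rate` above it.
#'
#' @param shape positive integer `r`.
#' @param rate positive rate (1/years).
#' @export
make_erlang <- function(shape, rate) {
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) ||
      shape < 1 || shape %% 1 != 0)
    stop("shape must be a positive integer")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("rate must be a positive number")
  r <- as.integer(shape)
  T <- diag(-rate, r)
  if (r > 1L) T[cbind(seq_len(r - 1L), seq_len(r - 1L) + 1L)] <- rate
  new_phase_type(c(1, rep(0, r - 1L)), T)
}

#' Specify a three-component Erlang mixture
#'
#' The mixture CDF is `G(t) = p1 F1(t) + p2 F2(t) + p3 F3(t)` with `Fi` the
#' CDF of Erlang E\[r_i, mu_i\], weights on the open simplex.
#'
#' @param weights length-3 vector of positive mixing weights summing to 1.
#' @param rates length-3 vector of positive rates (1/years).
#' @param shapes length-3 vector of positive integers (default `c(1, 3, 5)`).
#' @return an object of class `"erlang_mixture_spec"`.
#' @export
erlang_mixture_spec <- function(weights, rates, shapes = c(1, 3, 5)) {
  weights <- as.numeric(weights); rates <- as.numeric(rates)
  shapes <- as.numeric(shapes)
  if (length(weights) != 3L || length(rates) != 3L || length(shapes) != 3L)
    stop("weights, rates and shapes must each have length 3")
  if (any(!is.finite(c(weights, rates, shapes))))
    stop("weights, rates and shapes must be finite")
  if (any(weights <= 0)) stop("mixture weights must be strictly positive")
  if (abs(sum(weights) - 1) > 1e-6) stop("mixture weights must sum to 1")
  if (any(rates <= 0)) stop("rates must be strictly positive")
  if (any(shapes < 1 | shapes %% 1 != 0))
    stop("shapes must be positive integers")
  structure(list(weights = weights / sum(weights), rates = rates,
                 shapes = as.integer(shapes)),
            class = "erlang_mixture_spec")
}

#' @export
print.erlang_mixture_spec <- function(x, ...) {
  cat("Erlang mixture: shapes (", paste(x$shapes, collapse = ", "), ")\n",
      sep = "")
  cat("  weights:", format(x$weights, digits = 5), "\n")
  cat("  rates:  ", format(x$rates, digits = 5), "/yr\n")
  invisible(x)
}

#' Phase-type representation of an Erlang mixture
#'
#' Block-diagonal sub-generator of order `r1 + r2 + r3` with one Erlang chain
#' per component; `alpha` places the weight `p_i` on the first state of each
#' block.  For shapes `(1, 3, 5)` this is the canonical 9-state form.
#'
#' @param spec an `"erlang_mixture_spec"`.
#' @export
make_erlang_mixture <- function(spec) {
  stopifnot(inherits(spec, "erlang_mixture_spec"))
  r <- spec$shapes
  m <- sum(r)
  T <- matrix(0, m, m)
  alpha <- numeric(m)
  pos <- 1L
  for (i in 1:3) {
    idx <- pos:(pos + r[i] - 1L)
    blk <- diag(-spec$rates[i], r[i])
    if (r[i] > 1L)
      blk[cbind(seq_len(r[i] - 1L), seq_len(r[i] - 1L) + 1L)] <- spec$rates[i]
    T[idx, idx] <- blk
    alpha[pos] <- spec$weights[i]
    pos <- pos + r[i]
  }
  new_phase_type(alpha, T)
}

#' Erlang-mixture CDF, density and Laplace transform in closed form
#'
#' Direct evaluation through the gamma distribution with integer shape;
#' algebraically identical to the phase-type route but cheap enough for
#' optimization loops and vectorized transform inversion.
#'
#' @param spec an `"erlang_mixture_spec"`.
#' @param t non-negative times (years).
#' @return `em_cdf`/`em_pdf`: numeric vector along `t`.
#' @export
em_cdf <- function(spec, t) {
  check_times(t)
  out <- 0
  for (i in 1:3)
    out <- out + spec$weights[i] *
      stats::pgamma(t, shape = spec$shapes[i], rate = spec$rates[i])
  out
}

#' @rdname em_cdf
#' @export
em_pdf <- function(spec, t) {
  check_times(t)
  out <- 0
  for (i in 1:3)
    out <- out + spec$weights[i] *
      stats::dgamma(t, shape = spec$shapes[i], rate = spec$rates[i])
  out
}

#' @rdname em_cdf
#' @param s numeric or complex Laplace argument(s), `Re(s) >= 0`.
#' @export
em_laplace <- function(spec, s) {
  if (any(Re(s) < 0)) stop("Re(s) must be non-negative")
  out <- 0
  for (i in 1:3)
    out <- out + spec$weights[i] *
      (spec$rates[i] / (s + spec$rates[i]))^spec$shapes[i]
  out
}

#' Serialize a mixture spec or phase-type representation to JSON
#'
#' Plain-text round trip, exact on decimal literals.
#'
#' @param x an `"erlang_mixture_spec"` or `"phase_type"` object.
#' @param path file path to write to.
#' @export
write_spec_json <- function(x, path) {
  if (inherits(x, "erlang_mixture_spec")) {
    obj <- list(type = "erlang_mixture_spec", weights = x$weights,
                rates = x$rates, shapes = x$shapes)
  } else if (inherits(x, "phase_type")) {
    obj <- list(type = "phase_type", alpha = x$alpha,
                alpha_abs = x$alpha_abs, T = apply(x$T, 1, identity,
                                                   simplify = FALSE))
  } else stop("unsupported object for serialization")
  # I(17) significant digits: exact binary round trip for doubles
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_spec_json
#' @export
read_spec_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(obj$type,
    erlang_mixture_spec = erlang_mixture_spec(obj$weights, obj$rates,
                                              obj$shapes),
    phase_type = {
      T <- if (is.matrix(obj$T)) obj$T
           else do.call(rbind, lapply(obj$T, as.numeric))
      new_phase_type(obj$alpha, T, obj$alpha_abs)
    },
    stop("unknown serialized type: ", obj$type))
}
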