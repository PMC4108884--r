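#' Construct a branch transmittance
#'
#' A flowgraph branch label: the transition probability `p` paired with the
#' Laplace transform of the branch waiting-time density (an evaluable,
#' vectorized function of complex `s` with `lt(0) = 1`).
#'
#' @param p transition probability in `(0, 1]`.
#' @param lt function of (complex) `s` returning the Laplace transform.
#' @return an object of class `"transmittance"`.
#' @export
transmittance <- function(p, lt) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 1)
    stop("p must be a probability in (0, 1]")
  if (!is.function(lt)) stop("lt must be a function of s")
  l0 <- lt(0)
  if (abs(l0 - 1) > 1e-8)
    stop("lt(0) must equal 1 (proper waiting-time transform); got ",
         format(Re(l0)))
  structure(list(p = p, lt = lt), class = "transmittance")
}

#' Combine transmittances in series
#'
#' Two branches traversed one after the other: probabilities multiply and
#' transforms multiply (the waiting times convolve).
#'
#' @param a,b `"transmittance"` objects.
#' @export
tm_series <- function(a, b) {
  stopifnot(inherits(a, "transmittance"), inherits(b, "transmittance"))
  transmittance(a$p * b$p, function(s) a$lt(s) * b$lt(s))
}

#' Combine transmittances in parallel
#'
#' Two alternative branches out of the same state: the unnormalized
#' transmittances add, carried as total probability `a.p + b.p` with the
#' probability-weighted mixture transform.
#'
#' @param a,b `"transmittance"` objects with `a.p + b.p <= 1`.
#' @export
tm_parallel <- function(a, b) {
  stopifnot(inherits(a, "transmittance"), inherits(b, "transmittance"))
  ptot <- a$p + b$p
  if (ptot > 1 + 1e-12)
    stop("parallel transmittance probabilities sum to ", format(ptot),
         " > 1")
  transmittance(min(ptot, 1),
                function(s) (a$p * a$lt(s) + b$p * b$lt(s)) / ptot)
}

#' Three-state illness-death flowgraph
#'
#' States: 0 = disease-free (post-TUR), 1 = first recurrence,
#' 2 = progression; branches exactly `(0,1)`, `(0,2)`, `(1,2)`.
#'
#' @param t01,t02,t12 `"transmittance"` objects for the three branches.
#' @return an object of class `"flowgraph_model"`.
#' @export
flowgraph_model <- function(t01, t02, t12) {
  stopifnot(inherits(t01, "transmittance"), inherits(t02, "transmittance"),
            inherits(t12, "transmittance"))
  if (t01$p + t02$p > 1 + 1e-12)
    stop("branch probabilities out of state 0 sum to more than 1")
  structure(list(states = c(`0` = "disease-free", `1` = "recurrence",
                            `2` = "progression"),
                 branches = list(`01` = t01, `02` = t02, `12` = t12)),
            class = "flowgraph_model")
}

#' First-passage Laplace transform on the illness-death flowgraph
#'
#' Series/parallel reduction of the two source-to-target paths
#' (0-1-2 and 0-2) gives the unnormalized transform
#' `p01 p12 LT01(s) LT12(s) + p02 LT02(s)`.  Because passage is not certain
#' (a patient may never progress), dividing by the total path probability
#' `p01 p12 + p02` yields the proper first-passage waiting-time transform
#' conditional on eventual passage.
#'
#' @param model a `"flowgraph_model"`.
#' @param source,target states; this release supports `(0, 2)` only.
#' @param normalize divide by the total path probability (default).  With
#'   `normalize = FALSE` a plain list `(p, lt)` holding the unnormalized
#'   transform is returned for further composition.
#' @return a `"transmittance"` whose carried `p` is the overall passage
#'   probability `p01 p12 + p02`.
#' @export
first_passage_lt <- function(model, source = 0, target = 2,
                             normalize = TRUE) {
  stopifnot(inherits(model, "flowgraph_model"))
  if (source != 0 || target != 2)
    stop("only the (0, 2) first passage is supported on this graph")
  t01 <- model$branches[["01"]]; t02 <- model$branches[["02"]]
  t12 <- model$branches[["12"]]
  p_via <- t01$p * t12$p
  p_dir <- t02$p
  ptot <- p_via + p_dir
  if (ptot <= 0) stop("zero total path probability from 0 to 2")
  lt_un <- function(s) p_via * t01$lt(s) * t12$lt(s) + p_dir * t02$lt(s)
  if (!normalize) return(list(p = ptot, lt = lt_un))
  transmittance(ptot, function(s) lt_un(s) / ptot)
}

#' Estimate branch transition probabilities from a cohort
#'
#' Ratios of observed transitions to the number of patients at risk of the
#' transition: `p01` and `p02` over patients ever observed in state 0, `p12`
#' over patients observed in state 1.  The analysis accepts user-supplied
#' overrides in place of these ratios.
#'
#' @param cohort a cohort data frame (see [read_cohort()]).
#' @return named vector `c(p01, p02, p12)`.
#' @export
estimate_transition_probs <- function(cohort) {
  check_cohort(cohort)
  at0 <- unique(cohort$id[cohort$origin == 0])
  at1 <- unique(cohort$id[cohort$origin == 1])
  if (length(at0) == 0L) stop("no patients at risk in state 0")
  if (length(at1) == 0L) stop("no patients at risk in state 1")
  ev <- cohort$status == "event" & !is.na(cohort$dest)
  n01 <- sum(ev & cohort$origin == 0 & cohort$dest == 1)
  n02 <- sum(ev & cohort$origin == 0 & cohort$dest == 2)
  n12 <- sum(ev & cohort$origin == 1 & cohort$dest == 2)
  c(p01 = n01 / length(at0), p02 = n02 / length(at0),
    p12 = n12 / length(at1))
}

# Convolution of two phase-type laws: the first chain's exit feeds the
# second chain's initial distribution.
ph_convolve <- function(ph1, ph2) {
  m1 <- ph1$m; m2 <- ph2$m
  T <- matrix(0, m1 + m2, m1 + m2)
  T[1:m1, 1:m1] <- ph1$T
  T[1:m1, (m1 + 1):(m1 + m2)] <- outer(ph1$T0, ph2$alpha)
  T[(m1 + 1):(m1 + m2), (m1 + 1):(m1 + m2)] <- ph2$T
  alpha <- c(ph1$alpha, ph1$alpha_abs * ph2$alpha)
  new_phase_type(alpha, T, ph1$alpha_abs * ph2$alpha_abs)
}

#' Explicit phase-type form of the 0-to-2 first-passage law
#'
#' The conditional first-passage distribution on the illness-death graph is
#' itself phase-type: a two-component mixture of (i) the convolution of the
#' 0-1 and 1-2 sojourn laws, with weight `p01 p12 / (p01 p12 + p02)`, and
#' (ii) the direct 0-2 sojourn law with the complementary weight.  Used as an
#' analytic reference for curves obtained by transform inversion.
#'
#' @param s01,s12,s02 `"erlang_mixture_spec"` sojourn laws per branch.
#' @param p01,p02,p12 branch transition probabilities.
#' @return a `"phase_type"` object.
#' @export
first_passage_phase_type <- function(s01, s12, s02, p01, p02, p12) {
  ptot <- p01 * p12 + p02
  if (ptot <= 0) stop("zero total path probability from 0 to 2")
  w_via <- p01 * p12 / ptot
  ph_via <- ph_convolve(make_erlang_mixture(s01), make_erlang_mixture(s12))
  ph_dir <- make_erlang_mixture(s02)
  m1 <- ph_via$m; m2 <- ph_dir$m
  T <- matrix(0, m1 + m2, m1 + m2)
  T[1:m1, 1:m1] <- ph_via$T
  T[(m1 + 1):(m1 + m2), (m1 + 1):(m1 + m2)] <- ph_dir$T
  new_phase_type(c(w_via * ph_via$alpha, (1 - w_via) * ph_dir$alpha), T)
}
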