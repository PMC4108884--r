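#' Intensity matrix of the homogeneous illness-death Markov model
#'
#' 3x3 generator with free intensities `q01, q02, q12` (1/years), absorbing
#' progression state, rows summing to zero.
#'
#' @param q01,q02,q12 non-negative transition intensities.
#' @return an object of class `"intensity_matrix"` (a plain 3x3 matrix).
#' @export
intensity_matrix <- function(q01, q02, q12) {
  q <- c(q01, q02, q12)
  if (any(!is.finite(q)) || any(q < 0))
    stop("intensities must be finite and non-negative")
  Q <- rbind(c(-(q01 + q02), q01, q02),
             c(0, -q12, q12),
             c(0, 0, 0))
  dimnames(Q) <- list(0:2, 0:2)
  structure(Q, class = c("intensity_matrix", "matrix"))
}

#' Occurrence/exposure estimate of the intensity matrix
#'
#' `q_ij` = (number of observed i-to-j transitions) / (total time at risk in
#' state i) - the maximum-likelihood estimator for a homogeneous
#' continuous-time Markov chain under exactly observed transition times.
#' Censored sojourns contribute exposure but no occurrence.
#'
#' @param cohort a cohort data frame (see [read_cohort()]).
#' @return an `"intensity_matrix"`.
#' @export
estimate_intensities <- function(cohort) {
  check_cohort(cohort)
  if (nrow(cohort) == 0L) stop("empty cohort")
  expo <- function(i) sum(cohort$duration_years[cohort$origin == i])
  occ <- function(i, j) sum(cohort$origin == i & !is.na(cohort$dest) &
                              cohort$dest == j & cohort$status == "event")
  q <- function(i, j) {
    e <- expo(i); n <- occ(i, j)
    if (e <= 0) {
      if (n > 0) stop("observed ", i, "->", j,
                      " transitions with zero exposure in state ", i)
      return(0)
    }
    n / e
  }
  intensity_matrix(q(0, 1), q(0, 2), q(1, 2))
}

#' First-passage survival of the Markov baseline
#'
#' Probability of not yet having reached progression (state 2) by time `t`,
#' starting disease-free: the row-0 transient mass of `exp(Q_sub t)` with
#' `Q_sub` the 2x2 sub-generator on states `{0, 1}` - i.e. the phase-type
#' survival with `alpha = (1, 0)`, `T = Q_sub`.  This is the unconditional
#' non-absorption probability (absorption is certain in this chain, so no
#' conditioning is needed).
#'
#' @param Q an `"intensity_matrix"`.
#' @param grid non-negative evaluation times (years).
#' @return numeric survival values along `grid`.
#' @export
markov_first_passage_survival <- function(Q, grid) {
  stopifnot(inherits(Q, "intensity_matrix"))
  Qsub <- unclass(Q)[1:2, 1:2]
  if (any(diag(Qsub) >= 0))
    stop("degenerate generator: a transient state has zero total intensity")
  ph <- new_phase_type(c(1, 0), Qsub)
  ph_survival(ph, grid)
}
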