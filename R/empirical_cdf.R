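#' Construct a right-censored sample of waiting times
#'
#' @param times non-negative durations (years).
#' @param events indicators, 1 = transition observed, 0 = right-censored.
#' @return an object of class `"censored_sample"`.
#' @export
censored_sample <- function(times, events) {
  times <- as.numeric(times); events <- as.numeric(events)
  if (length(times) != length(events))
    stop("times and events must have the same length")
  if (length(times) == 0L) stop("empty sample")
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and non-negative")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  structure(list(times = times, events = as.integer(events)),
            class = "censored_sample")
}

#' Construct an empirical CDF step function
#'
#' Right-continuous step function with value `values[k]` on
#' `[jump_times[k], jump_times[k+1])` and 0 before the first jump.  The final
#' value (`plateau`) may be below 1 when the largest observation is censored;
#' it is kept as-is (no renormalization).
#'
#' @param jump_times strictly increasing jump locations (years).
#' @param values non-decreasing values in `[0, 1]` attained at/after each jump.
#' @param n number of observations behind the estimate (metadata).
#' @param tmax largest observed time (censored or not); defaults to the last
#'   jump.
#' @return an object of class `"empirical_cdf"`.
#' @export
empirical_cdf <- function(jump_times, values, n = length(jump_times),
                          tmax = NULL) {
  jump_times <- as.numeric(jump_times); values <- as.numeric(values)
  if (length(jump_times) == 0L) stop("empirical CDF must have at least one jump")
  if (length(jump_times) != length(values))
    stop("jump_times and values must have the same length")
  if (any(diff(jump_times) <= 0)) stop("jump_times must be strictly increasing")
  if (any(diff(values) < -1e-12)) stop("values must be non-decreasing")
  if (any(values < -1e-12) || any(values > 1 + 1e-12))
    stop("values must lie in [0, 1]")
  values <- pmin(pmax(values, 0), 1)
  if (is.null(tmax)) tmax <- jump_times[length(jump_times)]
  structure(list(jump_times = jump_times, values = values,
                 plateau = values[length(values)], n = n, tmax = tmax),
            class = "empirical_cdf")
}

#' @export
print.empirical_cdf <- function(x, ...) {
  cat("Empirical CDF:", length(x$jump_times), "jumps, plateau",
      format(x$plateau, digits = 4), "(n =", x$n, ")\n")
  invisible(x)
}

#' Evaluate an empirical CDF
#'
#' @param emp an `"empirical_cdf"`.
#' @param t evaluation times.
#' @export
eval_cdf <- function(emp, t) {
  stats::stepfun(emp$jump_times, c(0, emp$values), right = FALSE)(t)
}

#' Kaplan-Meier estimate of a waiting-time CDF
#'
#' Product-limit estimator of the survival function, returned as the
#' empirical distribution function `F(t) = 1 - S_KM(t)`.  Ties between an
#' event and a censoring at the same time are resolved events-first (the
#' product-limit convention).
#'
#' @param sample a `"censored_sample"`; must contain at least one event.
#' @return an `"empirical_cdf"`.
#' @export
km_cdf <- function(sample) {
  stopifnot(inherits(sample, "censored_sample"))
  if (sum(sample$events) == 0L)
    stop("all observations are censored: no estimable distribution")
  fit <- survival::survfit(
    survival::Surv(sample$times, sample$events) ~ 1, se.fit = FALSE)
  keep <- fit$n.event > 0
  empirical_cdf(fit$time[keep], 1 - fit$surv[keep],
                n = length(sample$times), tmax = max(sample$times))
}

#' Kaplan-Meier median and restricted mean of an empirical CDF
#'
#' The median is the smallest jump time with `F >= 0.5`, `NA` when the
#' plateau stays below 0.5.  The restricted mean integrates the step survival
#' function over `[0, tmax]`.
#'
#' @param emp an `"empirical_cdf"`.
#' @export
km_median <- function(emp) {
  i <- which(emp$values >= 0.5)
  if (length(i) == 0L) return(NA_real_)
  emp$jump_times[i[1]]
}

#' @rdname km_median
#' @export
km_restricted_mean <- function(emp) {
  tt <- c(0, emp$jump_times, emp$tmax)
  S <- c(1, 1 - emp$values)           # survival on each interval [tt_k, tt_k+1)
  sum(S * pmax(diff(tt), 0))
}

#' Extract the censored waiting-time sample of one transition
#'
#' For every patient observed at risk in `origin`, the sojourn duration until
#' `dest` counts as an event; exit by any other cause (a competing transition
#' or end of follow-up) censors the waiting time at the same duration
#' (cause-specific censoring).  The sojourn clock resets on state entry.
#'
#' @param cohort a cohort data frame (see [read_cohort()]).
#' @param origin,dest state labels in `{0, 1, 2}`.
#' @param competing handling of competing exits; `"censor"` (the
#'   latent-failure-time reading: the resulting estimates are conditional-law
#'   estimates under an independence assumption) is the only implemented
#'   policy and the documented extension point.
#' @return a `"censored_sample"`.
#' @export
extract_transition_samples <- function(cohort, origin, dest,
                                       competing = "censor") {
  competing <- match.arg(competing)
  check_cohort(cohort)
  if (!origin %in% 0:2 || !dest %in% 0:2 || origin == dest)
    stop("origin and dest must be distinct states in {0, 1, 2}")
  rows <- cohort[cohort$origin == origin, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("cohort contains no sojourns in state ", origin)
  ev <- as.integer(!is.na(rows$dest) & rows$dest == dest &
                     rows$status == "event")
  censored_sample(rows$duration_years, ev)
}

check_cohort <- function(cohort) {
  need <- c("id", "origin", "dest", "duration_years", "status")
  if (!is.data.frame(cohort) || !all(need %in% names(cohort)))
    stop("cohort must be a data frame with columns ",
         paste(need, collapse = ", "))
  if (!all(cohort$origin %in% 0:2))
    stop("unknown origin state labels (expected 0, 1, 2)")
  if (!all(is.na(cohort$dest) | cohort$dest %in% 0:2))
    stop("unknown destination state labels (expected 0, 1, 2 or NA)")
  if (!all(cohort$status %in% c("event", "censored")))
    stop("status must be 'event' or 'censored'")
  if (any(cohort$duration_years < 0)) stop("durations must be non-negative")
  invisible(cohort)
}

#' Read / write a multistate cohort table
#'
#' CSV schema: `id, origin, dest, duration_years, status` with
#' `status` in `{event, censored}`, `dest` empty on censored rows, and
#' durations in decimal years (sojourn clock, reset on state entry).
#'
#' @param path file path.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        colClasses = c(origin = "integer",
                                       duration_years = "numeric",
                                       status = "character"))
  df$dest <- suppressWarnings(as.integer(df$dest))
  check_cohort(df)
  df
}

#' @rdname read_cohort
#' @param cohort cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
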