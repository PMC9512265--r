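# Parameter estimation from behavioural observations.

#' Behavioural count summary for parameter estimation
#'
#' @param fighting_events_per_individual per-individual counts of fighting
#'   interactions (DOM or SUB rows) over the observation time.
#' @param observation_time_h total observation time, hours (> 0).
#' @param census_N number of insects in the night-time population census.
#' @param queen_interactions_total number of observed interactions involving a
#'   queen.
#' @param queen_subdominant number of those in which the queen was
#'   subdominant (<= total).
#' @return A validated list of class `"behavior_counts"`.
#' @export
behavior_counts <- function(fighting_events_per_individual,
                            observation_time_h, census_N,
                            queen_interactions_total = 0L,
                            queen_subdominant = 0L) {
  if (observation_time_h <= 0)
    stop("'observation_time_h' must be > 0", call. = FALSE)
  if (census_N < 1) stop("'census_N' must be >= 1", call. = FALSE)
  if (any(fighting_events_per_individual < 0))
    stop("event counts must be >= 0", call. = FALSE)
  if (queen_subdominant > queen_interactions_total)
    stop("queen_subdominant cannot exceed queen_interactions_total",
         call. = FALSE)
  structure(list(
    fighting_events_per_individual = fighting_events_per_individual,
    observation_time_h = observation_time_h,
    census_N = as.integer(census_N),
    queen_interactions_total = as.integer(queen_interactions_total),
    queen_subdominant = as.integer(queen_subdominant)),
    class = "behavior_counts")
}

#' Estimate the per-capita fighting interaction rate
#'
#' Total fighting interactions divided by census size and observation time,
#' reported per day, with the standard error of the mean across individuals.
#'
#' @param counts a [behavior_counts()] record.
#' @return A list: `rate_per_day`, `sem` (SEM of the per-individual daily
#'   rates), `n` individuals.
#' @examples
#' estimate_interaction_rate(
#'   behavior_counts(rep(74 / 20, 20), observation_time_h = 24, census_N = 20))
#' @export
estimate_interaction_rate <- function(counts) {
  stopifnot(inherits(counts, "behavior_counts"))
  days <- counts$observation_time_h / 24
  per_ind <- counts$fighting_events_per_individual / days
  # include censused insects without any recorded event
  n_extra <- counts$census_N - length(per_ind)
  if (n_extra > 0) per_ind <- c(per_ind, rep(0, n_extra))
  rate <- sum(per_ind) / counts$census_N
  sem <- if (length(per_ind) > 1) stats::sd(per_ind) / sqrt(length(per_ind))
         else 0
  list(rate_per_day = rate, sem = sem, n = length(per_ind))
}

#' Estimate the dominance error rate from queen interaction outcomes
#'
#' Rate at which a queen nevertheless ends up subdominant in an interaction.
#' With `k` observed queen-subdominant outcomes out of `n` queen interactions
#' the point estimate is the observed frequency `k/n`; when no error was
#' observed (`k = 0`) a single pseudo-observation is added, `(k + 1) / n`, so
#' that the estimate stays positive and usable as a bound (0 of 17 queen
#' interactions gives 1/17).
#'
#' @param queen_subdominant number of interactions with the queen subdominant.
#' @param queen_interactions total interactions involving queens (>= 1).
#' @return Point estimate in (0, 1].
#' @export
estimate_error_rate <- function(queen_subdominant, queen_interactions) {
  k <- queen_subdominant; n <- queen_interactions
  if (n < 1) stop("'queen_interactions' must be >= 1", call. = FALSE)
  if (k < 0 || k > n) stop("'queen_subdominant' must be in [0, n]",
                           call. = FALSE)
  if (k == 0) 1 / n else k / n
}

#' Lower bound on the interaction asymmetry from the dominance error rate
#'
#' Inverts the logistic discrimination function [sigma_dom()]: if a queen
#' separated from workers by a steady expression gap `Delta` loses a fraction
#' `error_rate` of her interactions, then
#' `lambda = log((1 - error_rate) / error_rate) / Delta`.
#' Because an error rate estimated from a finite sample without observed
#' errors is an upper bound on the true rate, the returned `lambda` is a lower
#' bound on the asymmetry. Exact inverse of `sigma_dom` on its domain.
#'
#' @param error_rate dominance error rate in (0, 1).
#' @param gap steady queen-worker expression gap `Delta` (> 0, scaled units).
#'   Defaults to the mean-field gap `1 - worker_attractor(alpha_tilde)` at the
#'   supplied `alpha_tilde`; the appropriate gap depends on which expression
#'   contrast the error events probe, so it is exposed.
#' @param alpha_tilde colony-level coupling used for the default gap.
#' @return Estimated lower bound on `lambda_asym`.
#' @examples
#' estimate_lambda_bound(1 / 17, gap = log(16) / 24)  # ~24
#' @export
estimate_lambda_bound <- function(error_rate, gap = NULL, alpha_tilde = NULL) {
  if (!is.finite(error_rate) || error_rate <= 0 || error_rate >= 1)
    stop("'error_rate' must be in (0, 1)", call. = FALSE)
  if (is.null(gap)) {
    if (is.null(alpha_tilde))
      stop("supply 'gap' or 'alpha_tilde' for the default mean-field gap",
           call. = FALSE)
    gap <- 1 - worker_attractor(alpha_tilde)
  }
  if (!is.finite(gap) || gap <= 0) stop("'gap' must be > 0", call. = FALSE)
  log((1 - error_rate) / error_rate) / gap
}

#' Estimate behavioural parameters from an interaction event log
#'
#' Convenience pipeline from an event log (see [event_log()]) to the model
#' parameters: per-capita daily fighting rate, queen dominance error rate
#' (queen = the individual with the highest dominance index), the asymmetry
#' bound, and the dimensionless placement `alpha` on the phase diagram.
#'
#' @param events an interaction event log.
#' @param hours_observed per-individual observed time on the nest: a data
#'   frame with columns `individual`, `hours`.
#' @param census_N census size; defaults to the number of individuals in
#'   `hours_observed`.
#' @param degradation_time_h molecular degradation time used to
#'   nondimensionalize the interaction rate (hours).
#' @param gap expression gap for [estimate_lambda_bound()] (optional).
#' @return A list: `rate` (from [estimate_interaction_rate()]), `queen`,
#'   `error_rate`, `lambda_bound` (NULL if no gap resolvable), `alpha`.
#' @export
estimate_from_log <- function(events, hours_observed, census_N = NULL,
                              degradation_time_h = 30, gap = NULL) {
  events <- validate_event_log(events)
  if (is.null(census_N)) census_N <- nrow(hours_observed)
  fights <- events[events$type %in% c("DOM", "SUB"), , drop = FALSE]
  per_ind <- vapply(hours_observed$individual, function(id)
    sum(fights$actor == id), 0L)
  obs_h <- stats::median(hours_observed$hours)
  counts_fight <- behavior_counts(per_ind, observation_time_h = obs_h,
                                  census_N = census_N)
  rate <- estimate_interaction_rate(counts_fight)

  idx <- behavior_indices(events, hours_observed)
  queen <- idx$individual[which.max(ifelse(is.na(idx$dominance_index), -1,
                                           idx$dominance_index))]
  q_n <- sum(fights$actor == queen)
  q_sub <- sum(fights$actor == queen & fights$type == "SUB")
  err <- if (q_n >= 1) estimate_error_rate(q_sub, q_n) else NA_real_
  lam <- if (!is.null(gap) && is.finite(err)) {
    estimate_lambda_bound(err, gap = gap)
  } else NULL
  alpha <- rate$rate_per_day / 24 * degradation_time_h
  list(rate = rate, queen = queen, error_rate = err, lambda_bound = lam,
       alpha = alpha)
}
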