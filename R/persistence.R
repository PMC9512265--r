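# Queen-persistence-time statistics.
#
# A queen persists until a worker's queen genes are activated by chance:
# between two consecutive subdominant interactions (mean gap T_int) a worker's
# repressed molecular state survives for a stability time R * T_int, so per
# observation window of length T_int each of the N workers independently
# escapes repression with probability p1 (e.g. exp(-R) for Poisson-timed
# interactions). The number of windows until the first escape is geometric
# with success probability 1 - (1 - p1)^N, and completing the activation costs
# one stability time, giving T = T_int * (R + 1 / (1 - (1 - p1)^N)).

persist_check <- function(R, N, T_int) {
  if (any(R < 0)) stop("'R' must be >= 0", call. = FALSE)
  if (any(N < 1)) stop("'N' must be >= 1", call. = FALSE)
  if (any(T_int <= 0)) stop("'T_int' must be > 0", call. = FALSE)
}

persist_template <- function(p1, R, N, T_int) {
  denom <- 1 - (1 - p1)^N
  ifelse(denom <= 0, Inf, T_int * (R + 1 / denom))
}

#' Expected queen persistence time from the interaction/stability time ratio
#'
#' Closed form `T = T_int * (R + 1 / (1 - (1 - exp(-R))^N))`, where `T_int` is
#' the mean time between two consecutive subdominant interactions of a worker,
#' `R` the ratio of the molecular stability time to `T_int`, and `N` the
#' number of workers. Monotone increasing in `R`; for `N = 1` it reduces to
#' `T_int * (R + exp(R))`. `R = 0` (no molecular stability) returns `Inf` as a
#' divergence flag: activation is certain in every window, but the template
#' formula degenerates.
#'
#' @param R stability-to-interaction time ratio, >= 0 (vectorized).
#' @param N number of workers, >= 1.
#' @param T_int mean inter-interaction time of a worker (e.g. hours); the
#'   result is in the same unit.
#' @return Expected persistence time (same unit as `T_int`); `Inf` where the
#'   expression diverges.
#' @examples
#' persistence_time_R(R = 4.6, N = 20, T_int = 30 / 4.6) / 24  # ~2.7 days
#' @export
persistence_time_R <- function(R, N, T_int) {
  persist_check(R, N, T_int)
  # R = 0: escape probability per window is exp(0) = 1 only in the limit
  # sense; the template formula has denominator 0 -> divergence flag.
  out <- persist_template(exp(-R), R, N, T_int)
  out[R == 0] <- Inf
  out
}

#' Expected queen persistence time under expression noise of scale sigma
#'
#' Variant in which a worker's chance activation is an excursion of its queen
#' gene expression above the (unit) activation threshold, with noise scale
#' `sigma_expr` across insects. For an exponential expression tail the
#' per-window activation probability is `exp(-1/sigma)`, giving
#' `T = T_int * (R + 1 / (1 - (1 - exp(-1/sigma))^N))`; for a normal tail it
#' is the upper-tail probability of a zero-mean Gaussian with scale `sigma` at
#' the unit threshold. Because the activation probability decreases faster
#' than exponentially as noise is reduced, a modest suppression of expression
#' noise (e.g. by gene-body DNA methylation) extends queen persistence by
#' orders of magnitude. Strictly decreasing in `sigma_expr`.
#'
#' @param sigma_expr expression noise scale(s) across insects, > 0.
#' @param tail expression-distribution family: `"exponential"` (default) or
#'   `"normal"`.
#' @inheritParams persistence_time_R
#' @return Expected persistence time (unit of `T_int`); `Inf` in the
#'   vanishing-noise limit.
#' @export
persistence_time_sigma <- function(sigma_expr, N, T_int, R,
                                   tail = c("exponential", "normal")) {
  tail <- match.arg(tail)
  if (any(!is.finite(sigma_expr)) || any(sigma_expr <= 0))
    stop("'sigma_expr' must be > 0", call. = FALSE)
  persist_check(R, N, T_int)
  p1 <- switch(tail,
               exponential = exp(-1 / sigma_expr),
               normal = stats::pnorm(1 / sigma_expr, lower.tail = FALSE))
  persist_template(p1, R, N, T_int)
}

#' Monte-Carlo verification of the persistence-time closed forms
#'
#' Simulates the probabilistic construction behind the closed forms: in each
#' observation window of length `T_int`, every worker independently escapes
#' repression (its gap since the last subdominant interaction exceeds the
#' stability time `R * T_int`, probability `exp(-R)` for Poisson-timed
#' interactions, or its expression excursion exceeds the unit threshold under
#' the chosen tail model). The first window containing an escape ends the
#' queen's reign after the activation completes (one stability time). Interaction
#' counts per stability period are drawn as Poisson variates (`scheme =
#' "poisson"`, the default renewal model) or as a deterministic-gap renewal
#' (`scheme = "deterministic"`, in which a worker escapes a window only if
#' `R < 1`, i.e. gaps are never longer than the stability time otherwise).
#'
#' @param params a list or [persistence_params()] record with `T_int`, `R`,
#'   `N`, and optionally `sigma_expr` and `tail`; when `sigma_expr` is
#'   supplied the noise-scale variant is simulated instead of the gap variant.
#' @param replicates number of simulated queen reigns (>= 1).
#' @param seed integer seed.
#' @param scheme renewal scheme for interaction timing (gap variant only).
#' @param conf confidence level of the reported interval.
#' @return A list: `mean`, `ci` (confidence interval for the mean), `sd`,
#'   `replicates`, and the matching closed-form value `closed_form`.
#' @export
simulate_replacement <- function(params, replicates = 1e4, seed = NULL,
                                 scheme = c("poisson", "deterministic"),
                                 conf = 0.95) {
  scheme <- match.arg(scheme)
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  p <- params
  persist_check(p$R, p$N, p$T_int)
  use_sigma <- !is.null(p$sigma_expr)
  tail <- if (is.null(p$tail)) "exponential" else p$tail

  escape_draw <- function(k) {  # k workers-in-window escape indicator draws
    if (use_sigma) {
      if (tail == "exponential") stats::rexp(k, rate = 1 / p$sigma_expr) > 1
      else stats::rnorm(k, sd = p$sigma_expr) > 1
    } else if (scheme == "poisson") {
      stats::rpois(k, lambda = p$R) == 0L  # no interaction in stability period
    } else {
      rep(p$R < 1, k)  # deterministic gaps of exactly T_int
    }
  }

  if (!use_sigma && scheme == "deterministic" && p$R >= 1) {
    # gaps of exactly T_int never reach the stability time: no replacement
    closed <- persistence_time_R(p$R, p$N, p$T_int)
    return(list(mean = Inf, ci = c(Inf, Inf), sd = NA_real_,
                replicates = replicates, closed_form = closed))
  }
  times <- with_seed(seed, {
    windows <- numeric(replicates)
    active <- seq_len(replicates)
    w <- 0L
    while (length(active)) {
      w <- w + 1L
      if (w > 1e6) { windows[active] <- Inf; break }
      esc <- matrix(escape_draw(length(active) * p$N), ncol = p$N)
      done <- rowSums(esc) > 0
      windows[active[done]] <- w
      active <- active[!done]
    }
    (windows + p$R) * p$T_int
  })

  closed <- if (use_sigma)
    persistence_time_sigma(p$sigma_expr, p$N, p$T_int, p$R, tail = tail)
  else persistence_time_R(p$R, p$N, p$T_int)
  m <- mean(times); s <- stats::sd(times)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(mean = m, ci = m + c(-1, 1) * z * s / sqrt(replicates), sd = s,
       replicates = replicates, closed_form = closed)
}

#' Parameters of the queen-persistence calculation
#'
#' @param T_int mean time between consecutive subdominant interactions of a
#'   worker (hours), > 0.
#' @param R ratio of the molecular stability time to `T_int`, >= 0.
#' @param N number of workers, >= 1.
#' @param sigma_expr optional queen-gene expression noise scale across
#'   insects, > 0 (activates the noise-scale variant).
#' @param tail expression-distribution family for the noise variant.
#' @return A validated list of class `"persistence_params"`.
#' @export
persistence_params <- function(T_int, R, N, sigma_expr = NULL,
                               tail = c("exponential", "normal")) {
  tail <- match.arg(tail)
  persist_check(R, N, T_int)
  if (!is.null(sigma_expr) && (!is.finite(sigma_expr) || sigma_expr <= 0))
    stop("'sigma_expr' must be > 0", call. = FALSE)
  structure(list(T_int = T_int, R = R, N = as.integer(N),
                 sigma_expr = sigma_expr, tail = tail),
            class = "persistence_params")
}
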