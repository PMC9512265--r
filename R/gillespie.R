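# Event-driven stochastic simulation of the colony (kinetic Monte Carlo).

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = genv)
      else if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    })
    set.seed(seed)
  }
  force(code)
}

new_nest_trajectory <- function(times, n, q = NULL, int_counts, events,
                                params, seed, model) {
  structure(
    list(times = times, n = n, q = q, r = n / params$n_ss,
         int_counts = int_counts, events = events, params = params,
         seed = seed, model = model),
    class = "nest_trajectory")
}

#' @export
print.nest_trajectory <- function(x, ...) {
  cat(sprintf("<nest_trajectory: %s model, N = %d, %d samples to tau = %g, seed = %s>\n",
              x$model, ncol(x$n), length(x$times), max(x$times),
              format(x$seed)))
  cat(sprintf("  final mean r = %.3f, interactions recorded = %d\n",
              mean(x$r[nrow(x$r), ]), sum(x$int_counts)))
  invisible(x)
}

#' @export
as.data.frame.nest_trajectory <- function(x, ...) {
  N <- ncol(x$n)
  out <- data.frame(
    time = rep(x$times, times = N),
    insect = rep(seq_len(N), each = length(x$times)),
    n = as.vector(x$n),
    q = if (is.null(x$q)) 0L else as.vector(x$q),
    r = as.vector(x$r))
  out[order(out$time, out$insect), , drop = FALSE]
}

#' Final (or time-averaged) expression snapshot of a trajectory
#'
#' @param traj a `nest_trajectory` from [simulate_reduced()] or
#'   [simulate_full()].
#' @param average_over if > 0, average each insect's scaled expression over the
#'   trailing window of this duration instead of using the last sample alone;
#'   averaging suppresses demographic noise (sd ~ `1/sqrt(n_ss)`) when
#'   classifying colony structure.
#' @return Numeric vector of per-insect scaled expression levels.
#' @export
final_snapshot <- function(traj, average_over = 0) {
  stopifnot(inherits(traj, "nest_trajectory"))
  if (average_over <= 0) return(traj$r[nrow(traj$r), ])
  keep <- traj$times >= max(traj$times) - average_over
  colMeans(traj$r[keep, , drop = FALSE])
}

#' Simulate the reduced colony model (exact Gillespie algorithm)
#'
#' Event-driven simulation of the reduced master equation for the per-insect
#' queen-gene product counts. Channels per insect: production (rate 1 in
#' scaled concentration units), degradation (rate `r_i`), and subdominant
#' interactions with each nestmate j at rate
#' `alpha * K(r_i, r_j)`, each removing `m` products (floored at zero).
#' With `alpha = 0` every insect is an independent birth-death process whose
#' stationary count is Poisson with mean `n_ss`; with frequent, asymmetric
#' interactions the colony splits into a single high-expression queen and
#' suppressed workers.
#'
#' @param params a [model_params()] record in scaled units (`delta = 1`).
#' @param r_init initial scaled expression per insect (length `params$N`,
#'   recycled if length 1). Default 0.1 (a queenless worker-like start).
#' @param horizon simulation end time, in degradation-time units (> 0).
#' @param seed integer seed; identical `(params, seed)` give identical
#'   trajectories. `NULL` continues the current RNG stream.
#' @param sample_dt spacing of state snapshots.
#' @param record_events if `TRUE`, every interaction is returned as a
#'   `(time, dominant, subdominant)` row; disable for long runs where only
#'   snapshots and per-interval interaction counts are needed.
#' @return A `nest_trajectory`: sample `times`, count matrix `n` and scaled
#'   matrix `r` (samples x insects), per-interval interaction counts
#'   `int_counts`, the interaction `events`, `params` and `seed`.
#' @export
simulate_reduced <- function(params, r_init = 0.1, horizon, seed = NULL,
                             sample_dt = 0.1, record_events = TRUE) {
  params <- validate_model_params(params)
  if (params$delta != 1 || params$mu != params$n_ss)
    stop("simulate_reduced expects scaled parameters (delta = 1, mu = n_ss); ",
         "see nondimensionalize()", call. = FALSE)
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("'horizon' must be a positive number", call. = FALSE)
  r_init <- rep_len(r_init, params$N)
  if (any(r_init < 0)) stop("initial expression must be >= 0", call. = FALSE)
  n0 <- as.integer(round(r_init * params$n_ss))
  res <- with_seed(seed, cpp_simulate_reduced(
    n0, mu = params$n_ss, alpha = params$alpha, lambda = params$lambda_asym,
    m = params$m, n_ss = params$n_ss, horizon = horizon,
    sample_dt = sample_dt, record_events = record_events))
  new_nest_trajectory(res$times, res$n, NULL, res$int_counts, res$events,
                      params, seed, "reduced")
}

#' Simulate the full colony model with explicit repression states
#'
#' Simulates the master equation for the joint per-insect state `(n_i, q_i)`:
#' production at rate `mu * (1 - q_i)`, degradation at rate `delta * n_i`,
#' repression decay `q_i: 1 -> 0` at rate `Gamma`, and repression onset
#' `q_i: 0 -> 1` at rate `omega * sum_j K(r_i, r_j)`. In the limit of
#' repression episodes much shorter than the time between interactions
#' (`Gamma` large), each episode removes on average `mu / Gamma` products and
#' the dynamics reduce to [simulate_reduced()] with `m = mu / Gamma` and
#' `alpha = omega`.
#'
#' @inheritParams simulate_reduced
#' @param q_init initial repression flags (0/1, recycled to length `N`).
#' @param repression `"markovian"` (default): repression decays at constant
#'   rate `Gamma`; `"deterministic"`: each repression episode lasts exactly
#'   `1/Gamma` (refractory-period variant for sensitivity checks).
#' @return A `nest_trajectory` with an additional repression-flag matrix `q`.
#' @export
simulate_full <- function(params, r_init = 0.1, q_init = 0, horizon,
                          seed = NULL, sample_dt = 0.1,
                          repression = c("markovian", "deterministic"),
                          record_events = TRUE) {
  params <- validate_model_params(params)
  repression <- match.arg(repression)
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("'horizon' must be a positive number", call. = FALSE)
  r_init <- rep_len(r_init, params$N)
  q_init <- as.integer(rep_len(q_init, params$N))
  if (any(r_init < 0)) stop("initial expression must be >= 0", call. = FALSE)
  if (!all(q_init %in% c(0L, 1L)))
    stop("'q_init' must be 0/1 flags", call. = FALSE)
  n0 <- as.integer(round(r_init * params$n_ss))
  res <- with_seed(seed, cpp_simulate_full(
    n0, q_init, mu = params$mu, delta = params$delta, Gamma = params$Gamma,
    omega = params$omega, lambda = params$lambda_asym, n_ss = params$n_ss,
    horizon = horizon, sample_dt = sample_dt,
    deterministic_refractory = (repression == "deterministic"),
    record_events = record_events))
  new_nest_trajectory(res$times, res$n, res$q, res$int_counts, res$events,
                      params, seed, "full")
}

#' Classify the social structure of a colony snapshot
#'
#' Counts insects whose scaled expression exceeds the queen threshold:
#' 0 above -> `"no-queen"`, exactly 1 -> `"single-queen"`, several but not all
#' -> `"multiple-queen"`, all -> `"all-queen"`. Pass a time-averaged snapshot
#' (see [final_snapshot()]) to classify the underlying molecular state rather
#' than instantaneous demographic noise.
#'
#' @param snapshot per-insect scaled expression levels (non-empty).
#' @param threshold queen threshold in (0, 1); see [queen_threshold()] for the
#'   parameter-free midpoint default of the two attractors.
#' @return One of `"no-queen"`, `"single-queen"`, `"multiple-queen"`,
#'   `"all-queen"`.
#' @export
classify_social_structure <- function(snapshot, threshold) {
  if (length(snapshot) == 0L)
    stop("'snapshot' must be non-empty", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("'threshold' must be in (0, 1)", call. = FALSE)
  k <- sum(snapshot > threshold)
  if (k == 0L) "no-queen"
  else if (k == 1L) "single-queen"
  else if (k == length(snapshot)) "all-queen"
  else "multiple-queen"
}

#' Phase diagram of emergent social structures
#'
#' Sweeps the interaction rate `alpha` and asymmetry `lambda` over a grid,
#' simulating `replicates` seeded colonies per cell from a worker-like start
#' and classifying the final (time-averaged) snapshot. For `alpha = 0` no
#' repression occurs and every insect reaches the molecular attractor
#' (all-queen); for sufficiently frequent and asymmetric interactions a single
#' queen emerges without parameter tuning.
#'
#' @param alpha_grid,lambda_grid non-empty numeric grids.
#' @param replicates seeded replicates per cell (>= 1).
#' @param params base [model_params()] record supplying `N`, `m`, `n_ss`.
#' @param seed integer; replicate s of cell (i, j) uses a deterministic
#'   sub-seed derived from it.
#' @param horizon simulation time per replicate.
#' @param threshold queen classification threshold.
#' @param r_init initial expression (worker-like default).
#' @param average_over trailing window for the classification snapshot.
#' @return Data frame with one row per cell: `alpha`, `lambda`, per-class
#'   frequencies and the modal class.
#' @export
phase_diagram <- function(alpha_grid, lambda_grid, replicates = 20,
                          params = model_params(), seed = 1, horizon = 50,
                          threshold = 0.6, r_init = 0.1, average_over = 5) {
  if (length(alpha_grid) == 0L || length(lambda_grid) == 0L)
    stop("parameter grids must be non-empty", call. = FALSE)
  if (replicates < 1L) stop("'replicates' must be >= 1", call. = FALSE)
  classes <- c("no-queen", "single-queen", "multiple-queen", "all-queen")
  grid <- expand.grid(alpha = alpha_grid, lambda = lambda_grid,
                      KEEP.OUT.ATTRS = FALSE)
  freq <- matrix(0, nrow(grid), length(classes),
                 dimnames = list(NULL, classes))
  for (g in seq_len(nrow(grid))) {
    p <- model_params(N = params$N, alpha = grid$alpha[g],
                      lambda_asym = grid$lambda[g], m = params$m,
                      n_ss = params$n_ss)
    for (s in seq_len(replicates)) {
      sub_seed <- (seed * 1000L + g * 101L + s) %% .Machine$integer.max
      traj <- simulate_reduced(p, r_init = r_init, horizon = horizon,
                               seed = sub_seed, record_events = FALSE)
      cls <- classify_social_structure(
        final_snapshot(traj, average_over = average_over), threshold)
      freq[g, cls] <- freq[g, cls] + 1L
    }
  }
  freq <- freq / replicates
  out <- cbind(grid, as.data.frame(freq, check.names = FALSE))
  out$modal <- classes[max.col(freq, ties.method = "first")]
  out
}

#' Queen-removal experiment on a simulated colony
#'
#' Runs a colony to its (typically single-queen) steady state, removes the
#' highest-expressing insect at time 0, and follows the relaxation: the
#' remaining insects collectively upregulate queen genes, interaction rates
#' rise transiently, several insects may transiently exceed the egg-laying
#' threshold, and eventually a unique replacement queen re-establishes.
#'
#' @inheritParams simulate_reduced
#' @param burn_in duration of the pre-removal simulation.
#' @param post_horizon duration of the post-removal simulation.
#' @param window width of the time windows over which the activity proxy
#'   (interactions per insect per unit time) is aggregated.
#' @param threshold egg-laying / queen threshold on scaled expression; default
#'   [queen_threshold()] at the colony-level coupling of `params`.
#' @param stable_for a replacement queen counts as re-established at the first
#'   time from which exactly one insect stays above `threshold` for at least
#'   this long.
#' @return A list with elements `pre` and `post` (`nest_trajectory`s; the
#'   post phase re-indexes the surviving insects), `removed` (insect id),
#'   `activity` (data frame: window mid-time, per-capita interaction rate,
#'   phase), `egg_layers` (data frame: time, insects above threshold, phase),
#'   `replacement_time` (or `NA`), the pre/post mean interaction rates, and
#'   the pre/post `arousal` (mean per-wasp scaled expression, the model's
#'   analogue of the per-wasp global movement measured by frame differencing:
#'   dominance-related movement tracks the queen-gene state, so the collective
#'   upregulation after queen removal predicts elevated nest activity even
#'   while the fight rate, which consumes gene products, does not rise).
#'   `pre_arousal` averages the second half of the burn-in; `post_arousal`
#'   the reprogramming window `[1, min(10, post_horizon)]`.
#' @export
queen_removal_experiment <- function(params, seed = NULL, burn_in = 40,
                                     post_horizon = 40, window = 2,
                                     threshold = NULL, r_init = 0.1,
                                     sample_dt = 0.1, stable_for = 5) {
  params <- validate_model_params(params)
  if (params$N < 2L) stop("queen removal needs N >= 2", call. = FALSE)
  if (is.null(threshold))
    threshold <- min(queen_threshold(alpha_tilde_match(params)), 0.8)

  pre <- simulate_reduced(params, r_init = r_init, horizon = burn_in,
                          seed = seed, sample_dt = sample_dt,
                          record_events = FALSE)
  r_final <- final_snapshot(pre, average_over = min(2, burn_in / 4))
  removed <- which.max(r_final)
  keep <- setdiff(seq_len(params$N), removed)
  p_post <- model_params(N = params$N - 1L, alpha = params$alpha,
                         lambda_asym = params$lambda_asym, m = params$m,
                         n_ss = params$n_ss)
  post_seed <- if (is.null(seed)) NULL else (seed + 7919L) %% .Machine$integer.max
  post <- simulate_reduced(p_post, r_init = pre$r[nrow(pre$r), keep],
                           horizon = post_horizon, seed = post_seed,
                           sample_dt = sample_dt, record_events = FALSE)

  act <- rbind(activity_windows(pre, window, phase = "pre", offset = -burn_in),
               activity_windows(post, window, phase = "post", offset = 0))
  egg <- rbind(
    data.frame(time = pre$times - burn_in,
               egg_layers = rowSums(pre$r > threshold), phase = "pre"),
    data.frame(time = post$times,
               egg_layers = rowSums(post$r > threshold), phase = "post"))

  above <- post$r > threshold
  counts <- rowSums(above)
  repl <- NA_real_
  need <- max(1L, ceiling(stable_for / sample_dt))
  for (k in seq_along(post$times)) {
    if (k + need - 1L > length(post$times)) break
    idx <- k:(k + need - 1L)
    if (all(counts[idx] == 1L) &&
        length(unique(max.col(post$r[idx, , drop = FALSE]))) == 1L) {
      repl <- post$times[k]
      break
    }
  }
  pre_act <- act$rate[act$phase == "pre"]
  post_act <- act$rate[act$phase == "post"]
  pre_arousal <- mean(pre$r[pre$times >= burn_in / 2, ])
  post_arousal <- mean(post$r[post$times >= 1 &
                                post$times <= min(10, post_horizon), ])
  list(pre = pre, post = post, removed = removed, activity = act,
       egg_layers = egg, replacement_time = repl,
       pre_activity = mean(pre_act), post_activity = mean(post_act),
       pre_arousal = pre_arousal, post_arousal = post_arousal)
}

# Per-capita interaction rate aggregated over fixed-width time windows.
activity_windows <- function(traj, window, phase, offset = 0) {
  dt <- diff(traj$times[1:2])
  per <- max(1L, round(window / dt))
  counts <- traj$int_counts[-1]  # counts[k] = events in (t_{k-1}, t_k]
  n_win <- floor(length(counts) / per)
  if (n_win == 0L) return(data.frame(time = numeric(0), rate = numeric(0),
                                     phase = character(0)))
  idx <- rep(seq_len(n_win), each = per)
  tot <- tapply(counts[seq_along(idx)], idx, sum)
  data.frame(
    time = offset + (seq_len(n_win) - 0.5) * per * dt,
    rate = as.vector(tot) / (per * dt) / ncol(traj$n),
    phase = phase)
}
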