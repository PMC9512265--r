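# Deterministic mean-field dynamics of the colony composition f(r, tau).
#
# In the limit of negligible fluctuations and time scales much longer than
# individual interactions, the colony composition f(r, tau) obeys the
# conservative transport equation
#     d_tau f + d_r [ v(r, [f]) f ] = 0,
#     v(r, [f]) = (1 - r) - alpha_tilde * Int K(r, r') f(r', tau) dr',
# with K(r, r') = r r' sigma(r - r'). f is normalized to total mass 1 (the
# colony composition); alpha_tilde is the colony-level coupling (see
# alpha_tilde_match()). Discretization: first-order upwind finite volume on
# [0, r_max], explicit time stepping under a CFL condition, which conserves
# mass exactly and preserves f >= 0.

#' Discretized colony composition on the expression axis
#'
#' @param f non-negative density values per cell (length `n_cells`), or `NULL`
#'   for all-zero.
#' @param n_cells number of finite-volume cells (default 600).
#' @param r_max upper edge of the expression axis (default 1.5).
#' @param tau current scaled time.
#' @param normalize if `TRUE` (default) rescale to total mass 1.
#' @return An object of class `"population_density"` with cell `edges`,
#'   `centers`, width `dr`, density `f` and time `tau`.
#' @export
population_density <- function(f = NULL, n_cells = 600, r_max = 1.5, tau = 0,
                               normalize = TRUE) {
  edges <- seq(0, r_max, length.out = n_cells + 1L)
  dr <- edges[2] - edges[1]
  centers <- edges[-1] - dr / 2
  if (is.null(f)) f <- numeric(n_cells)
  if (length(f) != n_cells)
    stop("'f' must have one value per cell", call. = FALSE)
  if (any(!is.finite(f)) || any(f < 0))
    stop("density must be finite and non-negative", call. = FALSE)
  mass <- sum(f) * dr
  if (normalize && mass > 0) f <- f / mass
  structure(list(edges = edges, centers = centers, dr = dr, f = f, tau = tau),
            class = "population_density")
}

#' @export
print.population_density <- function(x, ...) {
  cat(sprintf("<population_density: %d cells on [0, %g], mass = %.6f, tau = %g>\n",
              length(x$f), max(x$edges), density_mass(x), x$tau))
  if (density_mass(x) > 0)
    cat(sprintf("  mean r = %.4f\n", density_mean(x)))
  invisible(x)
}

#' Narrow Gaussian initial composition
#'
#' Delta-like initial conditions are represented as narrow Gaussians (default
#' width two cells), e.g. a queenless colony with every insect at low
#' expression.
#'
#' @param center location on the expression axis.
#' @param width standard deviation; default `2 * dr`.
#' @inheritParams population_density
#' @return A normalized `population_density`.
#' @export
density_gaussian <- function(center = 0.1, width = NULL, n_cells = 600,
                             r_max = 1.5) {
  d <- population_density(n_cells = n_cells, r_max = r_max)
  if (is.null(width)) width <- 2 * d$dr
  f <- stats::dnorm(d$centers, mean = center, sd = width)
  population_density(f, n_cells = n_cells, r_max = r_max)
}

#' Total mass and mass-weighted mean of a composition
#' @param density a `population_density`.
#' @return `density_mass()`: the total mass `Int f dr`; `density_mean()`: the
#'   mass-weighted mean expression `Int r f dr / Int f dr`.
#' @export
density_mass <- function(density) sum(density$f) * density$dr

#' @rdname density_mass
#' @export
density_mean <- function(density) {
  m <- density_mass(density)
  if (m <= 0) return(NA_real_)
  sum(density$centers * density$f) * density$dr / m
}

# Interaction kernel matrix K[c, c'] = r_c r_c' sigma(r_c - r_c') on the grid.
kernel_matrix <- function(centers, lambda_asym) {
  n <- length(centers)
  diffs <- outer(centers, centers, "-")
  outer(centers, centers) * stats::plogis(-lambda_asym * diffs)
}

#' Drift velocity on the expression axis
#'
#' Per-capita drift of an insect at expression `r` embedded in a colony with
#' composition `density`:
#' `v(r) = (1 - r) - alpha_tilde * Int K(r, r') f(r') dr'`.
#' The first term is the molecular scale (production minus degradation), the
#' second the repressive colony feedback. With an empty colony `v(r) = 1 - r`.
#'
#' @param r expression level(s) at which to evaluate the drift.
#' @param density a `population_density` normalized to mass 1 (the mass that
#'   is present is used as is).
#' @param alpha_tilde colony-level rescaled interaction rate.
#' @param lambda_asym discrimination steepness.
#' @return Drift velocity value(s), finite.
#' @export
drift_velocity <- function(r, density, alpha_tilde, lambda_asym) {
  stopifnot(inherits(density, "population_density"))
  if (any(density$f < 0))
    stop("density must be non-negative", call. = FALSE)
  if (any(r < 0)) stop("'r' must be >= 0", call. = FALSE)
  w <- density$f * density$dr
  sapply(r, function(ri) {
    (1 - ri) - alpha_tilde * ri *
      sum(density$centers * stats::plogis(-lambda_asym * (ri - density$centers)) * w)
  })
}

#' Evolve the colony composition under the mean-field transport equation
#'
#' Conservative first-order upwind finite-volume integration of
#' `d_tau f + d_r(v f) = 0` with the self-consistent drift [drift_velocity()].
#' Mass is conserved to machine precision and positivity is preserved by the
#' upwind scheme. Boundary fluxes are zero (the drift points inward at both
#' ends of `[0, r_max]` for `r_max > 1`).
#'
#' @param density initial `population_density` with positive mass.
#' @param alpha_tilde,lambda_asym mean-field parameters.
#' @param duration integration time in scaled units.
#' @param n_save number of intermediate snapshots to keep (>= 2).
#' @param cfl Courant number in (0, 1]; default 0.5.
#' @return A list of class `"density_trajectory"`: `times`, `densities` (list
#'   of `population_density` snapshots), `final`, `mass_drift` (absolute mass
#'   change over the run) and the parameters.
#' @export
evolve_density <- function(density, alpha_tilde, lambda_asym = 24, duration,
                           n_save = 11, cfl = 0.5) {
  stopifnot(inherits(density, "population_density"))
  if (density_mass(density) <= 0)
    stop("initial composition must have positive mass", call. = FALSE)
  if (duration <= 0) stop("'duration' must be > 0", call. = FALSE)
  f <- density$f
  rc <- density$centers
  dr <- density$dr
  n <- length(f)
  K <- kernel_matrix(rc, lambda_asym)
  mass0 <- sum(f) * dr

  save_times <- seq(0, duration, length.out = max(2L, n_save))
  out_t <- numeric(0); out_f <- list()
  tau <- 0; next_save <- 1L
  while (next_save <= length(save_times) && save_times[next_save] <= 0) {
    out_t <- c(out_t, tau); out_f[[length(out_f) + 1L]] <- f
    next_save <- next_save + 1L
  }

  repeat {
    v <- (1 - rc) - alpha_tilde * as.vector(K %*% f) * dr  # K has the r r' factor
    v_edge <- 0.5 * (v[-n] + v[-1])                 # interior edges
    dt <- cfl * dr / max(abs(v_edge), 1e-8)
    dt <- min(dt, duration - tau)
    flux <- ifelse(v_edge > 0, v_edge * f[-n], v_edge * f[-1])
    f <- f - dt / dr * (c(flux, 0) - c(0, flux))    # zero boundary flux
    tau <- tau + dt
    if (any(!is.finite(f)))
      stop("mean-field solver produced non-finite density at tau = ",
           signif(tau, 4), " (max |v| = ", signif(max(abs(v)), 4), ")",
           call. = FALSE)
    f[f < 0] <- 0  # clip tiny negative round-off
    while (next_save <= length(save_times) &&
           tau >= save_times[next_save] - 1e-12) {
      out_t <- c(out_t, tau); out_f[[length(out_f) + 1L]] <- f
      next_save <- next_save + 1L
    }
    if (tau >= duration - 1e-12) break
  }

  snaps <- lapply(seq_along(out_t), function(i)
    population_density(out_f[[i]], n_cells = n, r_max = max(density$edges),
                       tau = out_t[i], normalize = FALSE))
  structure(
    list(times = out_t, densities = snaps, final = snaps[[length(snaps)]],
         mass_drift = abs(sum(f) * dr - mass0),
         alpha_tilde = alpha_tilde, lambda_asym = lambda_asym),
    class = "density_trajectory")
}

#' Steady-state colony composition from a queenless start
#'
#' Convenience wrapper: evolves a narrow low-expression composition (the
#' queenless colony) to its steady state.
#'
#' @inheritParams evolve_density
#' @inheritParams population_density
#' @param start initial expression level.
#' @return The final `population_density`.
#' @export
meanfield_steady <- function(alpha_tilde, lambda_asym = 24, n_cells = 600,
                             r_max = 1.5, duration = 50, start = 0.1,
                             cfl = 0.5) {
  d0 <- density_gaussian(center = start, n_cells = n_cells, r_max = r_max)
  evolve_density(d0, alpha_tilde, lambda_asym, duration = duration,
                 n_save = 2, cfl = cfl)$final
}

# Tracer drift under the frozen-population closure: the composition enters
# only through its mean rbar (collapsed to a point mass), which is the
# construction behind the attractors r0 = 1 and r2 = 1/(1 + alpha_tilde rbar)
# and the saddle-node bifurcation diagram.
tracer_drift <- function(r, rbar, alpha_tilde, lambda_asym) {
  (1 - r) - alpha_tilde * r * rbar * stats::plogis(-lambda_asym * (r - rbar))
}

#' Fixed points of the tracer dynamics
#'
#' Locates the fixed points of the single-insect (tracer) drift, either under
#' the frozen-population closure (supply `rbar`) or embedded in a full
#' composition (supply `density`), and labels their stability from the sign of
#' the derivative. In the bistable regime the stable fixed points are the
#' worker attractor near `1/(1 + alpha_tilde * rbar)` and the queen attractor
#' near 1, separated by an unstable point (the separatrix).
#'
#' @param alpha_tilde,lambda_asym mean-field parameters.
#' @param rbar frozen colony mean (used if `density` is `NULL`).
#' @param density optional `population_density` for the full tracer field.
#' @param r_max search interval upper end.
#' @return Data frame with columns `r` and `stability`
#'   (`"stable"`/`"unstable"`), ordered by `r`.
#' @export
tracer_fixed_points <- function(alpha_tilde, lambda_asym = 24, rbar = NULL,
                                density = NULL, r_max = 1.5) {
  if (is.null(density) && is.null(rbar))
    stop("supply either 'rbar' or 'density'", call. = FALSE)
  vfun <- if (!is.null(density)) {
    function(r) drift_velocity(r, density, alpha_tilde, lambda_asym)
  } else {
    function(r) tracer_drift(r, rbar, alpha_tilde, lambda_asym)
  }
  grid <- seq(0, r_max, length.out = 3001L)
  vg <- vfun(grid)
  sgn <- sign(vg)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(idx, function(i)
    stats::uniroot(vfun, c(grid[i], grid[i + 1]), tol = 1e-10)$root, 0)
  roots <- c(roots, grid[vg == 0])
  if (!length(roots))
    return(data.frame(r = numeric(0), stability = character(0)))
  roots <- sort(unique(roots))
  h <- 1e-5
  stab <- ifelse(vapply(roots, function(r)
    (vfun(min(r + h, r_max)) - vfun(max(r - h, 0))), 0) < 0,
    "stable", "unstable")
  data.frame(r = roots, stability = stab)
}

#' Phase portrait of the joint colony/insect dynamics
#'
#' Vector field of the co-evolution of the colony mean `rbar` (whose drift
#' `1 - rbar - alpha_tilde * rbar^2 / 2` follows exactly from the complement
#' identity of the kernel) and a tracer insect's expression `r` under the
#' frozen-population closure, together with integrated tracer trajectories and
#' a bisection estimate of the separatrix at the steady colony mean.
#'
#' @param alpha_tilde,lambda_asym mean-field parameters.
#' @param rbar_grid,r_grid axis grids for the arrow field.
#' @param tracer_starts data frame / list with `rbar` and `r` start values for
#'   integrated trajectories (optional).
#' @param duration integration time for tracer trajectories.
#' @param dt integration step (RK4).
#' @return A list: `field` (data frame `rbar, r, drbar, dr`), `tracers` (list
#'   of trajectory data frames), `separatrix` (tracer separatrix at the steady
#'   colony mean, or `NA` with `converged = FALSE` if bisection failed),
#'   `rbar_steady`.
#' @export
phase_portrait <- function(alpha_tilde, lambda_asym = 24,
                           rbar_grid = seq(0.05, 1.2, by = 0.05),
                           r_grid = seq(0.05, 1.4, by = 0.05),
                           tracer_starts = NULL, duration = 30, dt = 0.01) {
  field <- expand.grid(rbar = rbar_grid, r = r_grid, KEEP.OUT.ATTRS = FALSE)
  field$drbar <- 1 - field$rbar - alpha_tilde * field$rbar^2 / 2
  field$dr <- tracer_drift(field$r, field$rbar, alpha_tilde, lambda_asym)

  step <- function(state) {
    deriv <- function(s) c(1 - s[1] - alpha_tilde * s[1]^2 / 2,
                           tracer_drift(s[2], s[1], alpha_tilde, lambda_asym))
    k1 <- deriv(state); k2 <- deriv(state + dt / 2 * k1)
    k3 <- deriv(state + dt / 2 * k2); k4 <- deriv(state + dt * k3)
    pmax(state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
  }
  integrate_tracer <- function(rbar0, r0) {
    n_steps <- ceiling(duration / dt)
    out <- matrix(NA_real_, n_steps + 1L, 3L,
                  dimnames = list(NULL, c("tau", "rbar", "r")))
    s <- c(rbar0, r0); out[1L, ] <- c(0, s)
    for (k in seq_len(n_steps)) {
      s <- step(s)
      out[k + 1L, ] <- c(k * dt, s)
    }
    as.data.frame(out)
  }
  tracers <- list()
  if (!is.null(tracer_starts)) {
    tracer_starts <- as.data.frame(tracer_starts)
    tracers <- lapply(seq_len(nrow(tracer_starts)), function(i)
      integrate_tracer(tracer_starts$rbar[i], tracer_starts$r[i]))
  }

  rbar_s <- steady_mean_expression(alpha_tilde)
  fate <- function(r0) {  # queen (TRUE) vs worker fate at frozen steady rbar
    r <- r0
    for (k in seq_len(ceiling(duration / dt)))
      r <- max(r + dt * tracer_drift(r, rbar_s, alpha_tilde, lambda_asym), 0)
    r > (1 + worker_attractor(alpha_tilde, rbar_s)) / 2
  }
  lo <- worker_attractor(alpha_tilde, rbar_s); hi <- 1
  converged <- fate(hi) && !fate(lo)
  sep <- NA_real_
  if (converged) {
    for (k in 1:40) {
      mid <- (lo + hi) / 2
      if (fate(mid)) hi <- mid else lo <- mid
    }
    sep <- (lo + hi) / 2
  }
  list(field = field, tracers = tracers,
       separatrix = sep, converged = converged, rbar_steady = rbar_s)
}

#' Classify the response to an intrinsic or extrinsic perturbation
#'
#' Starting from a steady colony composition, perturbs either a single tracer
#' insect (intrinsic: e.g. gene-expression noise displaces one insect's state
#' while the composition, a colony-scale quantity, is unchanged) or the
#' composition and tracer coherently (extrinsic: e.g. removal of the queen
#' mode affects every insect), and classifies the relaxation: `"suppressed"`
#' if the tracer returns to its pre-perturbation state, `"reprogrammed"` if it
#' converges elsewhere (a new attractor or the transient plastic state).
#'
#' @param steady a steady `population_density` (e.g. from
#'   [meanfield_steady()]).
#' @param mode `"intrinsic"` or `"extrinsic"`.
#' @param magnitude intrinsic: displacement of the tracer's expression
#'   (may be negative; the displaced value must stay >= 0). extrinsic:
#'   fraction in `[0, 1]` of the queen-mode mass removed from the composition.
#' @param alpha_tilde,lambda_asym mean-field parameters.
#' @param duration relaxation time integrated after the perturbation.
#' @param tol return tolerance for classifying as suppressed.
#' @return A list: `mode`, `magnitude`, `outcome`, tracer `r_start`,
#'   `r_final`, and `displacement = r_final - r_start`.
#' @export
perturb_and_classify <- function(steady, mode = c("intrinsic", "extrinsic"),
                                 magnitude, alpha_tilde, lambda_asym = 24,
                                 duration = 60, tol = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(steady, "population_density"))
  fp <- tracer_fixed_points(alpha_tilde, lambda_asym, density = steady)
  stable <- fp[fp$stability == "stable", , drop = FALSE]
  if (!nrow(stable)) stop("no stable tracer state in steady composition",
                          call. = FALSE)
  r_worker <- min(stable$r)
  dt <- 0.01

  if (mode == "intrinsic") {
    r0 <- r_worker + magnitude
    if (r0 < 0)
      stop("perturbation would make expression negative", call. = FALSE)
    r <- r0
    for (k in seq_len(ceiling(duration / dt)))
      r <- max(r + dt * drift_velocity(r, steady, alpha_tilde, lambda_asym), 0)
    out_r <- r
  } else {
    if (magnitude < 0 || magnitude > 1)
      stop("extrinsic magnitude is the removed queen-mode fraction in [0, 1]",
           call. = FALSE)
    thr <- (1 + r_worker) / 2
    f <- steady$f
    f[steady$centers > thr] <- f[steady$centers > thr] * (1 - magnitude)
    if (sum(f) <= 0) stop("perturbation removed all mass", call. = FALSE)
    d <- population_density(f, n_cells = length(f),
                            r_max = max(steady$edges))  # renormalized colony
    # co-evolve composition and tracer
    traj <- evolve_density(d, alpha_tilde, lambda_asym, duration = duration,
                           n_save = max(40L, ceiling(duration)))
    r <- r_worker
    for (k in seq_len(length(traj$times) - 1L)) {
      h <- traj$times[k + 1L] - traj$times[k]
      steps <- max(1L, ceiling(h / dt))
      for (s in seq_len(steps))
        r <- max(r + (h / steps) *
                   drift_velocity(r, traj$densities[[k]], alpha_tilde,
                                  lambda_asym), 0)
    }
    out_r <- r
  }
  outcome <- if (abs(out_r - r_worker) < tol) "suppressed" else "reprogrammed"
  list(mode = mode, magnitude = magnitude, outcome = outcome,
       r_start = r_worker, r_final = out_r,
       displacement = out_r - r_worker)
}

#' Saddle-node bifurcation diagram of the tracer dynamics
#'
#' Sweeps the colony structure (represented by the frozen mean `rbar` of the
#' composition, the functional bifurcation parameter) and tracks the fixed
#' points of the tracer drift. For small `rbar` only the queen state near 1
#' exists; beyond a fold the worker state and an unstable separatrix branch
#' appear through a saddle-node bifurcation.
#'
#' @param alpha_tilde,lambda_asym mean-field parameters.
#' @param rbar_seq increasing sweep of the control parameter; should straddle
#'   the fold.
#' @return A list: `branches` (data frame `rbar, r, stability`) and `fold`
#'   (data frame with the bracketed fold location, zero rows when no fold is
#'   inside the sweep).
#' @export
bifurcation_diagram <- function(alpha_tilde, lambda_asym = 24,
                                rbar_seq = seq(0.05, 1.2, by = 0.01)) {
  if (!length(rbar_seq)) stop("'rbar_seq' must be non-empty", call. = FALSE)
  per <- lapply(rbar_seq, function(rb) {
    fp <- tracer_fixed_points(alpha_tilde, lambda_asym, rbar = rb)
    if (nrow(fp)) cbind(rbar = rb, fp) else NULL
  })
  branches <- do.call(rbind, per)
  counts <- vapply(per, function(x) if (is.null(x)) 0L else nrow(x), 0L)
  fold <- data.frame(rbar = numeric(0), r = numeric(0))
  jump <- which(counts[-1] >= 3L & counts[-length(counts)] < 3L)
  if (length(jump)) {
    lo <- rbar_seq[jump[1]]; hi <- rbar_seq[jump[1] + 1L]
    n_roots <- function(rb)
      nrow(tracer_fixed_points(alpha_tilde, lambda_asym, rbar = rb))
    for (k in 1:30) {
      mid <- (lo + hi) / 2
      if (n_roots(mid) >= 3L) hi <- mid else lo <- mid
    }
    fp <- tracer_fixed_points(alpha_tilde, lambda_asym, rbar = hi)
    low2 <- sort(fp$r)[1:2]  # coalescing non-queen roots at the fold
    fold <- data.frame(rbar = (lo + hi) / 2, r = mean(low2))
  }
  list(branches = branches, fold = fold)
}
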