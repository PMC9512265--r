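#' Kinetic and interaction parameters of the colony model
#'
#' Bundles all parameters of the coupled molecular/colony model in one audited
#' record. The model tracks, for each of `N` insects, the number `n` of queen
#' gene products (produced at rate `mu`, degraded at per-molecule rate `delta`)
#' and couples insects through dominance interactions: insect i is subject to a
#' subdominant interaction with insect j at rate proportional to the kernel
#' [interaction_kernel()], which represses i's queen-gene production.
#'
#' By default parameters are in scaled units: time is measured in units of the
#' degradation time of queen gene products (`delta = 1`) and expression is
#' scaled by the unrepressed steady-state level, so `r = n / n_ss` fluctuates
#' around 1 for an unsuppressed insect. Use [nondimensionalize()] to build a
#' scaled record from physical rates.
#'
#' @param N number of insects in the colony (>= 1).
#' @param alpha per-individual interaction rate (dimensionless in scaled units):
#'   insect i is subdominant to j at rate `alpha * K(r_i, r_j)`.
#' @param lambda_asym interaction asymmetry: steepness of the dominance
#'   discrimination function [sigma_dom()]; expression differences are resolved
#'   on a scale `1/lambda_asym`. `0` means dominance is a coin flip.
#' @param m mean number of queen-gene products removed from the subdominant
#'   insect per interaction (non-negative integer, count units).
#' @param n_ss steady-state product count setting the granularity of the
#'   stochastic simulation (`r = n / n_ss`). Default 50.
#' @param mu production rate. In scaled units this defaults to `n_ss` counts per
#'   degradation time, i.e. rate 1 in concentration units.
#' @param delta per-molecule degradation rate; 1 in scaled units.
#' @param Gamma repression decay rate (full model only): a repressed insect
#'   (`q = 1`) returns to the producing state at rate `Gamma`.
#' @param omega interaction rate constant of the full model: insect i is
#'   repressed (`q`: 0 -> 1) at rate `omega * sum_j K(r_i, r_j)`.
#' @param alpha_tilde rescaled interaction rate of the mean-field limit. If
#'   `NULL`, the per-partner default mapping `alpha * m / n_ss` (i.e. alpha
#'   times the interaction-induced expression loss in scaled concentration
#'   units) is stored. See [alpha_tilde_match()] for the colony-level value
#'   used when comparing a finite-N simulation with the mean-field equation.
#'
#' @return An object of class `"model_params"` (a validated list).
#' @seealso [nondimensionalize()], [sigma_dom()], [interaction_kernel()]
#' @examples
#' p <- model_params(N = 16, alpha = 4.6, lambda_asym = 24)
#' p$alpha_tilde
#' @export
model_params <- function(N = 16, alpha = 4.6, lambda_asym = 24, m = 5,
                         n_ss = 50, mu = n_ss, delta = 1, Gamma = 10,
                         omega = 1, alpha_tilde = NULL) {
  if (is.null(alpha_tilde)) alpha_tilde <- alpha * m / n_ss
  p <- structure(
    list(N = as.integer(N), mu = mu, delta = delta, Gamma = Gamma,
         omega = omega, m = as.integer(m), alpha = alpha,
         lambda_asym = lambda_asym, alpha_tilde = alpha_tilde,
         n_ss = as.integer(n_ss)),
    class = "model_params")
  validate_model_params(p)
}

validate_model_params <- function(p) {
  stopifnot(is.list(p))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("mu", "delta", "Gamma", "omega", "alpha", "lambda_asym",
              "alpha_tilde")) {
    if (!num1(p[[f]])) stop("parameter '", f, "' must be a finite number",
                            call. = FALSE)
  }
  if (p$N < 1L) stop("N must be >= 1", call. = FALSE)
  if (p$n_ss < 1L) stop("n_ss must be >= 1", call. = FALSE)
  if (p$m < 0L) stop("m must be a non-negative integer", call. = FALSE)
  rates <- c(p$mu, p$delta, p$Gamma, p$omega, p$alpha)
  if (any(rates < 0)) stop("all rates must be >= 0", call. = FALSE)
  if (p$lambda_asym < 0) stop("lambda_asym must be >= 0", call. = FALSE)
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Colony model parameters (scaled time unit = degradation time)\n")
  cat(sprintf("  N = %d insects, n_ss = %d products\n", x$N, x$n_ss))
  cat(sprintf("  mu = %g, delta = %g, Gamma = %g, omega = %g\n",
              x$mu, x$delta, x$Gamma, x$omega))
  cat(sprintf("  alpha = %g, lambda = %g, m = %d, alpha_tilde = %g\n",
              x$alpha, x$lambda_asym, x$m, x$alpha_tilde))
  invisible(x)
}

#' Dominance discrimination function
#'
#' Probability weight that the focal insect loses (is subdominant in) an
#' encounter, as a function of the expression difference `x = r_i - r_j`
#' between the focal insect i and its opponent j. The logistic form
#' `1 / (1 + exp(lambda_asym * x))` decreases monotonically on a scale
#' `1/lambda_asym`: an insect expressing queen genes more highly than its
#' opponent is unlikely to be dominated, and for `lambda_asym = 0` dominance is
#' decided by a coin flip. Satisfies the exact complement identity
#' `sigma_dom(x) + sigma_dom(-x) = 1`.
#'
#' @param x expression difference(s) `r_i - r_j`; finite numeric.
#' @param lambda_asym discrimination steepness, >= 0.
#' @return Numeric vector of weights in `[0, 1]`.
#' @examples
#' sigma_dom(0, 24)        # 0.5: equals cannot be told apart
#' sigma_dom(-0.5, 24)     # ~1: much lower expression, almost surely loses
#' @export
sigma_dom <- function(x, lambda_asym) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric", call. = FALSE)
  if (!is.numeric(lambda_asym) || length(lambda_asym) != 1L ||
      !is.finite(lambda_asym) || lambda_asym < 0)
    stop("'lambda_asym' must be a single finite number >= 0", call. = FALSE)
  # plogis(-lambda*x) = 1/(1+exp(lambda*x)), numerically stable for large |x|
  stats::plogis(-lambda_asym * x)
}

#' Dominance interaction kernel
#'
#' Rate weight with which insect i is subject to subdominant interactions with
#' insect j: `K(r_i, r_j) = r_i * r_j * sigma_dom(r_i - r_j)`. The product
#' `r_i * r_j` makes highly expressing insects interact more; the
#' discrimination factor directs repression at the lower-expressing insect.
#' The complement identity gives `K(ri, rj) + K(rj, ri) = ri * rj` (every
#' encounter has exactly one loser).
#'
#' @param r_i,r_j scaled expression levels, >= 0 (vectorized).
#' @param lambda_asym discrimination steepness, >= 0.
#' @return Non-negative rate weight(s).
#' @examples
#' interaction_kernel(1, 1, 24)   # 0.5
#' interaction_kernel(0.2, 1, 24) + interaction_kernel(1, 0.2, 24)  # 0.2
#' @export
interaction_kernel <- function(r_i, r_j, lambda_asym) {
  if (any(!is.finite(r_i)) || any(!is.finite(r_j)) ||
      any(r_i < 0) || any(r_j < 0))
    stop("expression levels must be finite and >= 0", call. = FALSE)
  r_i * r_j * sigma_dom(r_i - r_j, lambda_asym)
}

#' Nondimensionalize physical rates into scaled model parameters
#'
#' Converts physically measured rates into the scaled units used throughout:
#' time in units of the degradation time of queen gene products (`delta = 1`)
#' and expression scaled by the unrepressed steady state (`mu/delta -> 1`, i.e.
#' `n_ss` counts). The dimensionless per-individual interaction rate is the
#' physical per-capita rate divided by the degradation rate, e.g. 3.7
#' interactions per day with a 30 h molecular degradation time gives
#' `alpha = 3.7 * 30/24 = 4.625`.
#'
#' @param interaction_rate physical per-capita subdominant interaction rate, in
#'   events per hour (use `rate_per_day / 24` for daily rates).
#' @param delta physical degradation rate of queen gene products, per hour
#'   (e.g. `1/30` for a 30 h degradation time). Must be > 0.
#' @param mu physical production rate, per hour; only its positivity is used
#'   (concentration is rescaled to the steady state `mu/delta`). Defaults to
#'   `delta` (steady state already at 1 in the caller's units).
#' @inheritParams model_params
#' @return A scaled [model_params()] record with `delta = 1`, `mu = n_ss`,
#'   `alpha = interaction_rate / delta`, `Gamma` and `omega` divided by
#'   `delta`, and `alpha_tilde = alpha * m / n_ss`.
#' @examples
#' p <- nondimensionalize(interaction_rate = 3.7 / 24, delta = 1 / 30)
#' p$alpha   # 4.625
#' @export
nondimensionalize <- function(interaction_rate, delta, mu = delta,
                              Gamma = 0, omega = 0, N = 16, m = 5, n_ss = 50,
                              lambda_asym = 24) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0)
    stop("'delta' (degradation rate) must be > 0", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("'mu' (production rate) must be > 0", call. = FALSE)
  if (interaction_rate < 0)
    stop("'interaction_rate' must be >= 0", call. = FALSE)
  model_params(N = N, alpha = interaction_rate / delta,
               lambda_asym = lambda_asym, m = m, n_ss = n_ss,
               mu = n_ss, delta = 1, Gamma = Gamma / delta,
               omega = omega / delta)
}

#' Colony-level rescaled interaction rate for mean-field comparison
#'
#' The mean-field transport equation (see [evolve_density()]) is written for a
#' colony composition normalized to total mass 1, so its coupling constant
#' `alpha_tilde` absorbs both the per-interaction expression loss in scaled
#' concentration units (`m / n_ss`) and the number of interaction partners
#' (`N - 1`). Use this mapping when matching a finite-N stochastic simulation
#' against the mean-field equation.
#'
#' @param params a [model_params()] record.
#' @return The colony-level `alpha_tilde = alpha * (m / n_ss) * (N - 1)`.
#' @export
alpha_tilde_match <- function(params) {
  params <- validate_model_params(params)
  params$alpha * (params$m / params$n_ss) * (params$N - 1L)
}

#' Steady-state mean expression of the mean-field colony
#'
#' At any steady state of the mean-field dynamics the colony mean satisfies
#' `rbar = 1 - alpha_tilde * rbar^2 / 2` exactly (the factor 1/2 comes from the
#' complement identity of the kernel: summed over ordered pairs, every
#' encounter represses exactly one of the two insects). The positive root is
#' `rbar = (sqrt(2 * alpha_tilde + 1) - 1) / alpha_tilde`, which tends to 1 as
#' `alpha_tilde -> 0` (no interactions: everyone at the molecular attractor).
#'
#' @param alpha_tilde colony-level rescaled interaction rate, >= 0.
#' @return Steady-state mass-weighted mean expression, in `(0, 1]`.
#' @export
steady_mean_expression <- function(alpha_tilde) {
  if (any(alpha_tilde < 0)) stop("alpha_tilde must be >= 0", call. = FALSE)
  # series for small coupling avoids catastrophic cancellation in the root
  ifelse(alpha_tilde < 1e-6,
         1 - alpha_tilde / 2 + alpha_tilde^2 / 2,
         (sqrt(2 * alpha_tilde + 1) - 1) / pmax(alpha_tilde, 1e-12))
}

#' Worker attractor of the microscopic dynamics
#'
#' Expression level at which production balances degradation plus repression
#' for an insect dominated by the whole colony: `r2 = 1 / (1 + alpha_tilde *
#' rbar)`, where `rbar` is the mass-weighted colony mean. Together with the
#' queen attractor `r0 = 1` (an insect dominated by nobody) these are the two
#' stable molecular states in the bistable regime.
#'
#' @inheritParams steady_mean_expression
#' @param rbar colony mean expression; defaults to the self-consistent steady
#'   value [steady_mean_expression()].
#' @return Worker fixed-point expression level in `(0, 1]`.
#' @export
worker_attractor <- function(alpha_tilde, rbar = steady_mean_expression(alpha_tilde)) {
  1 / (1 + alpha_tilde * rbar)
}

#' Default queen classification threshold
#'
#' Parameter-free separatrix proxy: the midpoint of the queen (`r0 = 1`) and
#' worker ([worker_attractor()]) fixed points at the steady colony mean.
#'
#' @inheritParams steady_mean_expression
#' @return Threshold on scaled expression in `(0, 1)`.
#' @export
queen_threshold <- function(alpha_tilde) {
  (1 + worker_attractor(alpha_tilde)) / 2
}

# ---- parameter config round trip ------------------------------------------

.param_fields <- c("N", "mu", "delta", "Gamma", "omega", "m", "alpha",
                   "lambda_asym", "alpha_tilde", "n_ss")

#' Read / write model parameters as a YAML config
#'
#' Parameters round-trip through a plain key-value YAML file. Unknown keys are
#' rejected so that typos in hand-edited configs fail loudly instead of being
#' silently ignored.
#'
#' @param params a [model_params()] record.
#' @param path file path of the YAML config.
#' @return `write_model_params()` returns `path` invisibly;
#'   `read_model_params()` returns a validated [model_params()] record.
#' @export
write_model_params <- function(params, path) {
  params <- validate_model_params(params)
  yaml::write_yaml(unclass(params)[.param_fields], path)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  x <- yaml::read_yaml(path)
  unknown <- setdiff(names(x), .param_fields)
  if (length(unknown))
    stop("unknown parameter key(s) in config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(.param_fields, names(x))
  if (length(missing))
    stop("missing parameter key(s) in config: ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(model_params, x)
}
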