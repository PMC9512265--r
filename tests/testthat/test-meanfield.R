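test_that("drift velocity reduces to the molecular scale for an empty colony", {
  d <- population_density(n_cells = 100)  # zero mass
  r <- c(0, 0.5, 1, 1.4)
  expect_equal(drift_velocity(r, d, alpha_tilde = 2, lambda_asym = 24), 1 - r)
  expect_error(drift_velocity(-0.1, d, 1, 24), ">= 0")
})

test_that("uncoupled transport advects all mass to the molecular attractor", {
  d0 <- density_gaussian(center = 0.2, n_cells = 300)
  tr <- evolve_density(d0, alpha_tilde = 0, lambda_asym = 24, duration = 8)
  expect_lt(tr$mass_drift, 1e-9)
  expect_equal(density_mass(tr$final), 1, tolerance = 1e-9)
  expect_equal(density_mean(tr$final), 1, tolerance = 0.02)
  expect_true(all(tr$final$f >= 0))
})

test_that("steady colony mean matches the self-consistency root and refines with the grid", {
  at <- 1
  d300 <- meanfield_steady(at, 24, n_cells = 300, duration = 40)
  expect_equal(density_mean(d300), steady_mean_expression(at),
               tolerance = 0.01)
  d150 <- meanfield_steady(at, 24, n_cells = 150, duration = 40)
  # grid refinement changes the steady mean by less than the cell width
  expect_lt(abs(density_mean(d300) - density_mean(d150)), 1.5 / 150)
})

test_that("tracer fixed points under the frozen colony reproduce both attractors", {
  for (at in c(0.5, 1, 2)) {
    rb <- steady_mean_expression(at)
    fp <- tracer_fixed_points(at, 24, rbar = rb)
    stable <- fp$r[fp$stability == "stable"]
    expect_gte(length(stable), 2)  # bistable
    expect_lt(abs(min(stable) - worker_attractor(at, rb)), 0.02)
    expect_lt(abs(max(stable) - 1), 0.02)
    # one unstable point (separatrix) between the attractors
    sep <- fp$r[fp$stability == "unstable"]
    expect_true(any(sep > min(stable) & sep < max(stable)))
  }
})

test_that("the colony structure acts as a saddle-node bifurcation parameter", {
  # a sparse colony leaves only the queen state
  fp0 <- tracer_fixed_points(2, 24, rbar = 0.05)
  expect_equal(nrow(fp0), 1L)
  expect_equal(fp0$r, 1, tolerance = 0.01)

  bd <- bifurcation_diagram(2, 24, rbar_seq = seq(0.05, 1, by = 0.02))
  expect_equal(nrow(bd$fold), 1L)  # fold located inside the sweep
  # below the fold: single branch; above: worker + separatrix + queen
  n_by_rbar <- table(bd$branches$rbar)
  expect_true(any(n_by_rbar == 1) && any(n_by_rbar == 3))
  # at the fold the two non-queen roots coincide: check near-tangency
  fp_at <- tracer_fixed_points(2, 24, rbar = bd$fold$rbar + 0.02)
  low2 <- sort(fp_at$r)[1:2]
  expect_lt(diff(low2), 0.2)
  # no fold in a sweep that stays below it -> empty result, not an error
  bd0 <- bifurcation_diagram(2, 24, rbar_seq = seq(0.05, 0.2, by = 0.05))
  expect_equal(nrow(bd0$fold), 0L)
})

test_that("phase portrait arrows, tracers and separatrix behave as constructed", {
  pp <- phase_portrait(1, 24, tracer_starts = data.frame(rbar = 0.1, r = 0.1),
                       duration = 25)
  expect_true(pp$converged)
  rb <- pp$rbar_steady
  expect_equal(rb, steady_mean_expression(1))
  # separatrix lies between the attractors
  expect_gt(pp$separatrix, worker_attractor(1, rb))
  expect_lt(pp$separatrix, 1)
  # a queenless colony rises collectively: tracer and mean increase together
  tr <- pp$tracers[[1]]
  expect_gt(max(tr$rbar), 0.5)
  expect_gt(tr$r[nrow(tr)], 0.3)
  # tracer fates: started at the attractors stays there
  fp <- tracer_fixed_points(1, 24, rbar = rb)
  stable <- fp$r[fp$stability == "stable"]
  pq <- phase_portrait(1, 24, tracer_starts = data.frame(
    rbar = c(rb, rb), r = c(max(stable), pp$separatrix - 0.05)),
    duration = 25)
  expect_equal(pq$tracers[[1]]$r[2501], max(stable), tolerance = 0.02)
  expect_equal(pq$tracers[[2]]$r[2501], min(stable), tolerance = 0.05)
})

test_that("intrinsic perturbations are suppressed, extrinsic queen removal reprograms", {
  at <- 1
  steady <- meanfield_steady(at, 24, n_cells = 300, duration = 40)
  fp <- tracer_fixed_points(at, 24, density = steady)
  r_w <- min(fp$r[fp$stability == "stable"])
  gap <- min(fp$r[fp$stability == "unstable" & fp$r > r_w]) - r_w

  z <- perturb_and_classify(steady, "intrinsic", 0, at, 24)
  expect_equal(z$outcome, "suppressed")
  expect_equal(z$displacement, 0, tolerance = 1e-6)
  small <- perturb_and_classify(steady, "intrinsic", 0.5 * gap, at, 24)
  expect_equal(small$outcome, "suppressed")

  ext <- perturb_and_classify(steady, "extrinsic", 1, at, 24, duration = 40)
  expect_equal(ext$outcome, "reprogrammed")
  expect_gt(ext$r_final, ext$r_start)

  expect_error(perturb_and_classify(steady, "intrinsic", -2, at, 24),
               "negative")
  expect_error(perturb_and_classify(steady, "extrinsic", 2, at, 24),
               "fraction")
})
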