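test_that("simulation is exactly reproducible for fixed (params, seed)", {
  p <- tiny_params(alpha = 4.6)
  a <- simulate_reduced(p, horizon = 5, seed = 42)
  b <- simulate_reduced(p, horizon = 5, seed = 42)
  expect_identical(a$n, b$n)
  expect_identical(a$events, b$events)
  c <- simulate_reduced(p, horizon = 5, seed = 43)
  expect_false(identical(a$n, c$n))

  pf <- tiny_params(alpha = 1, omega = 1, Gamma = 10)
  fa <- simulate_full(pf, horizon = 5, seed = 7)
  fb <- simulate_full(pf, horizon = 5, seed = 7)
  expect_identical(fa$n, fb$n)
  expect_true(all(fa$n >= 0))
  expect_true(all(fa$q %in% 0:1))
})

test_that("without interactions each insect is a Poisson birth-death process", {
  # stationary law of the linear birth-death process: n ~ Poisson(n_ss)
  p <- model_params(N = 5, alpha = 0, n_ss = 50)
  tr <- simulate_reduced(p, r_init = 1, horizon = 400, seed = 1,
                         record_events = FALSE)
  n <- as.vector(tr$n[tr$times > 40, ])
  expect_equal(mean(n), 50, tolerance = 0.03)
  expect_equal(stats::var(n), 50, tolerance = 0.12)
  expect_equal(nrow(tr$events), 0L)
  # full model with omega = 0 reduces to the same independent process
  pf <- model_params(N = 5, alpha = 0, omega = 0, Gamma = 1, n_ss = 50)
  tf <- simulate_full(pf, r_init = 1, horizon = 400, seed = 2,
                      record_events = FALSE)
  nf <- as.vector(tf$n[tf$times > 40, ])
  expect_equal(mean(nf), 50, tolerance = 0.03)
  expect_equal(stats::var(nf), 50, tolerance = 0.12)
  expect_true(all(tf$q == 0))
})

test_that("permanently repressed insects lose their gene products", {
  # q = 1 with Gamma = 0: production is switched off, n decays to 0
  p <- model_params(N = 4, alpha = 0, omega = 0, Gamma = 0)
  tr <- simulate_full(p, r_init = 1, q_init = 1, horizon = 12, seed = 3)
  expect_true(all(tr$n[nrow(tr$n), ] == 0))
  expect_true(all(tr$q == 1))
})

test_that("full model matches the reduced model when repression episodes are short", {
  # Gamma >> interaction rate: each episode removes ~ mu/Gamma products, so
  # full(omega, Gamma) ~ reduced(alpha = omega, m = mu/Gamma)
  N <- 8
  pr <- model_params(N = N, alpha = 1, lambda_asym = 24, m = 5)
  pf <- model_params(N = N, alpha = 1, lambda_asym = 24, omega = 1, Gamma = 10)
  tr <- simulate_reduced(pr, r_init = 1, horizon = 250, seed = 3,
                         record_events = FALSE)
  tf <- simulate_full(pf, r_init = 1, horizon = 250, seed = 4,
                      record_events = FALSE)
  a <- as.vector(tr$r[tr$times > 50, ])
  b <- as.vector(tf$r[tf$times > 50, ])
  expect_lt(abs(mean(a) - mean(b)), 0.06)
  ks <- suppressWarnings(stats::ks.test(a, b))$statistic
  expect_lt(unname(ks), 0.15)
  # deterministic-refractory variant runs and stays non-negative
  td <- simulate_full(pf, r_init = 1, horizon = 20, seed = 5,
                      repression = "deterministic")
  expect_true(all(td$n >= 0))
})

test_that("social structure classification counts insects above threshold", {
  expect_equal(classify_social_structure(rep(1, 5), 0.6), "all-queen")
  expect_equal(classify_social_structure(c(1, 0.1, 0.1), 0.6), "single-queen")
  expect_equal(classify_social_structure(c(1, 0.9, 0.1), 0.6), "multiple-queen")
  expect_equal(classify_social_structure(c(0.2, 0.1), 0.6), "no-queen")
  expect_error(classify_social_structure(numeric(0), 0.6), "non-empty")
  expect_error(classify_social_structure(c(1, 0), 1.2), "threshold")
})

test_that("phase diagram reproduces the qualitative social-structure map", {
  p <- model_params(N = 16, m = 5, n_ss = 50)
  pd <- phase_diagram(alpha_grid = c(0, 20), lambda_grid = c(0, 24),
                      replicates = 4, params = p, seed = 5, horizon = 50)
  expect_equal(nrow(pd), 4L)
  # no repression: everyone reaches the molecular attractor
  expect_true(all(pd$modal[pd$alpha == 0] == "all-queen"))
  # frequent asymmetric interactions: a single queen emerges
  expect_equal(pd$modal[pd$alpha == 20 & pd$lambda == 24], "single-queen")
  # frequent symmetric interactions suppress everyone (regression fixture)
  expect_equal(pd$modal[pd$alpha == 20 & pd$lambda == 0], "no-queen")
  expect_true(all(abs(rowSums(as.matrix(pd[, 3:6])) - 1) < 1e-12))
  expect_error(phase_diagram(numeric(0), 1, params = p), "non-empty")
})

test_that("queen removal triggers transient multi-layer states and replacement", {
  p <- model_params(N = 16, alpha = 20, lambda_asym = 24)
  qr <- queen_removal_experiment(p, seed = 201, burn_in = 60,
                                 post_horizon = 60)
  expect_equal(ncol(qr$post$n), 15L)
  post_egg <- qr$egg_layers$egg_layers[qr$egg_layers$phase == "post"]
  expect_gt(max(post_egg), 1)           # transient co-breeders
  expect_false(is.na(qr$replacement_time))
  expect_true(all(c("pre", "post") %in% qr$activity$phase))
  expect_gt(qr$post_arousal, 0)

  # removing one of many identical unsuppressed insects changes nothing
  p0 <- model_params(N = 8, alpha = 0)
  qr0 <- queen_removal_experiment(p0, seed = 1, burn_in = 30,
                                  post_horizon = 30, r_init = 1,
                                  threshold = 0.6)
  expect_equal(classify_social_structure(final_snapshot(qr0$post, 5), 0.6),
               "all-queen")
  expect_error(queen_removal_experiment(model_params(N = 1), seed = 1),
               "N >= 2")
})

test_that("trajectories export to long format and to the event-log schema", {
  p <- tiny_params(alpha = 4.6)
  tr <- simulate_reduced(p, horizon = 3, seed = 9)
  df <- as.data.frame(tr)
  expect_named(df, c("time", "insect", "n", "q", "r"))
  expect_equal(nrow(df), length(tr$times) * p$N)
  expect_true(all(diff(tr$times) > 0))

  ev <- trajectory_event_log(tr, phase = "control", hours_per_unit = 30)
  expect_equal(sum(ev$type == "DOM"), sum(ev$type == "SUB"))
  expect_equal(nrow(ev), 2L * nrow(tr$events))
  idx <- behavior_indices(ev, data.frame(individual = sprintf("w%02d", 1:8),
                                         hours = 3 * 30))
  expect_equal(sum(idx$dom), sum(idx$sub))
})
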