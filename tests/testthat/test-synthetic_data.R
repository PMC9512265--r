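test_that("generators are fully deterministic under a fixed seed", {
  sc <- nest_scenario(seed = 11, n_genes = 300, n_queen_genes = 20,
                      n_frames = 4)
  expect_identical(generate_events(sc), generate_events(sc))
  expect_identical(generate_expression(sc, phases = "control"),
                   generate_expression(sc, phases = "control"))
  expect_identical(generate_frames(sc, "control"),
                   generate_frames(sc, "control"))
  sc2 <- nest_scenario(seed = 12, n_genes = 300, n_queen_genes = 20,
                       n_frames = 4)
  expect_false(identical(generate_events(sc), generate_events(sc2)))
})

test_that("control-phase dominance concentrates on the queen at rate 1 - error", {
  # long horizon: the queen's dominance index converges to 1 - error_rate
  sc <- nest_scenario(N = 8, seed = 13, error_rate = 0.1,
                      phase_hours = c(control = 24 * 40, eggless = 1, D1 = 1,
                                      D4 = 1, D14 = 1))
  ev <- generate_events(sc)
  ctrl <- ev[ev$phase == "control", ]
  idx <- behavior_indices(ctrl, scenario_hours(sc, "control"))
  q <- idx[idx$individual == sc$queen, ]
  n_f <- q$dom + q$sub
  expect_lt(abs(q$dominance_index - 0.9), 3 * sqrt(0.1 * 0.9 / n_f))
  # workers almost never dominate
  w <- idx[idx$individual != sc$queen, ]
  expect_true(all(w$dominance_index < 0.5, na.rm = TRUE))
})

test_that("the eggless phase elevates the per-capita fighting rate", {
  sc <- nest_scenario(seed = 14, eggless_factor = 3,
                      phase_hours = c(control = 48, eggless = 48, D1 = 1,
                                      D4 = 1, D14 = 1))
  ev <- generate_events(sc)
  rate <- function(ph) {
    n_ids <- nrow(scenario_hours(sc, ph))
    sum(ev$phase == ph & ev$type %in% c("DOM", "SUB")) / n_ids / 2
  }
  expect_equal(rate("eggless") / rate("control"), 3, tolerance = 0.35)
  # zero rate: no fights at all
  sc0 <- nest_scenario(seed = 15, fight_rate_per_day = 0,
                       neutral_rate_per_day = 0, foraging_rate_per_day = 0)
  expect_equal(nrow(generate_events(sc0)), 0L)
})

test_that("expression tables carry the configured queen-gene and ovary structure", {
  sc <- nest_scenario(seed = 16, n_genes = 1200, n_queen_genes = 60)
  ex <- generate_expression(sc)
  # queens exceed the ovary maturity threshold; control workers do not
  s <- ex$samples
  ctrl_q <- s[s$individual == "control_w01", ]
  expect_gte(ctrl_q$ovary_mm, 1.5)
  expect_true(all(s$ovary_mm[s$phase == "control" &
                               s$individual != "control_w01"] < 1.5))
  # D4 collective upregulation raises queen-profile correlation of workers
  qc <- queen_profile_correlation(ex, reference_queens = "control_w01")
  workers <- qc$individual != "control_w01"
  m <- tapply(qc$queen_correlation[workers], qc$phase[workers], mean)
  expect_gt(m[["D4"]], m[["control"]] + 0.1)
  # ovary size tracks the queen-gene score
  score <- attr(ex, "queen_score")
  expect_gt(stats::cor(score, s$ovary_mm), 0.9)
})

test_that("a zero methylation-noise slope yields a null coupling", {
  sc <- nest_scenario(seed = 17, n_genes = 1000, n_queen_genes = 40,
                      meth_slope = 0)
  ex <- generate_expression(sc, phases = "control")
  vf <- variable_fraction_by_methylation(ex)
  expect_lt(abs(vf$correlation$estimate), 0.15)
  # ground-truth noise is flat in methylation
  expect_equal(stats::sd(attr(ex, "noise_sd")), 0)
})

test_that("frame stacks move at the configured per-phase speed", {
  sc <- nest_scenario(seed = 18, n_frames = 8,
                      speeds = c(control = 0, eggless = 3, D1 = 1.5,
                                 D4 = 1.2, D14 = 1))
  expect_equal(max(global_activity(generate_frames(sc, "control"), sc$N)), 0)
  sc2 <- nest_scenario(seed = 18, n_frames = 8)
  act_c <- mean(global_activity(generate_frames(sc2, "control"), sc2$N))
  act_e <- mean(global_activity(generate_frames(sc2, "eggless"), sc2$N - 1))
  expect_gt(act_e, act_c)
  # sub-diameter speeds: activity increases monotonically with speed
  acts <- sapply(c(0.5, 1.5, 2.5), function(v) {
    s <- nest_scenario(seed = 19, n_frames = 10,
                       speeds = c(control = v, eggless = 3, D1 = 1, D4 = 1,
                                  D14 = 1))
    mean(global_activity(generate_frames(s, "control"), s$N))
  })
  expect_true(all(diff(acts) > 0))
})
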