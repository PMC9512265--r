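test_that("behavioural indices follow their defining ratios", {
  ev <- toy_log()   # A: DOM 3, SUB 1, ANT 4 over 2 h
  hrs <- data.frame(individual = c("A", "B", "C", "D"), hours = 2)
  idx <- behavior_indices(ev, hrs)
  a <- idx[idx$individual == "A", ]
  expect_equal(a$interaction_rate, 4)
  expect_equal(a$fight_index, 0.5)
  expect_equal(a$dominance_index, 0.75)
  # present but silent individual: zero rate, undefined indices
  d <- idx[idx$individual == "D", ]
  expect_equal(d$interaction_rate, 0)
  expect_true(is.na(d$fight_index) && is.na(d$dominance_index))
  # only neutral interactions: defined fight index of 0, undefined dominance
  ant <- event_log(0.1, "E", "F", "ANT", "control")
  i2 <- behavior_indices(ant, data.frame(individual = "E", hours = 1))
  expect_equal(i2$fight_index, 0)
  expect_true(is.na(i2$dominance_index))
  # bounds
  expect_true(all(idx$fight_index >= 0 & idx$fight_index <= 1, na.rm = TRUE))
  expect_true(all(idx$dominance_index >= 0 & idx$dominance_index <= 1,
                  na.rm = TRUE))
})

test_that("event logs enforce their schema and pairing invariant", {
  expect_error(event_log(0.1, "A", "B", "BITE", "control"),
               "unknown interaction type 'BITE' in row 1")
  expect_error(event_log(0.1, "A", "B", "DOM", "D9"), "unknown phase")
  expect_error(event_log(-1, "A", "B", "DOM", "control"), ">= 0")
  # single-row dominance dialects expand to paired rows
  one_row <- data.frame(time_h = 0.2, actor = "A", recipient = "B",
                        type = "DOM", phase = "control")
  ex <- expand_dominance(one_row)
  expect_equal(sum(ex$type == "DOM"), sum(ex$type == "SUB"))
  expect_equal(ex$actor[ex$type == "SUB"], "B")
  # synthetic logs satisfy the invariant by construction
  ev <- generate_events(nest_scenario(seed = 2))
  expect_equal(sum(ev$type == "DOM"), sum(ev$type == "SUB"))
})

test_that("observables are invariant to the row order of their inputs", {
  ev <- toy_log()
  hrs <- data.frame(individual = c("A", "B", "C"), hours = 2)
  set.seed(4)
  shuffled <- ev[sample(nrow(ev)), ]
  expect_equal(behavior_indices(shuffled, hrs), behavior_indices(ev, hrs))
  expect_equal(subdominant_rate(shuffled, 10, 1), subdominant_rate(ev, 10, 1))
})

test_that("subdominant rate mirrors the census-normalized daily statistic", {
  ev <- event_log(rep(0.5, 74), rep("w", 74), rep("q", 74), rep("SUB", 74),
                  "control")
  expect_equal(subdominant_rate(ev, census_N = 20, observation_days = 1), 3.7)
  empty <- ev[0, ]
  expect_equal(subdominant_rate(empty, 20, 1), 0)
  expect_error(subdominant_rate(ev, 0, 1), "census")
})

test_that("global activity is the normalized mean absolute frame difference", {
  f <- matrix(0.5, 40, 40)
  expect_equal(global_activity(list(f, f, f), n_wasps = 4), c(0, 0))
  # one displaced disk of area A changes ~2A pixels
  f1 <- matrix(0, 50, 50); f2 <- f1
  f1[10:14, 10:14] <- 1; f2[30:34, 30:34] <- 1
  expect_equal(global_activity(list(f1, f2), 1) * 2500, 50)
  # normalization: doubling the wasp count halves activity
  expect_equal(global_activity(list(f1, f2), 2),
               global_activity(list(f1, f2), 1) / 2)
  expect_equal(global_activity(list(f1, f2), 1, spatial_scale = 2),
               global_activity(list(f1, f2), 1) / 4)
  expect_error(global_activity(list(f1), 1), "at least 2")
  expect_error(global_activity(list(f1, matrix(0, 10, 10)), 1), "identical")
})

test_that("queen-profile correlation scores queen-likeness", {
  set.seed(7)
  g <- sprintf("g%02d", 1:20)
  ref <- rnorm(20, 5)
  vals <- cbind(queen = ref, same = ref + 0.5,
                anti = -ref + 2 * mean(ref), flat = rep(3, 20))
  rownames(vals) <- g
  expr <- expression_table(
    vals,
    genes = data.frame(gene = g, queen_gene = TRUE, methylation = 0.1),
    samples = data.frame(individual = colnames(vals), phase = "control",
                         ovary_mm = c(2, 0.4, 0.4, 0.4)))
  qc <- suppressWarnings(queen_profile_correlation(expr, "queen"))
  expect_equal(qc$queen_correlation[qc$individual == "same"], 1)
  expect_equal(qc$queen_correlation[qc$individual == "anti"], -1)
  expect_true(is.na(qc$queen_correlation[qc$individual == "flat"]))
  expect_warning(queen_profile_correlation(expr, "queen"), "zero-variance")
  expect_error(queen_profile_correlation(expr, "queen", queen_genes = g[1]),
               "at least 2")
  expect_error(queen_profile_correlation(expr, "nobody"), "not found")
})

test_that("methylation-noise coupling is detected by the over-dispersion screen", {
  sc <- nest_scenario(seed = 31, n_genes = 1500, n_queen_genes = 50,
                      meth_slope = 1.5)
  ex <- generate_expression(sc, phases = "control")
  vf <- variable_fraction_by_methylation(ex)
  expect_lt(vf$correlation$estimate, -0.3)
  expect_lt(vf$correlation$p.value, 0.001)
  # low-methylation genes are the noisy ones
  frac <- vf$bins$fraction_variable
  expect_gt(frac[1], utils::tail(frac[!is.na(frac)], 1))
  expect_true(all(vf$genes$p_adj >= vf$genes$p, na.rm = TRUE))  # BH property
  expect_error(variable_fraction_by_methylation(ex, bins = 1), "at least 2")
})

test_that("phase comparisons use rank tests with BH correction", {
  set.seed(11)
  values <- c(rnorm(12), rnorm(12) + 3, rnorm(12))
  phase <- rep(c("control", "eggless", "D14"), each = 12)
  out <- compare_phases(values, phase)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$p_adj >= out$p))
  expect_lt(out$p_adj[out$phase1 == "control" & out$phase2 == "eggless"], 0.05)
  # identical samples: no evidence of a shift
  same <- compare_phases(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$p_adj, 1)
  # paired mode consumes pairing identifiers
  paired <- compare_phases(c(1:6, 3:8), rep(c("a", "b"), each = 6),
                           pair_id = rep(1:6, 2))
  expect_lt(paired$p, 0.05)
  # insufficient observations degrade to NA, not an error
  na_out <- compare_phases(c(1, 2, 3), c("a", "a", "b"))
  expect_true(is.na(na_out$p))
})

test_that("ovary maturity uses the inclusive 1.5 mm threshold", {
  expect_equal(classify_ovary(c(1.5, 0.4, 1.4999, 2.3)),
               c("mature", "immature", "immature", "mature"))
  expect_error(classify_ovary(-0.1), "egg length")
})
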