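test_that("event logs and expression tables round-trip through CSV", {
  ev <- generate_events(nest_scenario(seed = 3))
  path <- tempfile(fileext = ".csv")
  write_event_log(ev, path)
  back <- read_event_log(path)
  rownames(ev) <- rownames(back) <- NULL
  expect_equal(back, ev)

  ex <- generate_expression(nest_scenario(seed = 3, n_genes = 200,
                                          n_queen_genes = 10),
                            phases = c("control", "D4"))
  base <- tempfile()
  write_expression_table(ex, base)
  back_ex <- read_expression_table(base)
  expect_equal(back_ex$values, ex$values, tolerance = 1e-12)
  expect_equal(back_ex$genes, ex$genes, tolerance = 1e-12)
  expect_equal(back_ex$samples, ex$samples, tolerance = 1e-12)
})

test_that("densities and trajectories round-trip through delimited text", {
  d <- density_gaussian(center = 0.4, n_cells = 120)
  path <- tempfile(fileext = ".csv")
  write_density(d, path)
  back <- read_density(path)
  expect_equal(back$f, d$f, tolerance = 1e-10)
  expect_equal(back$centers, d$centers, tolerance = 1e-10)

  tr <- simulate_reduced(tiny_params(), horizon = 2, seed = 1)
  tpath <- tempfile(fileext = ".csv")
  write_trajectory(tr, tpath)
  df <- read_trajectory_frame(tpath)
  expect_equal(nrow(df), length(tr$times) * 8)
  expect_equal(max(df$time), max(tr$times))
})

test_that("frame stacks round-trip through 8-bit PNG", {
  skip_if_not_installed("png")
  frames <- generate_frames(nest_scenario(seed = 4, n_frames = 3,
                                          frame_size = c(40, 60)), "control")
  dir <- tempfile()
  write_frames(frames, dir)
  back <- read_frames(dir)
  expect_equal(length(back), 3L)
  # loss only at the documented 8-bit precision
  expect_lt(max(abs(back[[1]] - frames[[1]])), 1 / 255)
})

test_that("scenario directories materialize deterministically", {
  sc <- nest_scenario(seed = 6, n_genes = 150, n_queen_genes = 10)
  d1 <- tempfile(); d2 <- tempfile()
  write_scenario(sc, d1, frames = FALSE)
  write_scenario(sc, d2, frames = FALSE)
  expect_true(file.exists(file.path(d1, "events.csv")))
  expect_true(file.exists(file.path(d1, "ground_truth.yaml")))
  expect_identical(readLines(file.path(d1, "events.csv")),
                   readLines(file.path(d2, "events.csv")))
  expect_identical(readLines(file.path(d1, "expression_values.csv")),
                   readLines(file.path(d2, "expression_values.csv")))
  truth <- yaml::read_yaml(file.path(d1, "ground_truth.yaml"))
  expect_equal(truth$fight_rate_per_day, sc$fight_rate_per_day)
})

test_that("the CLI evaluates, validates and fails loudly", {
  out <- capture.output(
    status <- run_cli(c("persistence", "--R", "4.6", "--N", "20",
                        "--Tint-hours", "6.5217")))
  expect_equal(status, 0L)
  expect_match(out, "65.6", fixed = TRUE)
  expect_match(out, "2.73", fixed = TRUE)

  # schema violation in an event log: non-zero exit naming the row
  bad <- data.frame(time_h = 0.1, actor = "A", recipient = "B",
                    type = "POKE", phase = "control")
  path <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path, row.names = FALSE)
  expect_message(
    st <- run_cli(c("observe", "--events", path, "--hours", "2")),
    "unknown interaction type 'POKE' in row 1")
  expect_equal(st, 2L)

  expect_message(st2 <- run_cli("frobnicate"), "unknown subcommand")
  expect_equal(st2, 2L)
  expect_message(st3 <- run_cli(c("persistence", "--R")), "needs a value")
  expect_equal(st3, 2L)

  # synth twice with one seed: byte-identical event logs
  d1 <- tempfile(); d2 <- tempfile()
  expect_equal(run_cli(c("synth", "--seed", "1", "--N", "6", "--out", d1,
                         "--frames", "false")), 0L)
  expect_equal(run_cli(c("synth", "--seed", "1", "--N", "6", "--out", d2,
                         "--frames", "false")), 0L)
  expect_identical(readLines(file.path(d1, "events.csv")),
                   readLines(file.path(d2, "events.csv")))
})
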