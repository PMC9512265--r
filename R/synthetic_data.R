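# Seeded synthetic-data generators.
#
# These generators produce every input the analysis pipeline consumes, with
# the statistical structure the analysis assumes: control versus queen-removed
# nest phases, dominance asymmetry concentrated on the highest-expressing
# individual, collective queen-gene upregulation after queen removal,
# expression noise decreasing with gene-body methylation, and ovary size
# increasing with queen-gene expression. Every generator exposes its ground
# truth so downstream operations can be tested as estimator-recovery problems.

#' Synthetic nest scenario
#'
#' Defines a complete synthetic study: a colony followed through the
#' experimental phase schedule (unmanipulated control, then queen removal with
#' the eggless phase until a new egg appears, and D1/D4/D14 counted from
#' renewed egg laying), with behavioural, transcriptomic and imaging ground
#' truth. Defaults mirror the scale of field-monitored colonies: a colony of 16
#' insects, 45 min of video per phase, 3.7 fighting interactions per
#' individual per day, ~10,000 genes of which 200 are queen genes.
#'
#' @param N colony size (>= 2).
#' @param phase_hours named durations (hours) of the observation window in
#'   each phase.
#' @param fight_rate_per_day true per-capita fighting rate: expected number of
#'   fight rows (DOM or SUB involvement) per individual per day in the control
#'   phase.
#' @param eggless_factor multiplicative elevation of the fighting rate in the
#'   eggless phase, during which the whole colony contests the succession.
#' @param asymmetry if `TRUE`, control-phase dominance is concentrated on the
#'   queen: she wins each of her fights with probability `1 - error_rate`.
#'   If `FALSE`, fight outcomes are symmetric in every phase.
#' @param error_rate probability that the queen loses a fight when asymmetry
#'   is on.
#' @param neutral_rate_per_day per-capita rate of neutral interactions
#'   (antennation/trophallaxis rows).
#' @param foraging_rate_per_day per-capita rate of foraging exchanges
#'   (DEC/REC rows).
#' @param n_genes,n_queen_genes transcriptome size and queen-gene set size.
#' @param queen_effect queen-gene upregulation in queen-like individuals
#'   (log2 fold change).
#' @param meth_slope methylation-noise coupling: per-gene expression noise sd
#'   is `noise_sd0 * exp(-meth_slope * methylation)`; 0 switches the coupling
#'   off (null model).
#' @param noise_sd0 expression noise sd (log2) at zero methylation.
#' @param frame_size,n_frames,disk_radius imaging geometry: frame dimensions
#'   (pixels), frames per phase, wasp disk radius.
#' @param speeds named per-phase wasp speeds in pixels per frame.
#' @param seed global seed; each generator uses an independent substream
#'   derived from it, and a fixed seed makes every output byte-identical.
#' @return A list of class `"nest_scenario"`; `individuals` are labelled
#'   `w01..wNN` with `w01` the control queen (removed after control) and `w02`
#'   the replacement queen.
#' @export
nest_scenario <- function(N = 16,
                          phase_hours = c(control = 0.75, eggless = 0.75,
                                          D1 = 0.75, D4 = 0.75, D14 = 0.75),
                          fight_rate_per_day = 3.7,
                          eggless_factor = 3,
                          asymmetry = TRUE,
                          error_rate = 1 / 17,
                          neutral_rate_per_day = 8,
                          foraging_rate_per_day = 2,
                          n_genes = 10000,
                          n_queen_genes = 200,
                          queen_effect = 1.5,
                          meth_slope = 1.5,
                          noise_sd0 = 0.8,
                          frame_size = c(120, 160),
                          n_frames = 20,
                          disk_radius = 3,
                          speeds = c(control = 1, eggless = 3, D1 = 1.5,
                                     D4 = 1.2, D14 = 1),
                          seed = 1) {
  if (N < 2) stop("'N' must be >= 2", call. = FALSE)
  if (any(phase_hours <= 0)) stop("phase durations must be > 0", call. = FALSE)
  if (fight_rate_per_day < 0 || neutral_rate_per_day < 0 ||
      foraging_rate_per_day < 0)
    stop("rates must be >= 0", call. = FALSE)
  if (error_rate < 0 || error_rate >= 1)
    stop("'error_rate' must be in [0, 1)", call. = FALSE)
  if (n_queen_genes < 2 || n_queen_genes > n_genes)
    stop("need 2 <= n_queen_genes <= n_genes", call. = FALSE)
  missing_ph <- setdiff(phase_levels, names(phase_hours))
  if (length(missing_ph))
    stop("phase_hours must name all phases: ",
         paste(missing_ph, collapse = ", "), call. = FALSE)
  structure(list(
    N = as.integer(N), phase_hours = phase_hours[phase_levels],
    fight_rate_per_day = fight_rate_per_day, eggless_factor = eggless_factor,
    asymmetry = asymmetry, error_rate = error_rate,
    neutral_rate_per_day = neutral_rate_per_day,
    foraging_rate_per_day = foraging_rate_per_day,
    n_genes = as.integer(n_genes), n_queen_genes = as.integer(n_queen_genes),
    queen_effect = queen_effect, meth_slope = meth_slope,
    noise_sd0 = noise_sd0, frame_size = as.integer(frame_size),
    n_frames = as.integer(n_frames), disk_radius = disk_radius,
    speeds = speeds[phase_levels],
    individuals = sprintf("w%02d", seq_len(N)),
    queen = "w01", replacement_queen = "w02",
    seed = as.integer(seed)), class = "nest_scenario")
}

scenario_sub_seed <- function(scenario, offset) {
  (scenario$seed * 7919L + offset * 104729L) %% .Machine$integer.max
}

#' Hours observed on the nest per individual in a phase
#'
#' @param scenario a [nest_scenario()].
#' @param phase phase label.
#' @return Data frame `individual`, `hours` for the individuals present in
#'   that phase (the control queen is absent after the control phase).
#' @export
scenario_hours <- function(scenario, phase = "control") {
  ids <- scenario$individuals
  if (phase != "control") ids <- setdiff(ids, scenario$queen)
  data.frame(individual = ids, hours = unname(scenario$phase_hours[phase]),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic interaction event log
#'
#' Poisson event streams per phase. In the control phase with asymmetry on,
#' fights involve the queen, who dominates with probability `1 - error_rate`;
#' in the eggless phase (queen removed) all individuals fight symmetrically at
#' an elevated rate. Fights produce paired DOM/SUB rows; neutral (ANT/TR) and
#' foraging (DEC/REC) events are added at their configured rates.
#'
#' @param scenario a [nest_scenario()].
#' @return A validated event log covering all phases.
#' @export
generate_events <- function(scenario) {
  stopifnot(inherits(scenario, "nest_scenario"))
  sc <- scenario
  with_seed(scenario_sub_seed(sc, 1L), {
    offset <- 0
    out <- list()
    for (ph in phase_levels) {
      hrs <- sc$phase_hours[[ph]]
      ids <- scenario_hours(sc, ph)$individual
      n_here <- length(ids)
      ruler <- switch(ph, control = sc$queen, eggless = NA_character_,
                      sc$replacement_queen)
      rate <- sc$fight_rate_per_day *
        (if (ph == "eggless") sc$eggless_factor else 1)
      # one fight = two rows; expected rows per capita per day = rate
      n_fight <- stats::rpois(1, rate / 24 * hrs * n_here / 2)
      if (n_fight > 0) {
        t_f <- offset + sort(stats::runif(n_fight, 0, hrs))
        if (sc$asymmetry && !is.na(ruler)) {
          workers <- setdiff(ids, ruler)
          opp <- sample(workers, n_fight, replace = TRUE)
          q_wins <- stats::runif(n_fight) >= sc$error_rate
          winner <- ifelse(q_wins, ruler, opp)
          loser <- ifelse(q_wins, opp, ruler)
        } else {
          pair <- replicate(n_fight, sample(ids, 2))
          winner <- pair[1, ]; loser <- pair[2, ]
        }
        out[[length(out) + 1L]] <- data.frame(
          time_h = c(t_f, t_f), actor = c(winner, loser),
          recipient = c(loser, winner),
          type = rep(c("DOM", "SUB"), each = n_fight), phase = ph,
          stringsAsFactors = FALSE)
      }
      for (spec in list(list(rate = sc$neutral_rate_per_day,
                             types = c("ANT", "TR")),
                        list(rate = sc$foraging_rate_per_day,
                             types = c("DEC", "REC")))) {
        n_ev <- stats::rpois(1, spec$rate / 24 * hrs * n_here / 2)
        if (n_ev > 0) {
          t_e <- offset + sort(stats::runif(n_ev, 0, hrs))
          pair <- replicate(n_ev, sample(ids, 2))
          symmetric <- spec$types[1] == "ANT"
          ty <- if (symmetric) sample(spec$types, n_ev, replace = TRUE)
                else rep(spec$types[1], n_ev)
          ty2 <- if (symmetric) ty else rep(spec$types[2], n_ev)
          out[[length(out) + 1L]] <- data.frame(
            time_h = c(t_e, t_e), actor = c(pair[1, ], pair[2, ]),
            recipient = c(pair[2, ], pair[1, ]),
            type = c(ty, ty2), phase = ph, stringsAsFactors = FALSE)
        }
      }
      offset <- offset + hrs
    }
    if (!length(out))
      return(event_log(numeric(0), character(0), character(0),
                       character(0), character(0)))
    ev <- do.call(rbind, out)
    validate_event_log(ev[order(ev$time_h, ev$type, ev$actor), ,
                          drop = FALSE])
  })
}

# Queen-likeness score per individual and phase: 1 = full queen profile.
# Control: only the queen; eggless/D1: succession under way; D4: collective
# upregulation in all individuals; D14: re-specialized around the new queen.
scenario_queen_score <- function(sc, phase, ids) {
  base <- switch(phase,
                 control = ifelse(ids == sc$queen, 1, 0.05),
                 eggless = rep(0.45, length(ids)),
                 D1 = ifelse(ids == sc$replacement_queen, 1, 0.45),
                 D4 = rep(1, length(ids)),
                 D14 = ifelse(ids == sc$replacement_queen, 1, 0.2))
  stats::setNames(base, ids)
}

#' Generate a synthetic expression table
#'
#' Log2-scale expression with a per-gene baseline, queen-gene upregulation
#' proportional to each individual's queen-likeness (the queen in control
#' nests; every individual in the D4 phase), and per-gene noise whose sd
#' decreases with gene-body methylation at the configured slope. Ovary sizes
#' increase with the individual's queen-gene score, so queens exceed the
#' 1.5 mm maturity threshold.
#'
#' @param scenario a [nest_scenario()].
#' @param phases phases to include (default all five).
#' @return An [expression_table()]; ground-truth per-gene noise sd is attached
#'   as `attr(, "noise_sd")` and queen scores as `attr(, "queen_score")`.
#' @export
generate_expression <- function(scenario, phases = phase_levels) {
  stopifnot(inherits(scenario, "nest_scenario"))
  sc <- scenario
  with_seed(scenario_sub_seed(sc, 2L), {
    G <- sc$n_genes
    gene_ids <- sprintf("g%05d", seq_len(G))
    queen_gene <- c(rep(TRUE, sc$n_queen_genes),
                    rep(FALSE, G - sc$n_queen_genes))
    meth <- stats::rbeta(G, 1.2, 4)
    baseline <- stats::rnorm(G, mean = 6, sd = 1.5)
    noise_sd <- sc$noise_sd0 * exp(-sc$meth_slope * meth)
    # gene-specific queen signature: a flat shift would leave the Pearson
    # profile correlation unchanged, so the upregulation varies across the
    # queen-gene set (mean log2 fold change = queen_effect)
    effect_g <- sc$queen_effect * stats::rexp(G) * queen_gene

    cols <- list(); samp <- list(); scores <- numeric(0)
    for (ph in phases) {
      ids <- scenario_hours(sc, ph)$individual
      u <- scenario_queen_score(sc, ph, ids)
      for (id in ids) {
        x <- baseline + effect_g * u[[id]] + stats::rnorm(G, sd = noise_sd)
        nm <- paste(ph, id, sep = "_")
        cols[[nm]] <- x
        scores[nm] <- u[[id]]
        samp[[nm]] <- data.frame(
          individual = nm, phase = ph,
          ovary_mm = max(0, 0.3 + 1.5 * u[[id]] + stats::rnorm(1, sd = 0.08)),
          stringsAsFactors = FALSE)
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- gene_ids
    out <- expression_table(
      values,
      genes = data.frame(gene = gene_ids, queen_gene = queen_gene,
                         methylation = meth, stringsAsFactors = FALSE),
      samples = do.call(rbind, samp))
    attr(out, "noise_sd") <- noise_sd
    attr(out, "queen_score") <- scores
    out
  })
}

#' Generate a synthetic frame stack
#'
#' N bright disks (wasps) moving on a static dark comb background with the
#' per-phase speed configured in the scenario; positions are integer pixels so
#' a zero speed yields exactly identical frames. Reflecting boundaries.
#'
#' @param scenario a [nest_scenario()].
#' @param phase phase whose speed to use.
#' @return List of `n_frames` grayscale matrices in `[0, 1]`; the true
#'   per-frame displacement is attached as `attr(, "speed")`.
#' @export
generate_frames <- function(scenario, phase = "control") {
  stopifnot(inherits(scenario, "nest_scenario"))
  sc <- scenario
  ph_idx <- match(phase, phase_levels)
  if (is.na(ph_idx)) stop("unknown phase '", phase, "'", call. = FALSE)
  if (sc$n_frames < 2) stop("need at least 2 frames", call. = FALSE)
  with_seed(scenario_sub_seed(sc, 10L + ph_idx), {
    h <- sc$frame_size[1]; w <- sc$frame_size[2]
    rad <- sc$disk_radius
    speed <- unname(sc$speeds[[phase]])
    n_w <- if (phase == "control") sc$N else sc$N - 1L
    pos <- cbind(stats::runif(n_w, rad + 1, h - rad - 1),
                 stats::runif(n_w, rad + 1, w - rad - 1))
    ang <- stats::runif(n_w, 0, 2 * pi)
    vel <- speed * cbind(cos(ang), sin(ang))
    dy <- outer(seq_len(h), rep(1, w)); dx <- outer(rep(1, h), seq_len(w))
    draw <- function(p) {
      fr <- matrix(0.2, h, w)
      for (i in seq_len(n_w)) {
        ci <- round(p[i, ])
        disk <- (dy - ci[1])^2 + (dx - ci[2])^2 <= rad^2
        fr[disk] <- 0.9
      }
      fr
    }
    frames <- vector("list", sc$n_frames)
    for (k in seq_len(sc$n_frames)) {
      frames[[k]] <- draw(pos)
      pos <- pos + vel
      for (ax in 1:2) {
        lim <- c(h, w)[ax]
        low <- pos[, ax] < rad + 1; high <- pos[, ax] > lim - rad - 1
        pos[low, ax] <- 2 * (rad + 1) - pos[low, ax]
        pos[high, ax] <- 2 * (lim - rad - 1) - pos[high, ax]
        vel[low | high, ax] <- -vel[low | high, ax]
      }
    }
    attr(frames, "speed") <- speed
    frames
  })
}

#' Materialize a complete synthetic scenario directory
#'
#' Writes the event log, the expression table trio, per-phase frame stacks
#' (if the `png` package is available) and a `ground_truth.yaml` record of the
#' generator parameters.
#'
#' @param scenario a [nest_scenario()].
#' @param dir output directory (created if needed).
#' @param frames whether to write PNG frame stacks.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir, frames = TRUE) {
  stopifnot(inherits(scenario, "nest_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_event_log(generate_events(scenario), file.path(dir, "events.csv"))
  write_expression_table(generate_expression(scenario),
                         file.path(dir, "expression"))
  if (frames && requireNamespace("png", quietly = TRUE)) {
    for (ph in phase_levels)
      write_frames(generate_frames(scenario, ph),
                   file.path(dir, paste0("frames_", ph)))
  }
  truth <- unclass(scenario)
  truth$phase_hours <- as.list(truth$phase_hours)
  truth$speeds <- as.list(truth$speeds)
  yaml::write_yaml(truth, file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}
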