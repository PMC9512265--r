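# Behavioural, imaging and expression observables.

interaction_types <- c("DOM", "SUB", "DEC", "REC", "TR", "ANT")
phase_levels <- c("control", "eggless", "D1", "D4", "D14")

#' Interaction event log
#'
#' Per-event behavioural records mirroring a video-annotation table. Each row
#' is one individual's role in one event: `DOM` domination over a nestmate,
#' `SUB` subordination, `DEC`/`REC` donor/receiver of foraging material, `TR`
#' trophallaxis, `ANT` antennation. Every dyadic fight is stored as two rows
#' (a `DOM` row for the winner and a `SUB` row for the loser at the same
#' time); use [expand_dominance()] to import single-row dialects.
#'
#' @param time_h event time in hours (>= 0).
#' @param actor,recipient individual identifiers.
#' @param type interaction type, one of `DOM, SUB, DEC, REC, TR, ANT`.
#' @param phase study phase, one of `control, eggless, D1, D4, D14`.
#' @return A validated `data.frame` with those columns.
#' @export
event_log <- function(time_h, actor, recipient, type, phase) {
  validate_event_log(data.frame(
    time_h = time_h, actor = actor, recipient = recipient,
    type = type, phase = phase, stringsAsFactors = FALSE))
}

validate_event_log <- function(events) {
  need <- c("time_h", "actor", "recipient", "type", "phase")
  missing <- setdiff(need, names(events))
  if (length(missing))
    stop("event log is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(!events$type %in% interaction_types)
  if (length(bad))
    stop("unknown interaction type '", events$type[bad[1]], "' in row ",
         bad[1], call. = FALSE)
  bad_ph <- which(!events$phase %in% phase_levels)
  if (length(bad_ph))
    stop("unknown phase '", events$phase[bad_ph[1]], "' in row ", bad_ph[1],
         call. = FALSE)
  if (any(events$time_h < 0))
    stop("event times must be >= 0", call. = FALSE)
  events
}

#' Expand a single-row dominance dialect into paired DOM/SUB rows
#'
#' Some annotation tables store one row per fight (`DOM`, actor = winner,
#' recipient = loser). This adds the mirrored `SUB` row for each `DOM` row
#' that lacks one, restoring the invariant that colony-wide DOM and SUB counts
#' are equal.
#'
#' @param events an event log data frame.
#' @return The expanded, validated event log.
#' @export
expand_dominance <- function(events) {
  events <- validate_event_log(events)
  if (sum(events$type == "DOM") == sum(events$type == "SUB"))
    return(events)
  dom <- events[events$type == "DOM", , drop = FALSE]
  sub <- data.frame(time_h = dom$time_h, actor = dom$recipient,
                    recipient = dom$actor, type = "SUB", phase = dom$phase,
                    stringsAsFactors = FALSE)
  validate_event_log(rbind(events[events$type != "SUB", , drop = FALSE],
                           events[events$type == "SUB", , drop = FALSE],
                           sub))
}

#' Per-individual behavioural indices
#'
#' For each individual present on the nest: the interaction rate (all six
#' types per hour observed), the fight index (`(DOM + SUB) / all
#' interactions`) and the dominance index (`DOM / (DOM + SUB)`). Individuals
#' present without any interaction get rate 0; the fight and dominance indices
#' are undefined (`NA`) when their denominators are zero.
#'
#' @param events an event log (see [event_log()]).
#' @param hours_observed data frame with columns `individual` and `hours`
#'   (> 0): per-individual time observed on the nest.
#' @return Data frame with one row per individual: `individual`,
#'   `interaction_rate` (per hour), `fight_index`, `dominance_index`, and the
#'   raw `dom`, `sub`, `total` counts.
#' @export
behavior_indices <- function(events, hours_observed) {
  events <- validate_event_log(events)
  if (any(hours_observed$hours <= 0))
    stop("observed time must be > 0 for present individuals", call. = FALSE)
  rows <- lapply(seq_len(nrow(hours_observed)), function(i) {
    id <- hours_observed$individual[i]
    mine <- events[events$actor == id, , drop = FALSE]
    dom <- sum(mine$type == "DOM"); sub <- sum(mine$type == "SUB")
    total <- nrow(mine)
    data.frame(
      individual = id,
      interaction_rate = total / hours_observed$hours[i],
      fight_index = if (total > 0) (dom + sub) / total else NA_real_,
      dominance_index = if (dom + sub > 0) dom / (dom + sub) else NA_real_,
      dom = dom, sub = sub, total = total, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-worker daily subdominant-interaction rate
#'
#' SUB events per census individual per day: a passive measure of how often a
#' typical colony member is dominated, normalized by the night-time census so
#' that individuals absent from the video are included in the denominator.
#'
#' @param events an event log.
#' @param census_N census size (>= 1).
#' @param observation_days observation time in days (> 0).
#' @return Daily subdominant interaction rate per individual.
#' @export
subdominant_rate <- function(events, census_N, observation_days) {
  events <- validate_event_log(events)
  if (census_N < 1) stop("'census_N' must be >= 1", call. = FALSE)
  if (observation_days <= 0) stop("'observation_days' must be > 0",
                                  call. = FALSE)
  sum(events$type == "SUB") / census_N / observation_days
}

#' Global nest activity from frame differencing
#'
#' Mean absolute per-pixel intensity change between consecutive frames,
#' normalized by the number of wasps present and by the squared spatial scale
#' (e.g. the marker-label diameter in pixels, calibrating camera distance).
#' Only relative comparisons between phases/nests filmed with the same
#' calibration are meaningful.
#'
#' @param frames a list of equal-sized numeric matrices, or a 3D array with
#'   frames along the third dimension; at least 2 frames.
#' @param n_wasps number of wasps present (>= 1).
#' @param spatial_scale calibration length in pixels (> 0).
#' @return Numeric vector of activity values, one per frame transition.
#' @export
global_activity <- function(frames, n_wasps, spatial_scale = 1) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  if (!is.list(frames) || length(frames) < 2L)
    stop("need at least 2 frames", call. = FALSE)
  dims <- lapply(frames, dim)
  if (any(vapply(dims, function(d) !identical(d, dims[[1]]), TRUE)))
    stop("all frames must have identical dimensions", call. = FALSE)
  if (n_wasps < 1) stop("'n_wasps' must be >= 1", call. = FALSE)
  if (spatial_scale <= 0) stop("'spatial_scale' must be > 0", call. = FALSE)
  vapply(seq_len(length(frames) - 1L), function(k)
    mean(abs(frames[[k + 1L]] - frames[[k]])) / n_wasps / spatial_scale^2, 0)
}

#' Per-individual correlation with the queen expression profile
#'
#' For every individual, the Pearson correlation of its queen-gene expression
#' profile with each reference queen's profile, averaged over the references.
#' High values indicate a queen-like transcriptome; after queen removal the
#' whole colony transiently shifts toward the queen profile.
#'
#' @param expr an [expression_table()].
#' @param queen_genes gene identifiers over which profiles are correlated
#'   (defaults to the table's flagged queen genes; >= 2 required).
#' @param reference_queens individual identifiers of the reference queens
#'   (must be columns of the table).
#' @return Data frame: `individual`, `phase`, `queen_correlation` (`NA`, with
#'   a warning, for zero-variance profiles).
#' @export
queen_profile_correlation <- function(expr, reference_queens,
                                      queen_genes = NULL) {
  expr <- validate_expression_table(expr)
  if (is.null(queen_genes))
    queen_genes <- expr$genes$gene[expr$genes$queen_gene]
  if (length(queen_genes) < 2L)
    stop("need at least 2 queen genes", call. = FALSE)
  if (!all(reference_queens %in% colnames(expr$values)))
    stop("reference queens not found in expression table", call. = FALSE)
  sub <- expr$values[match(queen_genes, rownames(expr$values)), , drop = FALSE]
  refs <- sub[, reference_queens, drop = FALSE]
  cors <- vapply(colnames(sub), function(ind) {
    x <- sub[, ind]
    if (stats::sd(x) == 0 || any(apply(refs, 2, stats::sd) == 0)) {
      warning("zero-variance queen-gene profile; correlation undefined for '",
              ind, "'", call. = FALSE)
      return(NA_real_)
    }
    mean(apply(refs, 2, function(q) stats::cor(x, q)))
  }, 0)
  data.frame(individual = colnames(sub),
             phase = expr$samples$phase[match(colnames(sub),
                                              expr$samples$individual)],
             queen_correlation = unname(cors), stringsAsFactors = FALSE)
}

#' Fraction of significantly variable genes by DNA methylation level
#'
#' Tests each gene for biological over-dispersion among workers: the per-gene
#' variance is compared against a mean-variance trend fitted across all genes
#' (loess of log variance on mean expression), using the scaled statistic
#' `(n - 1) s^2 / trend ~ chi^2(n - 1)` with Benjamini-Hochberg correction.
#' This is a deliberately simple over-dispersion screen standing in for full
#' technical-noise decompositions; it preserves the contract needed here:
#' which genes vary more than expected at their expression level. Genes are
#' then binned by methylation and the fraction of significantly variable genes
#' per bin is reported, together with a Pearson correlation test on the
#' unbinned (methylation, log dispersion ratio) pairs. Gene-body methylation
#' suppressing expression noise shows up as a negative correlation.
#'
#' @param expr an [expression_table()].
#' @param workers individual identifiers to use (default: control-phase
#'   individuals with immature ovaries, i.e. workers); >= 2 required.
#' @param bins number of equal-width methylation bins (>= 2).
#' @param fdr Benjamini-Hochberg threshold for calling a gene variable.
#' @return A list: `genes` (per-gene data frame with `methylation`,
#'   `dispersion` = log2 variance ratio, `p`, `p_adj`, `variable`), `bins`
#'   (per-bin data frame with `fraction_variable`; empty bins give `NA` and
#'   are excluded from the correlation), and `correlation`
#'   (`estimate`, `p.value` of the unbinned Pearson test).
#' @export
variable_fraction_by_methylation <- function(expr, workers = NULL, bins = 5,
                                             fdr = 0.05) {
  expr <- validate_expression_table(expr)
  if (bins < 2) stop("need at least 2 methylation bins", call. = FALSE)
  if (is.null(workers)) {
    s <- expr$samples
    workers <- s$individual[s$phase == "control" & s$ovary_mm < 1.5]
  }
  if (length(workers) < 2L)
    stop("need at least 2 workers", call. = FALSE)
  x <- expr$values[, workers, drop = FALSE]
  n <- ncol(x)
  mu <- rowMeans(x)
  s2 <- apply(x, 1, stats::var)
  ok <- s2 > 0
  trend <- rep(NA_real_, length(s2))
  fit <- stats::loess(log(s2[ok]) ~ mu[ok], span = 0.75, degree = 1)
  trend[ok] <- exp(stats::predict(fit, mu[ok]))
  stat <- (n - 1) * s2 / trend
  p <- stats::pchisq(stat, df = n - 1, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p, method = "BH")
  genes <- data.frame(
    gene = rownames(expr$values),
    methylation = expr$genes$methylation,
    mean = mu, dispersion = log2(s2 / trend),
    p = p, p_adj = p_adj, variable = !is.na(p_adj) & p_adj < fdr,
    stringsAsFactors = FALSE)

  edges <- seq(0, max(genes$methylation, 1e-9), length.out = bins + 1L)
  bin_id <- cut(genes$methylation, edges, include.lowest = TRUE)
  frac <- tapply(genes$variable, bin_id, function(v)
    if (length(v)) mean(v) else NA_real_)
  bins_df <- data.frame(
    bin = levels(bin_id),
    midpoint = (edges[-1] + edges[-length(edges)]) / 2,
    n_genes = as.vector(table(bin_id)),
    fraction_variable = as.vector(frac))

  use <- is.finite(genes$dispersion)
  ct <- stats::cor.test(genes$methylation[use], genes$dispersion[use])
  list(genes = genes, bins = bins_df,
       correlation = list(estimate = unname(ct$estimate),
                          p.value = ct$p.value))
}

#' Pairwise comparison of a per-individual statistic across phases
#'
#' Wilcoxon tests between every pair of phases with Benjamini-Hochberg
#' correction: the signed-rank test when pairing identifiers are supplied and
#' the rank-sum test otherwise (collected colonies yield independent
#' individuals per phase, so unpaired is the default).
#'
#' @param values numeric per-individual statistic.
#' @param phase phase label per observation.
#' @param pair_id optional pairing identifier per observation; pairs are
#'   matched within each phase pair.
#' @return Data frame: `phase1`, `phase2`, `n1`, `n2`, `statistic`, `p`,
#'   `p_adj`. Pairs with fewer than 2 observations on either side get `NA`
#'   results.
#' @export
compare_phases <- function(values, phase, pair_id = NULL) {
  phase <- as.character(phase)
  phases <- unique(phase)
  if (length(phases) < 2L) stop("need at least 2 phases", call. = FALSE)
  combs <- utils::combn(phases, 2)
  rows <- lapply(seq_len(ncol(combs)), function(k) {
    a <- combs[1, k]; b <- combs[2, k]
    xa <- values[phase == a]; xb <- values[phase == b]
    out <- data.frame(phase1 = a, phase2 = b, n1 = length(xa),
                      n2 = length(xb), statistic = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    if (length(xa) < 2L || length(xb) < 2L) return(out)
    wt <- if (!is.null(pair_id)) {
      ia <- pair_id[phase == a]; ib <- pair_id[phase == b]
      common <- intersect(ia, ib)
      if (length(common) < 2L) return(out)
      suppressWarnings(stats::wilcox.test(xa[match(common, ia)],
                                          xb[match(common, ib)],
                                          paired = TRUE, exact = FALSE))
    } else {
      suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE))
    }
    out$statistic <- unname(wt$statistic); out$p <- wt$p.value
    out
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Classify ovary maturity from the largest egg length
#'
#' A mature egg has a length of at least 1.5 mm, the smallest egg size
#' associated with egg laying; the threshold is inclusive.
#'
#' @param egg_length_mm largest-egg length(s) in millimetres, >= 0.
#' @param threshold_mm maturity threshold (default 1.5 mm).
#' @return Character vector `"mature"` / `"immature"`.
#' @export
classify_ovary <- function(egg_length_mm, threshold_mm = 1.5) {
  if (any(!is.finite(egg_length_mm)) || any(egg_length_mm < 0))
    stop("egg length must be finite and >= 0", call. = FALSE)
  ifelse(egg_length_mm >= threshold_mm, "mature", "immature")
}
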