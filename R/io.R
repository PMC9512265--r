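# Format readers/writers: delimited-text schemas for event logs, expression
# tables, densities and trajectories, plus PNG frame stacks.

#' Genes x individuals expression table
#'
#' Container for normalized log-scale expression values with per-gene
#' queen-gene flags and gene-body methylation levels, and per-individual phase
#' and ovary size.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   individuals in columns.
#' @param genes data frame with columns `gene`, `queen_gene` (logical),
#'   `methylation` (in `[0, 1]`), one row per row of `values`.
#' @param samples data frame with columns `individual`, `phase`, `ovary_mm`,
#'   one row per column of `values`.
#' @return A validated list of class `"expression_table"`.
#' @export
expression_table <- function(values, genes, samples) {
  rownames(genes) <- NULL
  rownames(samples) <- NULL
  validate_expression_table(
    structure(list(values = values, genes = genes, samples = samples),
              class = "expression_table"))
}

validate_expression_table <- function(x) {
  stopifnot(inherits(x, "expression_table"))
  if (!is.matrix(x$values)) stop("'values' must be a matrix", call. = FALSE)
  if (nrow(x$values) != nrow(x$genes) || ncol(x$values) != nrow(x$samples))
    stop("expression table dimensions are inconsistent", call. = FALSE)
  if (!identical(rownames(x$values), as.character(x$genes$gene)))
    stop("rownames(values) must match genes$gene", call. = FALSE)
  if (!identical(colnames(x$values), as.character(x$samples$individual)))
    stop("colnames(values) must match samples$individual", call. = FALSE)
  if (!is.logical(x$genes$queen_gene))
    stop("queen_gene flags must be logical", call. = FALSE)
  if (any(x$genes$methylation < 0 | x$genes$methylation > 1))
    stop("methylation must lie in [0, 1]", call. = FALSE)
  x
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table: %d genes (%d queen genes) x %d individuals>\n",
              nrow(x$values), sum(x$genes$queen_gene), ncol(x$values)))
  cat("  phases:", paste(unique(x$samples$phase), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write an interaction event log as CSV
#'
#' @param events a validated event log (see [event_log()]).
#' @param path CSV file path.
#' @return `write_event_log()` returns `path` invisibly; `read_event_log()`
#'   the validated event log.
#' @export
write_event_log <- function(events, path) {
  events <- validate_event_log(events)
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  validate_event_log(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read / write an expression table as a trio of CSV files
#'
#' Writes `<base>_values.csv` (gene id + one column per individual),
#' `<base>_genes.csv` and `<base>_samples.csv`.
#'
#' @param expr an [expression_table()].
#' @param base path prefix for the three CSV files.
#' @return `write_expression_table()` returns `base` invisibly;
#'   `read_expression_table()` the validated table.
#' @export
write_expression_table <- function(expr, base) {
  expr <- validate_expression_table(expr)
  vals <- data.frame(gene = rownames(expr$values), expr$values,
                     check.names = FALSE)
  utils::write.csv(vals, paste0(base, "_values.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(expr$genes, paste0(base, "_genes.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(expr$samples, paste0(base, "_samples.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(base)
}

#' @rdname write_expression_table
#' @export
read_expression_table <- function(base) {
  vals <- utils::read.csv(paste0(base, "_values.csv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- vals$gene
  expression_table(
    m,
    utils::read.csv(paste0(base, "_genes.csv"), stringsAsFactors = FALSE),
    utils::read.csv(paste0(base, "_samples.csv"), stringsAsFactors = FALSE))
}

#' Read / write a colony composition as two-column delimited text
#'
#' @param density a [population_density()].
#' @param path CSV file path with columns `r` (cell centers) and `f`.
#' @return `write_density()` returns `path` invisibly; `read_density()` the
#'   reconstructed `population_density` (uniform grid inferred from the
#'   centers).
#' @export
write_density <- function(density, path) {
  stopifnot(inherits(density, "population_density"))
  utils::write.csv(data.frame(r = density$centers, f = density$f), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_density
#' @export
read_density <- function(path) {
  d <- utils::read.csv(path)
  dr <- d$r[2] - d$r[1]
  if (max(abs(diff(d$r) - dr)) > 1e-8 * dr)
    stop("density grid must be uniform", call. = FALSE)
  population_density(d$f, n_cells = nrow(d), r_max = max(d$r) + dr / 2,
                     normalize = FALSE)
}

#' Export a simulated trajectory to delimited text
#'
#' Long format: one row per sample time and insect with columns
#' `time, insect, n, q, r`.
#'
#' @param traj a `nest_trajectory`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "nest_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory_frame <- function(path) {
  utils::read.csv(path)
}

#' Convert simulated interaction events to the behavioural event-log schema
#'
#' Maps a trajectory's `(time, dominant, subdominant)` interaction records to
#' paired DOM/SUB rows so that simulated nests feed the behavioural
#' observables unchanged. Simulation time (degradation-time units) is
#' converted to hours.
#'
#' @param traj a `nest_trajectory` simulated with `record_events = TRUE`.
#' @param phase phase label for the exported rows.
#' @param hours_per_unit hours per scaled time unit (the molecular degradation
#'   time; default 30 h).
#' @return A validated event log.
#' @export
trajectory_event_log <- function(traj, phase = "control",
                                 hours_per_unit = 30) {
  stopifnot(inherits(traj, "nest_trajectory"))
  ev <- traj$events
  if (!nrow(ev))
    return(event_log(numeric(0), character(0), character(0), character(0),
                     character(0)))
  ids <- sprintf("w%02d", seq_len(ncol(traj$n)))
  t_h <- ev$time * hours_per_unit
  event_log(
    time_h = c(t_h, t_h),
    actor = c(ids[ev$dominant], ids[ev$subdominant]),
    recipient = c(ids[ev$subdominant], ids[ev$dominant]),
    type = rep(c("DOM", "SUB"), each = nrow(ev)),
    phase = phase)
}

#' Read / write a grayscale frame stack as PNG files
#'
#' Frames are 8-bit grayscale PNGs named `frame_0001.png`, ... inside `dir`.
#' Requires the `png` package.
#'
#' @param frames list of numeric matrices in `[0, 1]`.
#' @param dir directory (created if needed).
#' @return `write_frames()` returns `dir` invisibly; `read_frames()` the list
#'   of matrices.
#' @export
write_frames <- function(frames, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write frame stacks", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(frames))
    png::writePNG(frames[[k]], file.path(dir, sprintf("frame_%04d.png", k)))
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to read frame stacks", call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames in '", dir, "'", call. = FALSE)
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  })
}
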