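# Plain-text interchange: TSV for envelopes, matrices, ROI series, TRFs,
# partitions and edge lists; JSON for reports and ground-truth sidecars.

#' Write an envelope as single-column TSV
#'
#' Header comment line carries the sampling rate, then a `value` column.
#'
#' @param envelope an `envelope` object.
#' @param path output path.
#' @export
write_envelope_tsv <- function(envelope, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", envelope$fs), con)
  writeLines("value", con)
  writeLines(format(envelope$values, digits = 10, trim = TRUE), con)
  invisible(path)
}

#' Read an envelope written by [write_envelope_tsv()]
#'
#' @param path input path.
#' @return an `envelope` object.
#' @export
read_envelope_tsv <- function(path) {
  header <- readLines(path, n = 1)
  fs <- as.numeric(sub("# fs=", "", header, fixed = TRUE))
  values <- utils::read.table(path, skip = 1, header = TRUE)$value
  structure(list(values = values, fs = fs, duration = length(values) / fs),
            class = "envelope")
}

#' Write a numeric matrix as TSV with row and column names
#'
#' @param m matrix (or connectivity/ROI-series object).
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  if (inherits(m, "connectivity_matrix")) m <- m$values
  if (inherits(m, "roi_series")) m <- m$values
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = !is.null(rownames(m)), col.names = NA)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path input path.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                              check.names = FALSE))
}

#' Write TRF weights as TSV (rows = ROI, columns = lag in ms)
#'
#' @param trf a `trf_model`/`trf_decoder` or ROI x lag matrix with a
#'   `lags_ms` attribute.
#' @param path output path.
#' @export
write_trf_tsv <- function(trf, path) {
  w <- if (inherits(trf, c("trf_model", "trf_decoder"))) trf$weights else trf
  lags <- if (inherits(trf, c("trf_model", "trf_decoder"))) trf$lags_ms else
    attr(trf, "lags_ms")
  colnames(w) <- lags
  utils::write.table(w, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Write a partition as two-column TSV (roi_id, community)
#'
#' @param partition a `partition` object or label vector.
#' @param path output path.
#' @export
write_partition_tsv <- function(partition, path) {
  labels <- if (inherits(partition, "partition")) partition$labels else partition
  utils::write.table(
    data.frame(roi_id = seq_along(labels), community = labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a thresholded graph as a weighted edge-list TSV
#'
#' @param graph a `thresholded_graph` or symmetric matrix.
#' @param path output path.
#' @export
write_edge_list_tsv <- function(graph, path) {
  W <- graph_values(graph)
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  utils::write.table(
    data.frame(from = idx[, 1], to = idx[, 2], weight = W[idx]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# write the pipeline report plus key tables and a content-hash manifest
write_report <- function(report, networks, eeg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  p <- function(f) file.path(dir, f)

  for (pw in names(report$decoding)) {
    f <- p(sprintf("decoding_%s.tsv", pw))
    utils::write.table(report$decoding[[pw]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  for (cond in names(networks$cond_nets)) {
    f <- p(sprintf("connectivity_condition_%s.tsv", cond))
    write_matrix_tsv(networks$cond_nets[[cond]], f)
    files <- c(files, f)
    f <- p(sprintf("partition_condition_%s.tsv", cond))
    write_partition_tsv(networks$selected[[cond]]$partition, f)
    files <- c(files, f)
  }
  scan_tab <- data.frame(
    density = report$networks$densities,
    Q_A = report$networks$Q_curves$A,
    Q_B = report$networks$Q_curves$B,
    VI_A = c(NA, report$networks$VI_curves$A),
    VI_B = c(NA, report$networks$VI_curves$B),
    F1 = report$networks$f1_curve)
  f <- p("density_scan.tsv")
  utils::write.table(scan_tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  f <- p("report.json")
  jsonlite::write_json(
    report[c("mean_z", "f1_full", "f1_windows", "provenance")],
    f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

#' Write ground-truth metadata as a JSON sidecar
#'
#' Community labels per condition, dimensions, misalignment level and seeds
#' -- everything needed to score recovery against a stored simulation.  The
#' numeric arrays (kernels, lead field) travel separately as TSV via
#' [write_matrix_tsv()].
#'
#' @param ground_truth a [make_ground_truth()] object.
#' @param path output path.
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  gt <- ground_truth
  jsonlite::write_json(list(
    n_roi = gt$n_roi, n_channels = gt$n_channels, n_sources = gt$n_sources,
    n_communities = gt$n_communities, condition_b = gt$condition_b,
    misalignment = gt$misalignment,
    community_labels = gt$community_labels,
    parcellation = gt$parcellation,
    lag_grid_ms = gt$lag_grid_ms,
    seeds = as.list(gt$seeds)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
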