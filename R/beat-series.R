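#' Beat-indexed multivariate series
#'
#' Container for one subject-condition recording: a numeric matrix with one row
#' per beat and one column per physiological node. The default node set is
#' R (respiration amplitude), H (heart period), M (mean arterial pressure) and
#' C (arterial compliance).
#'
#' @param values numeric matrix, beats in rows, nodes in columns.
#' @param node_labels character vector of unique column names; defaults to the
#'   column names of `values`.
#' @param condition condition label, e.g. `"REST"` or `"HUT"`.
#' @param subject_id subject identifier.
#' @param mean_beat_duration_s mean beat duration in seconds, used to convert a
#'   cutoff in Hz to cycles/beat. Defaults to 1 (synthetic data convention).
#'
#' @return An object of class `beat_series`.
#' @export
beat_series <- function(values, node_labels = colnames(values),
                        condition = "REST", subject_id = "S1",
                        mean_beat_duration_s = 1.0) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(node_labels)) {
    node_labels <- paste0("X", seq_len(ncol(values)))
  }
  if (anyNA(values)) stop("beat series contains missing values")
  if (nrow(values) < 50L) stop("beat series must have at least 50 beats")
  if (anyDuplicated(node_labels)) stop("node labels must be unique")
  if (length(node_labels) != ncol(values)) {
    stop("node_labels length must match the number of columns")
  }
  if (!is.numeric(mean_beat_duration_s) || mean_beat_duration_s <= 0) {
    stop("mean_beat_duration_s must be positive")
  }
  colnames(values) <- node_labels
  structure(
    list(values = values, node_labels = node_labels, condition = condition,
         subject_id = subject_id, mean_beat_duration_s = mean_beat_duration_s),
    class = "beat_series"
  )
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> subject %s, condition %s: %d beats x %d nodes (%s)\n",
              x$subject_id, x$condition, nrow(x$values), ncol(x$values),
              paste(x$node_labels, collapse = ", ")))
  invisible(x)
}

#' @export
dim.beat_series <- function(x) dim(x$values)

n_beats <- function(series) nrow(series$values)
n_nodes <- function(series) ncol(series$values)

node_index <- function(series, node) {
  if (is.character(node)) {
    idx <- match(node, series$node_labels)
    if (anyNA(idx)) stop("unknown node label: ", paste(node[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(node)
}

#' Write / read a beat series table
#'
#' Plain comma-separated values, one header row of node labels, one row per
#' beat — the interchange format shared with the synthetic cohort writer.
#'
#' @param series a [beat_series()].
#' @param path file path.
#' @export
write_beat_series <- function(series, path) {
  utils::write.csv(as.data.frame(series$values), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_beat_series
#' @param condition,subject_id,mean_beat_duration_s metadata to attach on read.
#' @export
read_beat_series <- function(path, condition = "REST", subject_id = "S1",
                             mean_beat_duration_s = 1.0) {
  df <- utils::read.csv(path, check.names = FALSE)
  beat_series(as.matrix(df), condition = condition, subject_id = subject_id,
              mean_beat_duration_s = mean_beat_duration_s)
}
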