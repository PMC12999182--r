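#' Zero-lag directed acyclic graph
#'
#' Within-beat (instantaneous) effects arise because the beat-to-beat sampling
#' is coarser than the underlying physiological interactions. They are only
#' identifiable when constrained to a DAG; the measurement convention orders
#' the nodes R -> H -> M -> C within each beat, and the permitted zero-lag
#' edges are all forward edges in that ordering.
#'
#' @param node_order character vector giving the topological order of the nodes.
#' @param edges two-column character matrix (or data.frame) of permitted
#'   zero-lag edges, `from` then `to`. Defaults to every forward pair of
#'   `node_order`.
#'
#' @return An object of class `zero_lag_dag`.
#' @export
zero_lag_dag <- function(node_order = c("R", "H", "M", "C"), edges = NULL) {
  if (anyDuplicated(node_order)) stop("node_order must be unique")
  if (is.null(edges)) {
    pairs <- which(upper.tri(diag(length(node_order))), arr.ind = TRUE)
    edges <- cbind(from = node_order[pairs[, "row"]], to = node_order[pairs[, "col"]])
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns (from, to)")
  colnames(edges) <- c("from", "to")
  pos <- match(edges, node_order)
  if (anyNA(pos)) stop("edge endpoints must be nodes of node_order")
  ifrom <- match(edges[, 1L], node_order)
  ito <- match(edges[, 2L], node_order)
  if (any(ifrom >= ito)) {
    stop("zero-lag edges must point forward in node_order (acyclicity)")
  }
  structure(list(node_order = node_order, edges = edges), class = "zero_lag_dag")
}

#' @export
print.zero_lag_dag <- function(x, ...) {
  cat("<zero_lag_dag> order:", paste(x$node_order, collapse = " -> "), "\n")
  cat("  edges:", paste(paste0(x$edges[, 1], "->", x$edges[, 2]), collapse = ", "), "\n")
  invisible(x)
}

# Zero-lag parents of `node` under the DAG.
dag_parents <- function(dag, node) {
  dag$edges[dag$edges[, "to"] == node, "from"]
}

dag_has_edge <- function(dag, from, to) {
  any(dag$edges[, "from"] == from & dag$edges[, "to"] == to)
}
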