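#' Per-target extended regression
#'
#' Ordinary least squares of the target's present sample on the lagged samples
#' (lags 1..p) of the regressor nodes and on the present samples of those
#' regressor nodes that are zero-lag DAG parents of the target. This is the
#' building block of the extended (zero-lag augmented) vector autoregression:
#' the DAG makes the within-beat system recursive, so each equation is
#' identifiable by itself.
#'
#' @param series a [beat_series()] (detrended / zero mean).
#' @param target target node (label or index).
#' @param regressor_nodes nodes whose past (and DAG-permitted present) enter
#'   the regression; the target itself is normally included.
#' @param dag a [zero_lag_dag()].
#' @param p model order (>= 1).
#' @param rows sample window (response row indices); defaults to `(p+1):N`.
#'   All fits being compared must share the same window.
#' @return list with `coefficients` (named), `sigma2` (residual variance,
#'   denominator = window length), `residuals`, `rows`.
#' @export
target_regression <- function(series, target, regressor_nodes, dag, p,
                              rows = NULL) {
  stopifnot(inherits(series, "beat_series"), p >= 1L)
  x <- series$values
  N <- nrow(x)
  target <- series$node_labels[node_index(series, target)]
  regressor_nodes <- series$node_labels[node_index(series, regressor_nodes)]
  if (is.null(rows)) rows <- (p + 1L):N
  design <- extended_design(x, target, regressor_nodes, dag, p, rows)
  if (length(rows) <= ncol(design)) {
    stop("sample window shorter than the number of regressors")
  }
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    stop(sprintf("rank-deficient design (rank %d < %d columns, condition number %.3g)",
                 qrX$rank, ncol(design), kappa(design)))
  }
  y <- x[rows, target]
  beta <- qr.coef(qrX, y)
  res <- y - design %*% beta
  list(coefficients = stats::setNames(as.numeric(beta), colnames(design)),
       sigma2 = sum(res^2) / length(rows), residuals = as.numeric(res),
       rows = rows, target = target)
}

extended_design <- function(x, target, regressor_nodes, dag, p, rows) {
  cols <- list()
  for (m in regressor_nodes) {
    for (k in seq_len(p)) cols[[sprintf("%s.l%d", m, k)]] <- x[rows - k, m]
  }
  zl <- intersect(dag_parents(dag, target), regressor_nodes)
  for (m in zl) cols[[sprintf("%s.l0", m)]] <- x[rows, m]
  do.call(cbind, cols)
}

#' Model order selection by AIC
#'
#' Fits the full unrestricted extended model for each candidate order on a
#' common sample window (rows `p_max+1 .. N` for every candidate) and returns
#' the order minimizing `Nw * ln det(Sigma) + 2 * n_free`, with `Sigma` the
#' residual covariance across the M target equations and `n_free` the number
#' of free coefficients (`M^2 p` lagged plus the DAG zero-lag entries).
#'
#' @param series a [beat_series()].
#' @param dag a [zero_lag_dag()].
#' @param p_range candidate orders (default 1:10).
#' @return The selected order (integer).
#' @export
select_order_aic <- function(series, dag, p_range = 1:10) {
  if (!length(p_range)) stop("p_range must be non-empty")
  x <- series$values
  N <- nrow(x)
  m <- ncol(x)
  pmax <- max(p_range)
  rows <- (pmax + 1L):N
  aic <- vapply(p_range, function(p) {
    E <- sapply(series$node_labels, function(j) {
      target_regression(series, j, series$node_labels, dag, p, rows = rows)$residuals
    })
    Sigma <- crossprod(E) / length(rows)
    nfree <- m^2 * p + nrow(dag$edges)
    length(rows) * determinant(Sigma, logarithm = TRUE)$modulus + 2 * nfree
  }, 1.0)
  p_range[which.min(aic)]
}

#' Conditional Granger causality of one directed link
#'
#' Compares the residual variance of the target's extended regression with
#' (`sigma2`, unrestricted) and without (`lambda2`, restricted) every term of
#' the source node, on the identical sample window:
#' `F = ln(lambda2 / sigma2)`, and the equivalent transfer entropy for
#' Gaussian data is `T = F / 2`. The restricted design is a column subset of
#' the unrestricted one, so `F >= 0` on every input.
#'
#' @param series a [beat_series()].
#' @param source,target distinct node labels or indices.
#' @param dag a [zero_lag_dag()].
#' @param p model order (from [select_order_aic()]).
#' @return An `mb_link` list: `source`, `target`, `F`, `T`, `sigma2`,
#'   `lambda2`, `p`, `conditioning` (remaining nodes).
#' @export
conditional_gc <- function(series, source, target, dag, p) {
  source <- series$node_labels[node_index(series, source)]
  target <- series$node_labels[node_index(series, target)]
  if (source == target) stop("source and target must differ")
  rows <- (p + 1L):n_beats(series)
  unres <- target_regression(series, target, series$node_labels, dag, p, rows)
  res <- target_regression(series, target, setdiff(series$node_labels, source),
                           dag, p, rows)
  if (unres$sigma2 <= 0) stop("non-positive unrestricted residual variance")
  f <- max(log(res$sigma2 / unres$sigma2), 0)
  structure(
    list(source = source, target = target, F = f, T = f / 2,
         sigma2 = unres$sigma2, lambda2 = res$sigma2, p = p,
         conditioning = setdiff(series$node_labels, c(source, target))),
    class = "mb_link"
  )
}

#' Model-based causality network of one series
#'
#' Estimates all `M(M-1)` directed links with one shared model order.
#'
#' @param series a [beat_series()].
#' @param dag a [zero_lag_dag()].
#' @param p_range AIC search range; ignored when `p` is given.
#' @param p optional fixed order.
#' @return A `causality_network`: list with `estimator = "mb"`, `order`, and
#'   `links` (data.frame with columns source, target, F, T, sigma2, lambda2, p).
#' @export
mb_network <- function(series, dag = zero_lag_dag(), p_range = 1:10, p = NULL) {
  if (is.null(p)) p <- select_order_aic(series, dag, p_range)
  nodes <- series$node_labels
  pairs <- expand.grid(source = nodes, target = nodes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  links <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    est <- conditional_gc(series, pairs$source[r], pairs$target[r], dag, p)
    data.frame(source = est$source, target = est$target, F = est$F, T = est$T,
               sigma2 = est$sigma2, lambda2 = est$lambda2, p = p)
  }))
  rownames(links) <- NULL
  structure(
    list(estimator = "mb", condition = series$condition,
         subject_id = series$subject_id, order = p, links = links),
    class = "causality_network"
  )
}

#' @export
print.causality_network <- function(x, ...) {
  cat(sprintf("<causality_network> %s estimator, subject %s (%s), %d links\n",
              toupper(x$estimator), x$subject_id, x$condition, nrow(x$links)))
  print(utils::head(x$links, 12L))
  invisible(x)
}
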