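#' k-nearest-neighbour conditional mutual information
#'
#' KSG-style estimator of `I(a; b | c)` under the maximum (Chebyshev) norm:
#' the search radius is fixed per sample as the distance to its k-th neighbour
#' in the full joint space, neighbour counts in the three projected spaces use
#' strict inequality, and the digamma terms are combined as
#' `psi(k) + <psi(nC+1) - psi(nAC+1) - psi(nBC+1)>`. With an empty
#' conditioning block this reduces to the plain KSG mutual information.
#'
#' @param a,b numeric vectors or matrices (samples in rows).
#' @param c optional conditioning block; `NULL` for plain MI.
#' @param k neighbour count (default 10).
#' @param jitter_seed if non-`NULL`, adds seeded uniform jitter of amplitude
#'   1e-10 to every coordinate to break ties (neighbour counts with strict
#'   inequalities are ill-defined at ties).
#' @return The estimate in nats (may be negative: the estimator is biased
#'   down for weak dependence and estimates are reported unclipped).
#' @export
cmi_knn <- function(a, b, c = NULL, k = 10L, jitter_seed = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  c <- if (is.null(c)) matrix(0, nrow(a), 0L) else as.matrix(c)
  n <- nrow(a)
  if (n < 5L * k) stop("need at least 5k samples for a stable estimate")
  if (!is.null(jitter_seed)) {
    a <- add_jitter(a, jitter_seed)
    b <- add_jitter(b, jitter_seed + 1L)
    if (ncol(c)) c <- add_jitter(c, jitter_seed + 2L)
  }
  cmi_knn_cpp(a, b, c, as.integer(k))
}

add_jitter <- function(m, seed, amplitude = 1e-10) {
  m + with_seed(seed, matrix(runif(length(m), -amplitude, amplitude), nrow(m)))
}

#' Candidate set for non-uniform embedding
#'
#' All (node, lag) states up to maximum lag `L`: the target's own past
#' (lags 1..L; its present is never a candidate), and for every other node
#' lags `tau..L`, with `tau = 0` when the node is a zero-lag DAG parent of the
#' target and `tau = 1` otherwise.
#'
#' @param series a [beat_series()].
#' @param target target node.
#' @param dag a [zero_lag_dag()].
#' @param L maximum lag (default 10).
#' @return data.frame with columns `node`, `lag`.
#' @export
candidate_set <- function(series, target, dag, L = 10L) {
  target <- series$node_labels[node_index(series, target)]
  parents <- dag_parents(dag, target)
  out <- lapply(series$node_labels, function(nd) {
    if (nd == target) {
      data.frame(node = nd, lag = seq_len(L))
    } else {
      tau <- if (nd %in% parents) 0L else 1L
      data.frame(node = nd, lag = tau:L)
    }
  })
  do.call(rbind, out)
}

# Aligned sample matrix for a set of (node, lag) states: response rows are
# beats L+1 .. N so every lag up to L is available.
lagged_block <- function(x, states, L) {
  rows <- (L + 1L):nrow(x)
  if (!nrow(states)) return(matrix(0, length(rows), 0L))
  cols <- vapply(seq_len(nrow(states)), function(r) {
    x[rows - states$lag[r], states$node[r]]
  }, numeric(length(rows)))
  colnames(cols) <- sprintf("%s.l%d", states$node, states$lag)
  as.matrix(cols)
}

#' Non-uniform embedding by greedy CMI maximization
#'
#' Iteratively selects the candidate (node, lag) maximizing the conditional
#' mutual information with the target's present sample given the states
#' already selected. The selected candidate is admitted only if its CMI
#' exceeds the `100(1-alpha)`-th percentile of `Ns` null CMIs obtained by
#' independently shuffling the candidate's and the target's samples; the
#' search stops at the first rejection.
#'
#' @param series a [beat_series()] (standardized to unit variance internally).
#' @param target target node.
#' @param dag a [zero_lag_dag()].
#' @param L maximum lag. @param k neighbour count. @param Ns number of shuffle
#'   realizations. @param alpha admission significance level.
#' @param seed integer seed controlling jitter and the shuffles.
#' @return An `embedding_vector`: list with `selected` (data.frame node, lag in
#'   admission order), `scores` (admission CMI per step), `step_scores` (all
#'   candidate CMIs at each admitted step), `candidates`, `params`.
#' @export
nonuniform_embed <- function(series, target, dag = zero_lag_dag(), L = 10L,
                             k = 10L, Ns = 100L, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(series, "beat_series"))
  target <- series$node_labels[node_index(series, target)]
  series <- standardize(series, "unit_variance")
  x <- add_jitter(series$values, seed)
  cand <- candidate_set(series, target, dag, L)
  rows <- (L + 1L):nrow(x)
  n <- length(rows)
  if (n < 5L * k) stop("series too short for the requested k and L")
  y <- matrix(x[rows, target], ncol = 1L)

  selected <- cand[0L, ]
  scores <- numeric(0L)
  step_scores <- list()
  embX <- matrix(0, n, 0L)
  remaining <- cand
  shuffle_seeds <- derive_seeds(seed + 1L, nrow(cand))
  step <- 0L
  while (nrow(remaining)) {
    step <- step + 1L
    W <- lagged_block(x, remaining, L)
    cand_scores <- cmi_knn_score_cpp(y, W, embX, as.integer(k))
    best <- which.max(cand_scores)
    w <- lagged_block(x, remaining[best, , drop = FALSE], L)
    nulls <- with_seed(shuffle_seeds[step], {
      pa <- replicate(Ns, sample.int(n))
      pb <- replicate(Ns, sample.int(n))
      cmi_knn_null_cpp(y, w, embX, as.integer(k), pa, pb)
    })
    thr <- surrogate_threshold(nulls[-1L], 100 * (1 - alpha))
    if (!(nulls[1L] > thr)) break
    selected <- rbind(selected, remaining[best, ])
    scores <- c(scores, cand_scores[best])
    step_scores[[length(step_scores) + 1L]] <- as.numeric(cand_scores)
    embX <- cbind(embX, w)
    remaining <- remaining[-best, , drop = FALSE]
  }
  rownames(selected) <- NULL
  structure(
    list(selected = selected, scores = scores, step_scores = step_scores,
         candidates = cand,
         params = list(L = L, k = k, Ns = Ns, alpha = alpha, seed = seed)),
    class = "embedding_vector"
  )
}

#' @export
print.embedding_vector <- function(x, ...) {
  if (nrow(x$selected)) {
    cat("<embedding_vector>", paste(sprintf("%s(-%d)", x$selected$node, x$selected$lag),
                                    collapse = ", "), "\n")
  } else cat("<embedding_vector> empty\n")
  invisible(x)
}

#' Model-free conditional transfer entropy of one link
#'
#' Runs the non-uniform embedding for the target with the full candidate set
#' (source included), partitions the selected states into target past (Vj),
#' source states (Vi) and other-node states (Vz), and evaluates the kNN
#' transfer-entropy combination with the radius fixed per sample by the k-th
#' neighbour in the full joint space. When no source state is selected the
#' information transfer is exactly 0 by convention.
#'
#' @param series a [beat_series()].
#' @param source,target distinct nodes.
#' @param dag a [zero_lag_dag()].
#' @param L,k,Ns,alpha embedding parameters, see [nonuniform_embed()].
#' @param seed integer seed.
#' @param embedding optional precomputed [nonuniform_embed()] result for this
#'   target (must have been run with the full candidate set).
#' @return An `mf_link`: list with `source`, `target`, `T` (nats, unclipped),
#'   `embedding`, `d_i`, `d_j`, `d_z`, `k`.
#' @export
mf_cte <- function(series, source, target, dag = zero_lag_dag(), L = 10L,
                   k = 10L, Ns = 100L, alpha = 0.05, seed = 1L,
                   embedding = NULL) {
  source <- series$node_labels[node_index(series, source)]
  target <- series$node_labels[node_index(series, target)]
  if (source == target) stop("source and target must differ")
  if (is.null(embedding)) {
    embedding <- nonuniform_embed(series, target, dag, L, k, Ns, alpha, seed)
  } else {
    # keep the jitter realization of the embedding run
    seed <- embedding$params$seed
    L <- embedding$params$L
    k <- embedding$params$k
  }
  sel <- embedding$selected
  vi <- sel[sel$node == source, , drop = FALSE]
  vj <- sel[sel$node == target, , drop = FALSE]
  vz <- sel[!(sel$node %in% c(source, target)), , drop = FALSE]
  t_est <- 0
  if (nrow(vi)) {
    series_s <- standardize(series, "unit_variance")
    x <- add_jitter(series_s$values, seed)
    rows <- (L + 1L):nrow(x)
    y <- matrix(x[rows, target], ncol = 1L)
    t_est <- cmi_knn_cpp(y, lagged_block(x, vi, L),
                         cbind(lagged_block(x, vj, L), lagged_block(x, vz, L)),
                         as.integer(k))
  }
  structure(
    list(source = source, target = target, T = t_est, embedding = embedding,
         d_i = nrow(vi), d_j = nrow(vj), d_z = nrow(vz), k = k),
    class = "mf_link"
  )
}

#' Model-free causality network of one series
#'
#' All `M(M-1)` directed links; the embedding is recomputed for every
#' (source, target) pair with the full candidate set, under per-pair seeds
#' derived from `seed`.
#'
#' @inheritParams mf_cte
#' @return A `causality_network` with `estimator = "mf"` and `links`
#'   (data.frame source, target, T, d_i, d_j, d_z, embedding list-column as
#'   comma-separated states).
#' @export
mf_network <- function(series, dag = zero_lag_dag(), L = 10L, k = 10L,
                       Ns = 100L, alpha = 0.05, seed = 1L) {
  nodes <- series$node_labels
  pairs <- expand.grid(source = nodes, target = nodes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  seeds <- derive_seeds(seed, nrow(pairs))
  links <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    est <- mf_cte(series, pairs$source[r], pairs$target[r], dag, L, k, Ns,
                  alpha, seed = seeds[r])
    sel <- est$embedding$selected
    data.frame(source = est$source, target = est$target, T = est$T,
               d_i = est$d_i, d_j = est$d_j, d_z = est$d_z,
               embedding = paste(sprintf("%s(-%d)", sel$node, sel$lag),
                                 collapse = ";"))
  }))
  rownames(links) <- NULL
  structure(
    list(estimator = "mf", condition = series$condition,
         subject_id = series$subject_id,
         params = list(L = L, k = k, Ns = Ns, alpha = alpha), links = links),
    class = "causality_network"
  )
}
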