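#' Surrogate test configuration
#'
#' @param n_surrogates number of surrogate series (default 100).
#' @param percentile significance threshold percentile (default 95).
#' @param method `"iaaft"` (model-based path) or `"time_shift"` (model-free path).
#' @param min_shift minimum circular shift in beats for time-shift surrogates.
#' @param seed integer seed.
#' @return A `surrogate_config` list.
#' @export
surrogate_config <- function(n_surrogates = 100L, percentile = 95,
                             method = c("iaaft", "time_shift"),
                             min_shift = 20L, seed = 1L) {
  method <- match.arg(method)
  if (percentile <= 0 || percentile >= 100) stop("percentile must be in (0, 100)")
  structure(list(n_surrogates = as.integer(n_surrogates), percentile = percentile,
                 method = method, min_shift = as.integer(min_shift),
                 seed = as.integer(seed)),
            class = "surrogate_config")
}

#' Iterative amplitude adjusted Fourier transform surrogate
#'
#' Constrained randomization preserving the value distribution exactly (the
#' surrogate is a permutation of the original samples) and the amplitude
#' spectrum approximately, while destroying any dependence with other series.
#' Iteration alternates spectrum substitution (impose the original amplitude
#' spectrum on the current phases) and rank-ordered amplitude substitution
#' (replace values by the original order statistics), stopping when the
#' permutation stabilizes, the spectrum matches within `tol`, or at `max_iter`.
#'
#' @param x numeric series (length >= 32).
#' @param seed integer seed for the initial permutation.
#' @param max_iter maximum iterations. @param tol relative RMS tolerance on the
#'   amplitude spectrum.
#' @return A numeric series, same length and value multiset as `x`.
#' @export
iaaft_surrogate <- function(x, seed = 1L, max_iter = 100L, tol = 1e-8) {
  n <- length(x)
  if (n < 32L) stop("iAAFT needs at least 32 samples")
  amp <- Mod(fft(x))
  sorted <- sort(x)
  y <- with_seed(seed, sample(x))
  prev <- NULL
  for (iter in seq_len(max_iter)) {
    Y <- fft(y)
    y2 <- Re(fft(amp * exp(1i * Arg(Y)), inverse = TRUE)) / n
    r <- rank(y2, ties.method = "first")
    y <- sorted[r]
    if (identical(r, prev)) break
    prev <- r
    if (sqrt(mean((Mod(fft(y)) - amp)^2)) / sqrt(mean(amp^2)) < tol) break
  }
  y
}

#' Time-shift surrogate
#'
#' Circular rotation of the series by a uniform random shift in
#' `[min_shift, N - min_shift]`, preserving the value multiset and the
#' circular autocorrelation exactly while destroying lagged cross-dependence.
#'
#' @param x numeric series with `N > 2 * min_shift`.
#' @param min_shift minimum shift in beats (default 20).
#' @param seed integer seed.
#' @return The rotated series.
#' @export
time_shift_surrogate <- function(x, min_shift = 20L, seed = 1L) {
  n <- length(x)
  if (n <= 2L * min_shift) stop("series too short for the requested minimum shift")
  s <- with_seed(seed, sample(min_shift:(n - min_shift), 1L))
  x[((seq_len(n) - 1L + s) %% n) + 1L]
}

#' Per-subject significance of one link
#'
#' Compares the observed causality measure with its distribution over
#' surrogate datasets built under the no-coupling null:
#' \itemize{
#'   \item MB path: every node series is replaced by an independent iAAFT
#'     surrogate (individual spectra and amplitude distributions preserved,
#'     all interconnections destroyed) and the conditional Granger causality
#'     is recomputed with the same model order.
#'   \item MF path: the target series is circularly time-shifted (minimum
#'     shift `min_shift`) with all other series untouched, and the model-free
#'     transfer entropy is recomputed with the same parameters, including
#'     re-selection of the embedding under the null.
#' }
#' The link is significant when the observed value exceeds the
#' `percentile`-th percentile (linear interpolation between order statistics)
#' of the surrogate values.
#'
#' @param estimator `"mb"` or `"mf"`.
#' @param series a [beat_series()] (detrended).
#' @param source,target link nodes.
#' @param cfg a [surrogate_config()].
#' @param dag a [zero_lag_dag()].
#' @param p MB model order (selected by AIC when `NULL`).
#' @param mf_params list of MF parameters (`L`, `k`, `Ns`, `alpha`).
#' @return A `link_significance`: list with `observed`, `surrogate_values`,
#'   `threshold`, `significant`, plus link/estimator metadata.
#' @export
link_significance <- function(estimator = c("mb", "mf"), series, source, target,
                              cfg = surrogate_config(), dag = zero_lag_dag(),
                              p = NULL, mf_params = list()) {
  estimator <- match.arg(estimator)
  source <- series$node_labels[node_index(series, source)]
  target <- series$node_labels[node_index(series, target)]
  seeds <- derive_seeds(cfg$seed, 2L * cfg$n_surrogates + 2L)

  if (estimator == "mb") {
    if (is.null(p)) p <- select_order_aic(series, dag)
    observed <- conditional_gc(series, source, target, dag, p)$F
    measure <- function(surr_series) conditional_gc(surr_series, source, target, dag, p)$F
    make_surr <- function(seed) {
      v <- series$values
      col_seeds <- derive_seeds(seed, ncol(v))
      for (cc in seq_len(ncol(v))) v[, cc] <- iaaft_surrogate(v[, cc], col_seeds[cc])
      s2 <- series; s2$values <- v; s2
    }
  } else {
    mp <- utils::modifyList(list(L = 10L, k = 10L, Ns = 100L, alpha = 0.05), mf_params)
    observed <- mf_cte(series, source, target, dag, mp$L, mp$k, mp$Ns, mp$alpha,
                       seed = seeds[1L])$T
    measure <- function(surr_series) {
      mf_cte(surr_series, source, target, dag, mp$L, mp$k, mp$Ns, mp$alpha,
             seed = attr(surr_series, "mf_seed"))$T
    }
    make_surr <- function(seed) {
      ss <- derive_seeds(seed, 2L)
      v <- series$values
      v[, target] <- time_shift_surrogate(v[, target], cfg$min_shift, ss[1L])
      s2 <- series; s2$values <- v
      attr(s2, "mf_seed") <- ss[2L]
      s2
    }
  }

  surr_vals <- numeric(cfg$n_surrogates)
  for (s in seq_len(cfg$n_surrogates)) {
    val <- NULL
    for (attempt in 0L:10L) {
      sd_s <- seeds[1L + s] + attempt * 7919L
      val <- tryCatch(measure(make_surr(sd_s)), error = function(e) NULL)
      if (!is.null(val)) break
    }
    if (is.null(val)) stop("surrogate replicate failed after 10 redraws")
    surr_vals[s] <- val
  }
  thr <- surrogate_threshold(surr_vals, cfg$percentile)
  structure(
    list(estimator = estimator, source = source, target = target,
         observed = observed, surrogate_values = surr_vals, threshold = thr,
         significant = observed > thr),
    class = "link_significance"
  )
}

#' Significance of every link of one subject's network
#'
#' Shares surrogate datasets across links where the null permits it: the MB
#' iAAFT scheme randomizes all columns, so one surrogate dataset serves all
#' 12 links; the MF time-shift scheme rotates the target, so one rotated
#' dataset serves the links into that target.
#'
#' @inheritParams link_significance
#' @return data.frame with one row per directed link: `source`, `target`,
#'   `observed`, `threshold`, `significant`.
#' @export
network_significance <- function(estimator = c("mb", "mf"), series,
                                 cfg = surrogate_config(), dag = zero_lag_dag(),
                                 p = NULL, mf_params = list()) {
  estimator <- match.arg(estimator)
  nodes <- series$node_labels
  seeds <- derive_seeds(cfg$seed, cfg$n_surrogates + length(nodes) + 1L)

  if (estimator == "mb") {
    if (is.null(p)) p <- select_order_aic(series, dag)
    obs <- mb_network(series, dag, p = p)$links
    surr <- vector("list", cfg$n_surrogates)
    for (s in seq_len(cfg$n_surrogates)) {
      v <- series$values
      col_seeds <- derive_seeds(seeds[s], ncol(v))
      for (cc in seq_len(ncol(v))) v[, cc] <- iaaft_surrogate(v[, cc], col_seeds[cc])
      s2 <- series; s2$values <- v
      surr[[s]] <- mb_network(s2, dag, p = p)$links$F
    }
    surr <- do.call(cbind, surr)            # 12 x n_surrogates
    thr <- apply(surr, 1L, surrogate_threshold, percentile = cfg$percentile)
    data.frame(source = obs$source, target = obs$target, observed = obs$F,
               threshold = thr, significant = obs$F > thr)
  } else {
    mp <- utils::modifyList(list(L = 10L, k = 10L, Ns = 100L, alpha = 0.05), mf_params)
    out <- list()
    for (ti in seq_along(nodes)) {
      tgt <- nodes[ti]
      srcs <- setdiff(nodes, tgt)
      pair_seeds <- derive_seeds(seeds[cfg$n_surrogates + ti], length(srcs))
      obs_vals <- vapply(seq_along(srcs), function(si) {
        mf_cte(series, srcs[si], tgt, dag, mp$L, mp$k, mp$Ns, mp$alpha,
               seed = pair_seeds[si])$T
      }, 1.0)
      surr_vals <- matrix(0, length(srcs), cfg$n_surrogates)
      for (s in seq_len(cfg$n_surrogates)) {
        ss <- derive_seeds(seeds[s] + ti, length(srcs) + 1L)
        v <- series$values
        v[, tgt] <- time_shift_surrogate(v[, tgt], cfg$min_shift, ss[1L])
        s2 <- series; s2$values <- v
        for (si in seq_along(srcs)) {
          surr_vals[si, s] <- mf_cte(s2, srcs[si], tgt, dag, mp$L, mp$k, mp$Ns,
                                     mp$alpha, seed = ss[1L + si])$T
        }
      }
      thr <- apply(surr_vals, 1L, surrogate_threshold, percentile = cfg$percentile)
      out[[ti]] <- data.frame(source = srcs, target = tgt, observed = obs_vals,
                              threshold = thr, significant = obs_vals > thr)
    }
    do.call(rbind, out)
  }
}

#' Cohort significance degree of one link
#'
#' The degree of significance `s` is the percentage of subjects for which the
#' link passed the per-subject surrogate test, binned into
#' none (`s < 25`), low (`[25, 50)`, reported but not considered statistically
#' relevant), medium (`[50, 75)`) and high (`[75, 100]`).
#'
#' @param flags logical vector, one per subject.
#' @return list with `n_significant`, `n_total`, `s` (percent), `class`.
#' @export
significance_degree <- function(flags) {
  flags <- as.logical(flags)
  if (!length(flags)) stop("need at least one subject")
  n_sig <- sum(flags)
  s <- 100 * n_sig / length(flags)
  cls <- if (s < 25) "none" else if (s < 50) "low" else if (s < 75) "medium" else "high"
  list(n_significant = n_sig, n_total = length(flags), s = s, class = cls)
}
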