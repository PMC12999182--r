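#' Simulation configuration for a synthetic beat-to-beat network
#'
#' Defines a stationary four-node beat-to-beat system: each node follows its
#' own autoregression plus lagged and within-beat (zero-lag) linear couplings
#' from other nodes, optional nonlinear couplings, and Gaussian innovations.
#' Zero-lag couplings must lie on the zero-lag DAG, which makes the
#' within-beat system recursive and the model well defined.
#'
#' @param linear_coupling data.frame with columns `source`, `target`, `lag`
#'   (integer >= 0) and `coef`.
#' @param nonlinear_coupling optional data.frame with columns `source`,
#'   `target`, `lag`, `form` (`"quadratic"` or `"threshold"`) and `coef`.
#' @param self_dynamics named list: per-node numeric vector of AR coefficients.
#' @param noise_sd named numeric vector of innovation standard deviations.
#' @param n_samples number of beats returned per realization (default 300,
#'   the standard short-term stationary window length).
#' @param dag a [zero_lag_dag()]; also fixes the node set and their order.
#' @param seed default seed used when [generate_subject()] is called without one.
#'
#' @details Stability of the implied linear system is checked at construction:
#' with `A0` the zero-lag coefficient matrix the reduced-form lag matrices are
#' `(I - A0)^{-1} A_k`, and the spectral radius of their companion matrix must
#' be `< 1`. Nonlinear couplings use a source value standardized by its
#' stationary SD under the linear part, so they perturb rather than destabilize.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(linear_coupling = NULL, nonlinear_coupling = NULL,
                       self_dynamics = list(), noise_sd = NULL,
                       n_samples = 300L, dag = zero_lag_dag(), seed = 1L) {
  nodes <- dag$node_order
  m <- length(nodes)
  empty <- data.frame(source = character(), target = character(),
                      lag = integer(), coef = numeric())
  linear_coupling <- if (is.null(linear_coupling)) empty else as.data.frame(linear_coupling)
  if (nrow(linear_coupling)) {
    stopifnot(all(c("source", "target", "lag", "coef") %in% names(linear_coupling)))
  }
  if (!is.null(nonlinear_coupling)) {
    nonlinear_coupling <- as.data.frame(nonlinear_coupling)
    stopifnot(all(c("source", "target", "lag", "form", "coef") %in% names(nonlinear_coupling)))
    if (!all(nonlinear_coupling$form %in% c("quadratic", "threshold"))) {
      stop("nonlinear form must be 'quadratic' or 'threshold'")
    }
  }
  for (cp in list(linear_coupling, nonlinear_coupling)) {
    if (is.null(cp) || !nrow(cp)) next
    if (!all(cp$source %in% nodes) || !all(cp$target %in% nodes)) {
      stop("coupling endpoints must be DAG nodes")
    }
    if (any(cp$lag < 0)) stop("coupling lags must be >= 0")
    if (any(cp$source == cp$target)) stop("self couplings belong in self_dynamics")
    z <- cp[cp$lag == 0L, , drop = FALSE]
    for (r in seq_len(nrow(z))) {
      if (!dag_has_edge(dag, z$source[r], z$target[r])) {
        stop(sprintf("zero-lag coupling %s->%s is not an edge of the zero-lag DAG",
                     z$source[r], z$target[r]))
      }
    }
  }
  if (is.null(noise_sd)) noise_sd <- stats::setNames(rep(1, m), nodes)
  if (is.null(names(noise_sd))) names(noise_sd) <- nodes
  stopifnot(all(nodes %in% names(noise_sd)), all(noise_sd > 0))
  cfg <- structure(
    list(nodes = nodes, n_samples = as.integer(n_samples),
         linear_coupling = linear_coupling, nonlinear_coupling = nonlinear_coupling,
         self_dynamics = self_dynamics, noise_sd = noise_sd[nodes],
         dag = dag, seed = as.integer(seed)),
    class = "sim_config"
  )
  sr <- spectral_radius(cfg)
  if (sr >= 1) {
    stop(sprintf("unstable configuration: companion spectral radius %.4f >= 1", sr))
  }
  cfg$spectral_radius <- sr
  cfg
}

# Coefficient matrices A_k (k = 0..p) of the linear part; A_k[j, i] weights
# source i at lag k in the equation of target j. Self dynamics sit on the
# diagonal for k >= 1.
coef_matrices <- function(config) {
  nodes <- config$nodes
  m <- length(nodes)
  p <- max(c(0L, config$linear_coupling$lag,
             vapply(config$self_dynamics, length, 1L),
             if (!is.null(config$nonlinear_coupling)) config$nonlinear_coupling$lag))
  A <- lapply(seq_len(p + 1L), function(i) {
    matrix(0, m, m, dimnames = list(nodes, nodes))
  })
  for (nd in names(config$self_dynamics)) {
    ar <- config$self_dynamics[[nd]]
    for (k in seq_along(ar)) A[[k + 1L]][nd, nd] <- ar[k]
  }
  lc <- config$linear_coupling
  for (r in seq_len(nrow(lc))) {
    k <- lc$lag[r] + 1L
    A[[k]][lc$target[r], lc$source[r]] <- A[[k]][lc$target[r], lc$source[r]] + lc$coef[r]
  }
  A
}

# Spectral radius of the companion matrix of the reduced-form VAR
# X_n = (I-A0)^{-1} sum_k A_k X_{n-k} + (I-A0)^{-1} U_n.
spectral_radius <- function(config) {
  A <- coef_matrices(config)
  m <- length(config$nodes)
  p <- length(A) - 1L
  if (p == 0L) return(0)
  B0 <- solve(diag(m) - A[[1L]])
  comp <- matrix(0, m * p, m * p)
  for (k in seq_len(p)) {
    comp[seq_len(m), (k - 1L) * m + seq_len(m)] <- B0 %*% A[[k + 1L]]
  }
  if (p > 1L) {
    comp[m + seq_len(m * (p - 1L)), seq_len(m * (p - 1L))] <-
      diag(m * (p - 1L))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# Stationary covariance of the linear part via the discrete Lyapunov equation
# on the companion form. Used to standardize nonlinear coupling inputs.
stationary_cov <- function(config) {
  A <- coef_matrices(config)
  m <- length(config$nodes)
  p <- length(A) - 1L
  B0 <- solve(diag(m) - A[[1L]])
  Q <- B0 %*% diag(config$noise_sd^2, m) %*% t(B0)
  if (p == 0L) return(Q)
  comp <- matrix(0, m * p, m * p)
  for (k in seq_len(p)) comp[seq_len(m), (k - 1L) * m + seq_len(m)] <- B0 %*% A[[k + 1L]]
  if (p > 1L) comp[m + seq_len(m * (p - 1L)), seq_len(m * (p - 1L))] <- diag(m * (p - 1L))
  Qe <- matrix(0, m * p, m * p)
  Qe[seq_len(m), seq_len(m)] <- Q
  vecS <- solve(diag((m * p)^2) - kronecker(comp, comp), as.vector(Qe))
  S <- matrix(vecS, m * p, m * p)
  S[seq_len(m), seq_len(m), drop = FALSE]
}

nonlinear_transform <- function(x, form) {
  switch(form,
         quadratic = x^2 - 1,
         threshold = as.numeric(x > 0) - 0.5,
         stop("unknown nonlinear form: ", form))
}

#' Generate one synthetic subject
#'
#' Simulates the configured system, discarding a burn-in of 500 beats so the
#' returned window is stationary. Innovations are drawn up front and nodes are
#' evaluated within each beat in DAG (topological) order, so any valid
#' evaluation order yields the identical series.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @param condition,subject_id metadata for the returned series.
#' @param topo_order optional alternative DAG-consistent node evaluation order
#'   (used to verify order invariance).
#' @return A [beat_series()] of `config$n_samples` beats.
#' @export
generate_subject <- function(config, seed = config$seed, condition = "REST",
                             subject_id = "S1", topo_order = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples < 50L) stop("n_samples must be >= 50")
  nodes <- config$nodes
  m <- length(nodes)
  burn <- 500L
  total <- config$n_samples + burn
  if (is.null(topo_order)) topo_order <- nodes
  if (!setequal(topo_order, nodes)) stop("topo_order must be a permutation of the nodes")
  pos <- match(topo_order, config$dag$node_order)
  for (r in seq_len(nrow(config$dag$edges))) {
    if (match(config$dag$edges[r, 1], topo_order) > match(config$dag$edges[r, 2], topo_order))
      stop("topo_order is not DAG-consistent")
  }

  innov <- with_seed(seed, {
    e <- matrix(rnorm(total * m), total, m, dimnames = list(NULL, nodes))
    sweep(e, 2L, config$noise_sd, `*`)
  })

  nl <- config$nonlinear_coupling
  nl_sd <- NULL
  if (!is.null(nl) && nrow(nl)) {
    S <- stationary_cov(config)
    dimnames(S) <- list(nodes, nodes)
    nl_sd <- sqrt(pmax(diag(S), .Machine$double.eps))
  }

  x <- matrix(0, total, m, dimnames = list(NULL, nodes))
  lc <- config$linear_coupling
  for (n in seq_len(total)) {
    for (nd in topo_order) {
      v <- innov[n, nd]
      ar <- config$self_dynamics[[nd]]
      for (k in seq_along(ar)) if (n > k) v <- v + ar[k] * x[n - k, nd]
      rows <- which(lc$target == nd)
      for (r in rows) {
        k <- lc$lag[r]
        if (n > k) v <- v + lc$coef[r] * x[n - k, lc$source[r]]
      }
      if (!is.null(nl) && nrow(nl)) {
        rows <- which(nl$target == nd)
        for (r in rows) {
          k <- nl$lag[r]
          if (n > k) {
            s <- x[n - k, nl$source[r]] / nl_sd[nl$source[r]]
            v <- v + nl$coef[r] * nonlinear_transform(s, nl$form[r])
          }
        }
      }
      x[n, nd] <- v
    }
  }
  beat_series(x[burn + seq_len(config$n_samples), , drop = FALSE],
              node_labels = nodes, condition = condition, subject_id = subject_id)
}

#' Ground-truth adjacency of a configuration
#'
#' @param config a [sim_config()].
#' @return A list with `adjacency` (logical source x target matrix, `TRUE`
#'   where any coupling at any lag, including 0, exists) and `nonlinear`
#'   (logical matrix flagging links with a nonlinear component).
#' @export
ground_truth <- function(config) {
  nodes <- config$nodes
  m <- length(nodes)
  adj <- matrix(FALSE, m, m, dimnames = list(source = nodes, target = nodes))
  nlm <- adj
  lc <- config$linear_coupling
  for (r in seq_len(nrow(lc))) {
    if (lc$coef[r] != 0) adj[lc$source[r], lc$target[r]] <- TRUE
  }
  nl <- config$nonlinear_coupling
  if (!is.null(nl)) {
    for (r in seq_len(nrow(nl))) {
      if (nl$coef[r] != 0) {
        adj[nl$source[r], nl$target[r]] <- TRUE
        nlm[nl$source[r], nl$target[r]] <- TRUE
      }
    }
  }
  list(adjacency = adj, nonlinear = nlm)
}

#' Default resting-state configuration
#'
#' A linear-Gaussian four-node system emulating supine rest: respiration R is
#' an autonomous AR(2) oscillator near 0.25 cycles/beat; heart period H
#' receives respiratory drive (respiratory sinus arrhythmia, lag 0 and 1) and
#' baroreflex input from pressure M (lag 1); M receives within-beat feedforward
#' from H, respiratory drive and a weak compliance effect; compliance C is
#' driven within-beat by M, H and R plus a lagged H effect.
#'
#' @param n_samples beats per realization.
#' @return A [sim_config()].
#' @export
default_rest_config <- function(n_samples = 300L) {
  sim_config(
    linear_coupling = data.frame(
      source = c("R", "R", "M", "H", "R", "C", "M", "H", "H", "R"),
      target = c("H", "H", "H", "M", "M", "M", "C", "C", "C", "C"),
      lag    = c(0L,  1L,  1L,  0L,  1L,  1L,  0L,  0L,  1L,  0L),
      coef   = c(0.4, 0.2, 0.3, 0.3, 0.2, 0.1, 0.3, 0.25, 0.15, 0.2)
    ),
    self_dynamics = list(R = c(0, -0.81), H = c(0.6, -0.1), M = 0.5, C = 0.5),
    n_samples = n_samples
  )
}

#' Default head-up tilt configuration
#'
#' Same topology as [default_rest_config()] with the sympathetic-shift pattern:
#' respiratory drive on H and the H influence on C halved; baroreflex M->H,
#' respiratory drive on M and the C->M effect increased.
#'
#' @inheritParams default_rest_config
#' @return A [sim_config()].
#' @export
default_hut_config <- function(n_samples = 300L) {
  sim_config(
    linear_coupling = data.frame(
      source = c("R", "R", "M", "H", "R", "C", "M", "H", "H", "R"),
      target = c("H", "H", "H", "M", "M", "M", "C", "C", "C", "C"),
      lag    = c(0L,  1L,  1L,  0L,  1L,  1L,  0L,  0L,  1L,  0L),
      coef   = c(0.2, 0.1, 0.4, 0.3, 0.3, 0.2, 0.3, 0.125, 0.075, 0.2)
    ),
    self_dynamics = list(R = c(0, -0.81), H = c(0.6, -0.1), M = 0.5, C = 0.5),
    n_samples = n_samples
  )
}

#' Nonlinear variant of the resting configuration
#'
#' Replaces the linear respiratory drive on H with a quadratic coupling
#' (standardized source squared, lag 1). A linear model-based estimator is
#' blind to this link while the model-free estimator is not, which makes the
#' MB-vs-MF detection contrast testable on synthetic data.
#'
#' @inheritParams default_rest_config
#' @param coef quadratic coupling coefficient.
#' @return A [sim_config()].
#' @export
default_nonlinear_config <- function(n_samples = 300L, coef = 0.6) {
  base <- default_rest_config(n_samples)
  lc <- base$linear_coupling
  lc <- lc[!(lc$source == "R" & lc$target == "H"), ]
  sim_config(
    linear_coupling = lc,
    nonlinear_coupling = data.frame(source = "R", target = "H", lag = 1L,
                                    form = "quadratic", coef = coef),
    self_dynamics = base$self_dynamics,
    n_samples = n_samples
  )
}

# Multiplicative coefficient jitter shared between the paired conditions of one
# subject; redrawn (up to max_attempts) until both jittered systems are stable.
jitter_configs <- function(rest, hut, jitter_sd = 0.10, max_attempts = 100L) {
  for (attempt in seq_len(max_attempts)) {
    fac <- rnorm(nrow(rest$linear_coupling), 1, jitter_sd)
    fac_nl <- if (!is.null(rest$nonlinear_coupling)) {
      rnorm(nrow(rest$nonlinear_coupling), 1, jitter_sd)
    } else NULL
    out <- lapply(list(rest, hut), function(cfg) {
      lc <- cfg$linear_coupling
      lc$coef <- lc$coef * fac
      nl <- cfg$nonlinear_coupling
      if (!is.null(nl)) nl$coef <- nl$coef * fac_nl
      tryCatch(sim_config(lc, nl, cfg$self_dynamics, cfg$noise_sd,
                          cfg$n_samples, cfg$dag, cfg$seed),
               error = function(e) NULL)
    })
    if (!any(vapply(out, is.null, TRUE))) return(out)
  }
  stop("could not draw a stable jittered configuration in ", max_attempts, " attempts")
}

same_topology <- function(a, b) {
  key <- function(cfg) {
    lc <- cfg$linear_coupling
    k1 <- paste(lc$source, lc$target, lc$lag, sep = ":")
    nl <- cfg$nonlinear_coupling
    k2 <- if (is.null(nl)) character() else paste(nl$source, nl$target, nl$lag, nl$form, sep = ":")
    list(sort(k1), sort(k2), cfg$nodes)
  }
  identical(key(a), key(b))
}

#' Generate a paired synthetic cohort
#'
#' Each subject gets one REST and one HUT realization sharing subject-specific
#' multiplicative coefficient jitter (SD 10% of each coupling coefficient), so
#' the cohort has between-subject variability with a paired condition shift.
#' Subject seeds are a prefix-stable stream of `master_seed`: subject i's data
#' do not change when `n_subjects` grows.
#'
#' @param rest,hut [sim_config()]s sharing the same topology.
#' @param n_subjects number of subjects (>= 2).
#' @param master_seed integer seed for the whole cohort.
#' @param jitter_sd SD of the multiplicative coefficient jitter.
#' @return A list of `n_subjects` elements, each `list(rest =, hut =)` of
#'   [beat_series()], with attribute `"ground_truth"` from the REST config.
#' @export
generate_cohort <- function(rest, hut, n_subjects, master_seed = 1L,
                            jitter_sd = 0.10) {
  stopifnot(inherits(rest, "sim_config"), inherits(hut, "sim_config"))
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  if (!same_topology(rest, hut)) stop("REST and HUT configurations have mismatched topologies")
  seeds <- derive_seeds(master_seed, n_subjects * 2L)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", i)
    cfgs <- with_seed(seeds[2L * i - 1L], jitter_configs(rest, hut, jitter_sd))
    subjects[[i]] <- list(
      rest = generate_subject(cfgs[[1L]], seed = seeds[2L * i], condition = "REST",
                              subject_id = sid),
      hut = generate_subject(cfgs[[2L]], seed = seeds[2L * i] + 1L, condition = "HUT",
                             subject_id = sid)
    )
  }
  attr(subjects, "ground_truth") <- ground_truth(rest)
  subjects
}

#' Write a cohort to disk
#'
#' One comma-separated table per subject-condition plus a JSON manifest mapping
#' subject ids to file paths and a JSON ground-truth adjacency.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(subjects = list())
  for (sub in cohort) {
    sid <- sub$rest$subject_id
    files <- list()
    for (cond in names(sub)) {
      fn <- sprintf("%s_%s.csv", sid, sub[[cond]]$condition)
      write_beat_series(sub[[cond]], file.path(dir, fn))
      files[[sub[[cond]]$condition]] <- fn
    }
    manifest$subjects[[sid]] <- files
  }
  gt <- attr(cohort, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(
      list(nodes = colnames(gt$adjacency),
           adjacency = unname(apply(gt$adjacency, 1L, as.list)),
           nonlinear = unname(apply(gt$nonlinear, 1L, as.list))),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE
    )
    manifest$ground_truth <- "ground_truth.json"
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.json`.
#' @return A cohort list in the same shape as [generate_cohort()] output.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  cohort <- lapply(names(manifest$subjects), function(sid) {
    files <- manifest$subjects[[sid]]
    stats::setNames(
      lapply(names(files), function(cond) {
        read_beat_series(file.path(dir, files[[cond]]), condition = cond,
                         subject_id = sid)
      }),
      tolower(names(files))
    )
  })
  cohort
}
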