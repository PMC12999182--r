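#' Paired Wilcoxon signed rank test
#'
#' Two-sided test on paired samples: zero differences are dropped, the exact
#' signed-rank distribution is enumerated for n <= 25 without ties in the
#' absolute differences, and the normal approximation with continuity
#' correction is used otherwise.
#'
#' @param x,y equal-length paired numeric vectors.
#' @return list with `statistic` (V), `p.value`, `n` (pairs used).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p.value = 1, n = 0L))
  }
  if (length(d) < 5L) warning("fewer than 5 nonzero differences; test has little power")
  exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p.value = min(wt$p.value, 1),
       n = length(d))
}

#' Benjamini-Hochberg FDR decisions
#'
#' Step-up procedure: with sorted p-values, reject up to the largest i with
#' `p_(i) <= i q / m`; adjusted p-values by step-up monotonization.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `reject` (logical, original order), `adjusted`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(reject = adjusted <= q, adjusted = adjusted)
}

#' Collect per-subject link estimates of one cohort-condition
#'
#' @param networks list of `causality_network` objects (one per subject, same
#'   estimator and condition).
#' @return data.frame `subject`, `source`, `target`, `estimate` (F for MB,
#'   T for MF).
#' @export
collect_links <- function(networks) {
  est <- unique(vapply(networks, function(n) n$estimator, ""))
  if (length(est) != 1L) stop("networks mix estimators")
  do.call(rbind, lapply(networks, function(nw) {
    data.frame(subject = nw$subject_id, source = nw$links$source,
               target = nw$links$target,
               estimate = if (est == "mb") nw$links$F else nw$links$T)
  }))
}

#' Paired condition comparison of two cohort networks
#'
#' Per-link paired Wilcoxon signed rank test on the subject-wise estimates,
#' Benjamini-Hochberg corrected within the family of the estimator's 12 links;
#' the direction of a rejected link is the sign of the median paired
#' difference (`HUT>REST` / `HUT<REST`).
#'
#' @param rest,hut data.frames from [collect_links()] (same subjects, links).
#' @param q FDR level.
#' @param labels length-2 condition labels used in the direction string.
#' @return data.frame per link: `source`, `target`, `statistic`, `p`,
#'   `p_adj`, `reject`, `direction`.
#' @export
compare_networks <- function(rest, hut, q = 0.05, labels = c("REST", "HUT")) {
  key <- function(d) paste(d$subject, d$source, d$target)
  hut <- hut[match(key(rest), key(hut)), ]
  if (anyNA(hut$estimate) && !anyNA(rest$estimate)) {
    stop("REST and HUT cohorts do not share subjects and links")
  }
  links <- unique(rest[, c("source", "target")])
  res <- do.call(rbind, lapply(seq_len(nrow(links)), function(r) {
    sel <- rest$source == links$source[r] & rest$target == links$target[r]
    wt <- wilcoxon_signed_rank(hut$estimate[sel], rest$estimate[sel])
    data.frame(source = links$source[r], target = links$target[r],
               statistic = wt$statistic, p = wt$p.value,
               med_diff = stats::median(hut$estimate[sel] - rest$estimate[sel]))
  }))
  fdr <- bh_fdr(res$p, q)
  res$p_adj <- fdr$adjusted
  res$reject <- fdr$reject
  res$direction <- ifelse(!res$reject, "none",
                          ifelse(res$med_diff > 0,
                                 paste0(labels[2], ">", labels[1]),
                                 paste0(labels[2], "<", labels[1])))
  res$med_diff <- NULL
  rownames(res) <- NULL
  res
}

#' Cohort significance summary per link
#'
#' @param sig_tables list of per-subject data.frames from
#'   [network_significance()].
#' @return data.frame per link: `source`, `target`, `n_significant`,
#'   `n_total`, `s`, `class`.
#' @export
significance_summary <- function(sig_tables) {
  links <- sig_tables[[1L]][, c("source", "target")]
  do.call(rbind, lapply(seq_len(nrow(links)), function(r) {
    flags <- vapply(sig_tables, function(tb) {
      tb$significant[tb$source == links$source[r] & tb$target == links$target[r]]
    }, TRUE)
    deg <- significance_degree(flags)
    data.frame(source = links$source[r], target = links$target[r],
               n_significant = deg$n_significant, n_total = deg$n_total,
               s = deg$s, class = deg$class)
  }))
}

#' Export a link table as a JSON weighted adjacency
#'
#' @param links data.frame with `source`, `target` and a weight column.
#' @param path output path.
#' @param weight name of the weight column.
#' @export
write_network_json <- function(links, path, weight = intersect(c("F", "T", "estimate"),
                                                               names(links))[1L]) {
  nodes <- unique(c(links$source, links$target))
  adj <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(links))) {
    adj[links$source[r], links$target[r]] <- links[[weight]][r]
  }
  jsonlite::write_json(list(nodes = nodes, weights = unname(apply(adj, 1L, as.list))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    cohort = list(n_subjects = 20L, n_samples = 300L, nonlinear = FALSE,
                  jitter_sd = 0.10),
    preprocess = list(cutoff_hz = 0.0156),
    mb = list(p_range = 1:10),
    mf = list(enabled = TRUE, L = 10L, k = 10L, Ns = 100L, alpha = 0.05),
    surrogates = list(n_surrogates = 100L, percentile = 95, min_shift = 20L),
    output_dir = "ctenet-results"
  )
}

#' Run the full cohort analysis pipeline
#'
#' Simulates (or loads) a paired REST/HUT cohort, detrends it, estimates the
#' model-based (and optionally model-free) causality network of every
#' subject-condition, assesses per-subject link significance against
#' surrogates, summarizes cohort significance degrees, compares conditions
#' with paired Wilcoxon tests under FDR control, and writes all tables, JSON
#' networks and a run log to `output_dir`.
#'
#' @param config named list (see `mb_only` / `n_surrogates` shortcuts below for
#'   desk-scale runs) or path to a YAML/JSON file with the same structure.
#'   Fields default to: seed 1; cohort (n_subjects 20, n_samples 300,
#'   nonlinear FALSE); preprocess (cutoff_hz 0.0156); mb (p_range 1:10);
#'   mf (enabled TRUE, L 10, k 10, Ns 100, alpha 0.05); surrogates
#'   (n_surrogates 100, percentile 95, min_shift 20); output_dir.
#'   Set `config$cohort$dir` to load a cohort written by [write_cohort()]
#'   instead of simulating.
#' @param mb_only if TRUE, skip the (slow) model-free path.
#' @param n_surrogates override of `config$surrogates$n_surrogates` for
#'   desk-scale runs.
#' @return Invisibly, a list with `markers`, `networks`, `significance`,
#'   `degrees`, `comparison` per estimator.
#' @export
run_pipeline <- function(config = list(), mb_only = FALSE, n_surrogates = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package required")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (isTRUE(mb_only)) cfg$mf$enabled <- FALSE
  if (!is.null(n_surrogates)) cfg$surrogates$n_surrogates <- as.integer(n_surrogates)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  dag <- zero_lag_dag()
  seeds <- derive_seeds(cfg$seed, 6L)

  if (!is.null(cfg$cohort$dir)) {
    cohort <- read_cohort(cfg$cohort$dir)
  } else {
    rest_cfg <- if (isTRUE(cfg$cohort$nonlinear)) {
      default_nonlinear_config(cfg$cohort$n_samples)
    } else default_rest_config(cfg$cohort$n_samples)
    cohort <- generate_cohort(rest_cfg, default_hut_config(cfg$cohort$n_samples),
                              cfg$cohort$n_subjects, master_seed = seeds[1L],
                              jitter_sd = cfg$cohort$jitter_sd %||% 0.10)
  }

  markers <- do.call(rbind, lapply(cohort, function(sub) {
    rbind(time_domain_markers(sub$rest), time_domain_markers(sub$hut))
  }))
  utils::write.csv(markers, file.path(cfg$output_dir, "markers.csv"), row.names = FALSE)

  pre <- lapply(cohort, function(sub) {
    lapply(sub, highpass_detrend, cutoff_hz = cfg$preprocess$cutoff_hz)
  })

  estimators <- c("mb", if (isTRUE(cfg$mf$enabled)) "mf")
  out <- list(markers = markers, networks = list(), significance = list(),
              degrees = list(), comparison = list())
  for (est in estimators) {
    for (cond in c("rest", "hut")) {
      nws <- lapply(seq_along(pre), function(i) {
        s <- pre[[i]][[cond]]
        if (est == "mb") {
          mb_network(s, dag, p_range = cfg$mb$p_range)
        } else {
          mf_network(s, dag, cfg$mf$L, cfg$mf$k, cfg$mf$Ns, cfg$mf$alpha,
                     seed = seeds[2L] + i)
        }
      })
      out$networks[[paste(est, cond, sep = "_")]] <- nws
      links <- collect_links(nws)
      utils::write.csv(links, file.path(cfg$output_dir,
                                        sprintf("links_%s_%s.csv", est, cond)),
                       row.names = FALSE)
      mean_links <- stats::aggregate(estimate ~ source + target, links, mean)
      write_network_json(mean_links,
                         file.path(cfg$output_dir,
                                   sprintf("network_%s_%s.json", est, cond)))
      sig <- lapply(seq_along(pre), function(i) {
        network_significance(est, pre[[i]][[cond]],
                             surrogate_config(cfg$surrogates$n_surrogates,
                                              cfg$surrogates$percentile,
                                              if (est == "mb") "iaaft" else "time_shift",
                                              cfg$surrogates$min_shift,
                                              seed = seeds[3L] + i),
                             dag, mf_params = cfg$mf)
      })
      out$significance[[paste(est, cond, sep = "_")]] <- sig
      deg <- significance_summary(sig)
      out$degrees[[paste(est, cond, sep = "_")]] <- deg
      utils::write.csv(deg, file.path(cfg$output_dir,
                                      sprintf("significance_%s_%s.csv", est, cond)),
                       row.names = FALSE)
    }
    cmp <- compare_networks(collect_links(out$networks[[paste0(est, "_rest")]]),
                            collect_links(out$networks[[paste0(est, "_hut")]]))
    out$comparison[[est]] <- cmp
    utils::write.csv(cmp, file.path(cfg$output_dir,
                                    sprintf("comparison_%s.csv", est)),
                     row.names = FALSE)
  }
  log <- list(config = cfg[setdiff(names(cfg), "output_dir")],
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              estimators = estimators)
  jsonlite::write_json(log, file.path(cfg$output_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(out)
}
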