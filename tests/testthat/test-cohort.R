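test_that("the signed rank test matches exhaustive enumeration", {
  # n = 6, all differences positive with distinct magnitudes: enumerate all
  # 2^6 sign assignments of the ranks to get the exact two-sided p
  x <- c(5, 9, 14, 20, 27, 35)
  y <- c(4, 7, 11, 16, 22, 29)
  res <- wilcoxon_signed_rank(x, y)
  ranks <- rank(abs(x - y))
  vmax <- sum(ranks)
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  vdist <- as.matrix(signs) %*% ranks
  observed <- sum(ranks[(x - y) > 0])
  p_exact <- mean(vdist >= observed) + mean(vdist <= vmax - observed)
  expect_equal(p_exact, 2 / 64)
  expect_equal(res$p.value, p_exact)

  expect_warning(res0 <- wilcoxon_signed_rank(1:6, 1:6), "zero")
  expect_equal(res0$p.value, 1)
})

test_that("large-sample signed rank uses the corrected normal approximation", {
  set.seed(120)
  x <- rnorm(40); y <- x - 0.5 - rnorm(40, sd = 0.3)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(ours$p.value, ref$p.value)
  expect_lt(ours$p.value, 0.001)
})

test_that("BH decisions follow the step-up rule", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  out <- bh_fdr(p, q = 0.05)
  expect_equal(sum(out$reject), 4L)
  expect_false(out$reject[5])
  # adjusted p monotone nondecreasing in raw-p order
  expect_true(all(diff(out$adjusted[order(p)]) >= 0))

  expect_equal(sum(bh_fdr(rep(1, 10))$reject), 0L)
  expect_true(bh_fdr(0.04, q = 0.05)$reject)
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")
})

fake_cohort_links <- function(effect = 0, n_sub = 12L, seed = 1L) {
  set.seed(seed)
  nodes <- c("R", "H", "M", "C")
  pairs <- expand.grid(source = nodes, target = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  do.call(rbind, lapply(seq_len(n_sub), function(i) {
    est <- abs(rnorm(nrow(pairs), 0.2, 0.05))
    est[pairs$source == "M" & pairs$target == "H"] <-
      est[pairs$source == "M" & pairs$target == "H"] + effect
    data.frame(subject = sprintf("S%02d", i), source = pairs$source,
               target = pairs$target, estimate = est)
  }))
}

test_that("identical cohorts yield no rejected links", {
  rest <- fake_cohort_links(seed = 2L)
  suppressWarnings(cmp <- compare_networks(rest, rest))
  expect_equal(nrow(cmp), 12L)
  expect_false(any(cmp$reject))
  expect_true(all(cmp$direction == "none"))
})

test_that("condition comparison finds a known shift and is antisymmetric", {
  rest <- fake_cohort_links(effect = 0, seed = 3L)
  hut <- fake_cohort_links(effect = 0.15, seed = 4L)
  cmp <- compare_networks(rest, hut)
  mh <- cmp[cmp$source == "M" & cmp$target == "H", ]
  expect_true(mh$reject)
  expect_equal(mh$direction, "HUT>REST")

  flipped <- compare_networks(hut, rest)
  expect_equal(flipped$p, cmp$p)
  mh2 <- flipped[flipped$source == "M" & flipped$target == "H", ]
  expect_equal(mh2$direction, "HUT<REST")
})

test_that("the pipeline writes a complete, reproducible report bundle", {
  cfg <- list(seed = 99L,
              cohort = list(n_subjects = 6L, n_samples = 300L),
              mb = list(p_range = 1:4),
              surrogates = list(n_surrogates = 20L, percentile = 95, min_shift = 20L),
              output_dir = file.path(tempdir(), "ctenet-demo"))
  out <- suppressWarnings(run_pipeline(cfg, mb_only = TRUE))
  files <- list.files(cfg$output_dir)
  expect_true(all(c("markers.csv", "links_mb_rest.csv", "links_mb_hut.csv",
                    "significance_mb_rest.csv", "significance_mb_hut.csv",
                    "comparison_mb.csv", "network_mb_rest.json",
                    "run_log.json") %in% files))
  links <- read.csv(file.path(cfg$output_dir, "links_mb_rest.csv"))
  expect_equal(nrow(links), 6L * 12L)
  expect_equal(nrow(out$comparison$mb), 12L)

  # rerun: identical outputs
  links1 <- readLines(file.path(cfg$output_dir, "links_mb_rest.csv"))
  cmp1 <- readLines(file.path(cfg$output_dir, "comparison_mb.csv"))
  suppressWarnings(run_pipeline(cfg, mb_only = TRUE))
  expect_identical(readLines(file.path(cfg$output_dir, "links_mb_rest.csv")), links1)
  expect_identical(readLines(file.path(cfg$output_dir, "comparison_mb.csv")), cmp1)
})

test_that("cohorts round-trip through the CSV/JSON interchange format", {
  co <- generate_cohort(default_rest_config(), default_hut_config(), 2L,
                        master_seed = 7L)
  dir <- file.path(tempdir(), "ctenet-cohort")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_cohort(dir)
  expect_equal(back[[1]]$rest$values, co[[1]]$rest$values, tolerance = 1e-12)
  expect_equal(back[[2]]$hut$condition, "HUT")
})
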