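make_series <- function(v, ...) {
  beat_series(v, node_labels = paste0("X", seq_len(ncol(v))), ...)
}

test_that("high-pass removes DC and keeps the top of the band", {
  const <- make_series(matrix(3.7, 200, 2))
  out <- highpass_detrend(const)
  expect_lt(max(abs(out$values)), 1e-9)

  # passband identity holds away from the filter transient zone at the edges
  alt <- make_series(matrix(rep(c(1, -1), 300), ncol = 1))
  out <- highpass_detrend(alt)
  core <- 101:500
  expect_gt(cor(out$values[core, 1], alt$values[core, 1]), 0.99)
})

test_that("slow sinusoids are attenuated per the designed magnitude response", {
  n <- 4096L
  f0 <- 0.005
  x <- sin(2 * pi * f0 * seq_len(n))
  s <- make_series(matrix(x, ncol = 1))
  out <- highpass_detrend(s)$values[, 1]

  # oracle: evaluate the order-4 Butterworth high-pass transfer function at f0;
  # the forward-backward pass squares the magnitude
  filt <- signal::butter(4, 2 * 0.0156, type = "high")
  z <- exp(-1i * 2 * pi * f0)
  H <- sum(filt$b * z^(seq_along(filt$b) - 1)) /
    sum(filt$a * z^(seq_along(filt$a) - 1))
  gain2 <- Mod(H)^2
  # compare RMS over the central window (away from edge transients, whose
  # extent is set by the filter's ~550-beat impulse response)
  core <- 601:(n - 600)
  expect_lt(sqrt(mean(out[core]^2)), 1.1 * gain2 * sqrt(mean(x[core]^2)) + 1e-6)
})

test_that("filtering passband-limited content is idempotent", {
  n <- 4096L
  t <- seq_len(n)
  x <- sin(2 * pi * 0.11 * t) + 0.5 * sin(2 * pi * 0.27 * t + 1) +
    0.25 * sin(2 * pi * 0.43 * t + 2)
  s <- make_series(matrix(x, ncol = 1))
  once <- highpass_detrend(s)
  twice <- highpass_detrend(once)
  core <- 601:(n - 600)
  # the final de-mean is taken over the full series (edge transients included),
  # so align the core windows on their own means before comparing samples
  a <- once$values[core, 1] - mean(once$values[core, 1])
  b <- twice$values[core, 1] - mean(twice$values[core, 1])
  expect_lt(max(abs(b - a)), 1e-6 * sd(once$values[, 1]))
})

test_that("detrending commutes with column permutation", {
  set.seed(3)
  s <- make_series(matrix(rnorm(300 * 3), ncol = 3))
  perm <- c(3, 1, 2)
  a <- highpass_detrend(s)$values[, perm]
  s2 <- s
  s2$values <- s$values[, perm]
  s2$node_labels <- s$node_labels[perm]
  colnames(s2$values) <- s2$node_labels
  b <- highpass_detrend(s2)$values
  expect_equal(unname(a), unname(b), tolerance = 1e-12)
})

test_that("cutoffs at or above Nyquist are rejected", {
  s <- make_series(matrix(rnorm(100), ncol = 1), mean_beat_duration_s = 40)
  expect_error(highpass_detrend(s), "Nyquist")
})

test_that("standardize centers and scales columns", {
  set.seed(4)
  s <- make_series(matrix(rnorm(200 * 3, mean = 5, sd = 3), ncol = 3))
  zm <- standardize(s, "zero_mean")
  expect_lt(max(abs(colMeans(zm$values))), 1e-12)
  uv <- standardize(s, "unit_variance")
  expect_lt(max(abs(colMeans(uv$values))), 1e-12)
  expect_lt(max(abs(apply(uv$values, 2, sd) - 1)), 1e-12)

  s$values[, 2] <- 1.5
  expect_error(standardize(s, "unit_variance"), "X2")
})

test_that("time-domain markers are the per-node mean and sample SD", {
  v <- cbind(A = c(1, 2, 3, 4), B = rep(7, 4))
  v <- v[rep(1:4, 20), ]  # meet the minimum length with the same values
  s <- make_series(v)
  s$node_labels <- c("A", "B"); colnames(s$values) <- c("A", "B")
  mk <- time_domain_markers(s)
  expect_equal(mk$mu, c(2.5, 7))
  # hand formula: sqrt(sum((x - mu)^2) / (n - 1))
  xa <- s$values[, "A"]
  expect_equal(mk$sigma[1], sqrt(sum((xa - 2.5)^2) / (length(xa) - 1)))
  expect_equal(mk$sigma[2], 0)
  expect_equal(mk$node, c("A", "B"))
  # the classic 4-point example, against the same formula
  expect_equal(sqrt(sum((c(1, 2, 3, 4) - 2.5)^2) / 3), 1.29099, tolerance = 1e-5)
})
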