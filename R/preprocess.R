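#' Zero-phase high-pass detrending
#'
#' Removes slow trends from each node series with an order-4 Butterworth
#' high-pass applied forward and backward (zero phase), then removes the
#' residual mean. The cutoff is given in Hz and converted to cycles/beat via
#' the series' mean beat duration (normalized cutoff = `cutoff_hz` x mean beat
#' duration), the only dimensionally consistent mapping for beat-indexed data
#' without resampling.
#'
#' Edge effects are controlled by odd-reflection padding at both ends before
#' each pass, combined with steady-state initial filter conditions; the pad
#' length is set to the filter's transient length (the number of beats over
#' which the slowest pole decays to 1e-9, capped at N-1), since a narrow
#' high-pass rings far longer than a few filter orders.
#'
#' @param series a [beat_series()].
#' @param cutoff_hz high-pass cutoff in Hz (default 0.0156).
#' @return A [beat_series()] of the same shape, filtered and de-meaned.
#' @export
highpass_detrend <- function(series, cutoff_hz = 0.0156) {
  stopifnot(inherits(series, "beat_series"))
  fc <- cutoff_hz * series$mean_beat_duration_s   # cycles/beat
  if (fc >= 0.5) stop(sprintf("normalized cutoff %.3f cycles/beat is above Nyquist", fc))
  if (fc <= 0) stop("cutoff must be positive")
  ord <- 4L
  filt <- signal::butter(ord, 2 * fc, type = "high")
  # reflection padding must cover the filter's transient: length at which the
  # slowest pole has decayed to 1e-9, capped at N-1
  pole <- max(Mod(polyroot(rev(filt$a))))
  pad <- min(nrow(series$values) - 1L, max(3L * ord, ceiling(log(1e-9) / log(pole))))
  out <- apply(series$values, 2L, zero_phase_filter, filt = filt, pad = pad)
  out <- sweep(out, 2L, colMeans(out), `-`)
  series$values <- out
  series
}

# Steady-state initial filter state for a unit-step input (transposed direct
# form II), so edge transients do not leak into the filtered window.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a))) / a[1L]
  b <- c(b, rep(0, n - length(b)))
  if (n == 1L) return(numeric(0L))
  comp <- rbind(-a[-1L], cbind(diag(n - 2L), rep(0, n - 2L)))
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n - 1L) - t(comp), B)
}

# Single IIR pass in transposed direct form II with explicit initial state.
iir_pass <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a))) / a[1L]
  b <- c(b, rep(0, n - length(b)))
  z <- c(zi, 0)
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    yi <- b[1L] * x[i] + z[1L]
    for (j in seq_len(n - 1L)) {
      z[j] <- b[j + 1L] * x[i] + z[j + 1L] - a[j + 1L] * yi
    }
    y[i] <- yi
  }
  y
}

# Forward-backward IIR pass with odd (point-symmetric) reflection padding and
# steady-state initial conditions at both ends.
zero_phase_filter <- function(x, filt, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  ext <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  zi <- lfilter_zi(filt$b, filt$a)
  y <- iir_pass(filt$b, filt$a, ext, zi * ext[1L])
  y <- rev(y)
  y <- rev(iir_pass(filt$b, filt$a, y, zi * y[1L]))
  y[pad + seq_len(n)]
}

#' Column standardization
#'
#' @param series a [beat_series()].
#' @param mode `"zero_mean"` subtracts column means; `"unit_variance"`
#'   additionally scales columns to sample SD 1 (required before model-free
#'   estimation).
#' @return A [beat_series()] with standardized columns.
#' @export
standardize <- function(series, mode = c("zero_mean", "unit_variance")) {
  stopifnot(inherits(series, "beat_series"))
  mode <- match.arg(mode)
  v <- sweep(series$values, 2L, colMeans(series$values), `-`)
  if (mode == "unit_variance") {
    sds <- apply(v, 2L, sd)
    if (any(sds == 0)) {
      stop("constant column(s) cannot be scaled to unit variance: ",
           paste(series$node_labels[sds == 0], collapse = ", "))
    }
    v <- sweep(v, 2L, sds, `/`)
  }
  series$values <- v
  series
}

#' Time-domain markers
#'
#' Per-node mean and sample standard deviation (denominator N-1) of the raw
#' (unfiltered) series — the classical markers compared between conditions.
#'
#' @param series a [beat_series()].
#' @return data.frame with columns `subject`, `condition`, `node`, `mu`, `sigma`.
#' @export
time_domain_markers <- function(series) {
  stopifnot(inherits(series, "beat_series"))
  data.frame(
    subject = series$subject_id,
    condition = series$condition,
    node = series$node_labels,
    mu = colMeans(series$values),
    sigma = apply(series$values, 2L, sd),
    row.names = NULL
  )
}
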