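# Shared fixtures, all generated in code. Cached so expensive simulations are
# reused across test files within one run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# one detrended REST subject
rest_subject <- function(i = 1L) {
  cached(paste0("rest", i), {
    highpass_detrend(generate_subject(default_rest_config(), seed = 1000L + i,
                                      subject_id = sprintf("S%02d", i)))
  })
}

# four mutually independent AR(2) nodes, the null system used for calibration
null_config <- function(n_samples = 300L) {
  sim_config(self_dynamics = list(R = c(0.5, -0.2), H = c(0.5, -0.2),
                                  M = c(0.5, -0.2), C = c(0.5, -0.2)),
             n_samples = n_samples)
}

# a two-node DAG with no zero-lag edges, for bivariate checks
dag2 <- function(labels = c("X1", "X2")) {
  zero_lag_dag(labels, edges = matrix(character(0), ncol = 2))
}

# independent plain-R KSG mutual information (max norm, strict counts),
# the dual-route oracle for the C++ kernel
ksg_mi_r <- function(x, y, k = 10L) {
  n <- length(x)
  psi <- digamma
  acc <- 0
  for (i in seq_len(n)) {
    dx <- abs(x - x[i]); dy <- abs(y - y[i])
    dj <- pmax(dx, dy); dj[i] <- Inf
    eps <- sort(dj, partial = k)[k]
    nx <- sum(dx < eps) - 1L
    ny <- sum(dy < eps) - 1L
    acc <- acc + psi(n) - psi(nx + 1L) - psi(ny + 1L)
  }
  psi(k) + acc / n
}

# seeded evaluation that restores the caller RNG state
with_seed_test <- function(seed, expr) {
  old <- .Random.seed
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}
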