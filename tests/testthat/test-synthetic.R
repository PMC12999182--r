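test_that("uncoupled unit-noise nodes are mutually independent", {
  cfg <- sim_config(n_samples = 300L)   # no couplings, no self dynamics
  s <- generate_subject(cfg, seed = 1L)
  v <- s$values
  n <- nrow(v)
  for (a in 1:4) for (b in 1:4) {
    if (a == b) next
    for (k in 0:5) {
      r <- cor(v[1:(n - k), a], v[(1 + k):n, b])
      expect_lt(abs(r), 0.15)
    }
  }
})

test_that("sample autocovariances match the Yule-Walker solution", {
  cfg <- default_rest_config(n_samples = 1e5L)
  s <- generate_subject(cfg, seed = 21L)

  # independent oracle: build the reduced-form companion matrix straight from
  # the coupling table and solve the discrete Lyapunov equation
  nodes <- cfg$nodes; m <- 4L; p <- 2L
  A <- lapply(1:3, function(i) matrix(0, m, m, dimnames = list(nodes, nodes)))
  for (nd in names(cfg$self_dynamics)) {
    ar <- cfg$self_dynamics[[nd]]
    for (k in seq_along(ar)) A[[k + 1]][nd, nd] <- ar[k]
  }
  lc <- cfg$linear_coupling
  for (r in seq_len(nrow(lc))) {
    A[[lc$lag[r] + 1]][lc$target[r], lc$source[r]] <-
      A[[lc$lag[r] + 1]][lc$target[r], lc$source[r]] + lc$coef[r]
  }
  B0 <- solve(diag(m) - A[[1]])
  Fc <- rbind(cbind(B0 %*% A[[2]], B0 %*% A[[3]]),
              cbind(diag(m), matrix(0, m, m)))
  Q <- matrix(0, 2 * m, 2 * m)
  Q[1:m, 1:m] <- B0 %*% diag(cfg$noise_sd^2) %*% t(B0)
  S <- matrix(solve(diag((2 * m)^2) - kronecker(Fc, Fc), as.vector(Q)), 2 * m)
  gamma0 <- S[1:m, 1:m]           # lag-0 covariance
  gamma1 <- (Fc %*% S)[1:m, 1:m]  # lag-1 covariance E[X_n X_{n-1}']

  v <- s$values
  n <- nrow(v)
  vc <- sweep(v, 2, colMeans(v))
  emp0 <- crossprod(vc) / n
  emp1 <- crossprod(vc[2:n, ], vc[1:(n - 1), ]) / n
  expect_lt(max(abs(emp0 - gamma0)), 0.02)
  expect_lt(max(abs(emp1 - gamma1)), 0.02)
})

test_that("defaults produce 300-beat series and deterministic cohorts", {
  s <- generate_subject(default_rest_config(), seed = 5L)
  expect_equal(nrow(s$values), 300L)
  expect_equal(s$node_labels, c("R", "H", "M", "C"))

  co1 <- generate_cohort(default_rest_config(), default_hut_config(), 3L,
                         master_seed = 42L)
  co2 <- generate_cohort(default_rest_config(), default_hut_config(), 3L,
                         master_seed = 42L)
  expect_identical(co1[[2]]$rest$values, co2[[2]]$rest$values)
  expect_identical(co1[[3]]$hut$values, co2[[3]]$hut$values)

  # seed isolation: subject data unchanged when the cohort grows
  co3 <- generate_cohort(default_rest_config(), default_hut_config(), 5L,
                         master_seed = 42L)
  expect_identical(co1[[2]]$rest$values, co3[[2]]$rest$values)
})

test_that("invalid configurations and cohorts are rejected", {
  expect_error(generate_cohort(default_rest_config(), default_hut_config(), 1L),
               "n_subjects")
  # mismatched topology
  rest <- default_rest_config()
  lc <- rest$linear_coupling
  lc <- lc[-1, ]
  hut_bad <- sim_config(lc, self_dynamics = rest$self_dynamics)
  expect_error(generate_cohort(rest, hut_bad, 3L), "topolog")
  # zero-lag edge outside the DAG
  expect_error(
    sim_config(data.frame(source = "M", target = "R", lag = 0L, coef = 0.2)),
    "zero-lag"
  )
  # unstable system
  expect_error(
    sim_config(self_dynamics = list(H = 1.05)),
    "unstable.*spectral radius"
  )
})

test_that("ground truth adjacency mirrors the coupling lists", {
  expect_false(any(ground_truth(sim_config())$adjacency))

  cfg <- default_rest_config()
  gt <- ground_truth(cfg)
  # independent scan of the coupling table
  expected <- matrix(FALSE, 4, 4, dimnames = dimnames(gt$adjacency))
  lc <- cfg$linear_coupling
  for (r in seq_len(nrow(lc))) expected[lc$source[r], lc$target[r]] <- TRUE
  expect_identical(gt$adjacency, expected)
  expect_false(any(diag(gt$adjacency)))

  # single added link flips exactly one entry
  lc2 <- rbind(lc, data.frame(source = "H", target = "R", lag = 1L, coef = 0.3))
  gt2 <- ground_truth(sim_config(lc2, self_dynamics = cfg$self_dynamics))
  expect_equal(sum(gt2$adjacency != gt$adjacency), 1L)
  expect_true(gt2$adjacency["H", "R"])
})

test_that("any DAG-consistent evaluation order yields the identical series", {
  cfg <- default_rest_config(n_samples = 120L)
  a <- generate_subject(cfg, seed = 9L)
  # R->H->M->C default order; R,H,M,C with H and M swapped is NOT consistent,
  # but the DAG has all forward edges so the only valid order is the node
  # order itself; drop one edge to open alternatives
  dag <- zero_lag_dag(edges = cbind(from = c("R", "R", "H"),
                                    to = c("H", "M", "M")))
  lc <- default_rest_config()$linear_coupling
  lc <- lc[!(lc$lag == 0 & lc$target == "C"), ]
  cfg2 <- sim_config(lc, self_dynamics = cfg$self_dynamics,
                     n_samples = 120L, dag = dag)
  b1 <- generate_subject(cfg2, seed = 9L)
  b2 <- generate_subject(cfg2, seed = 9L, topo_order = c("R", "H", "C", "M"))
  expect_identical(b1$values, b2$values)
  expect_error(generate_subject(cfg2, seed = 9L, topo_order = c("M", "R", "H", "C")),
               "not DAG-consistent")
})

test_that("accepted configurations are stationary", {
  for (cfg in list(default_rest_config(1e4L), default_hut_config(1e4L))) {
    v <- generate_subject(cfg, seed = 31L)$values
    n <- nrow(v)
    h1 <- v[1:(n / 2), ]; h2 <- v[(n / 2 + 1):n, ]
    for (j in 1:4) {
      se <- sqrt(var(h1[, j]) / nrow(h1) + var(h2[, j]) / nrow(h2))
      expect_lt(abs(mean(h1[, j]) - mean(h2[, j])), 5 * se)
    }
  }
})
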