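test_that("edge rule: at least three streamlines, weight equals mean FA", {
  counts <- matrix(0, 3, 3); fa <- matrix(0, 3, 3)
  counts[1, 2] <- counts[2, 1] <- 2; fa[1, 2] <- fa[2, 1] <- 0.5
  counts[1, 3] <- counts[3, 1] <- 3; fa[1, 3] <- fa[3, 1] <- 0.4
  counts[2, 3] <- counts[3, 2] <- 10; fa[2, 3] <- fa[3, 2] <- 0.7
  cn <- build_connectome(counts, fa)
  expect_equal(cn$weights[1, 2], 0)    # 2 streamlines: filtered
  expect_equal(cn$weights[1, 3], 0.4)  # exactly 3: kept
  expect_equal(cn$weights[2, 3], 0.7)
  expect_equal(build_connectome(matrix(0, 4, 4),
                                matrix(0.5, 4, 4) - diag(0.5, 4))$weights,
               matrix(0, 4, 4))
  # idempotence: re-applying the mask with the connectome's own support
  cn2 <- build_connectome((cn$weights > 0) * 3, cn$weights)
  expect_equal(cn2$weights, cn$weights)
})

test_that("malformed inputs to build_connectome are rejected", {
  expect_error(build_connectome(matrix(0, 3, 3), matrix(0, 4, 4)), "shape")
  bad <- matrix(0, 3, 3); bad[1, 2] <- 5
  expect_error(build_connectome(bad, matrix(0, 3, 3)), "symmetric")
})

test_that("sparsity is the fraction of connected node pairs", {
  expect_equal(sparsity(complete_unit(8)), 1.0)
  expect_equal(sparsity(connectome(matrix(0, 6, 6))), 0.0)
  w <- matrix(0, 90, 90)
  p <- which(upper.tri(w), arr.ind = TRUE)[1:801, ]
  w[p] <- 0.5; w <- w + t(w)
  expect_equal(sparsity(connectome(w)), 801 / 4005)
  expect_equal(801 / 4005, 0.2)
})

test_that("threshold_to_sparsity keeps the top-k edges with weights intact", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.9; w[1, 3] <- 0.5; w[1, 4] <- 0.4; w[2, 3] <- 0.1
  w <- w + t(w)
  cn <- connectome(w)
  thr <- threshold_to_sparsity(cn, 2 / 6)
  expect_equal(thr$weights[1, 2], 0.9)
  expect_equal(thr$weights[1, 3], 0.5)
  expect_equal(sum(thr$weights > 0) / 2, 2)
  # target equal to current sparsity leaves the network unchanged
  expect_equal(threshold_to_sparsity(cn, sparsity(cn))$weights, w)
  expect_error(threshold_to_sparsity(cn, 0.9), "sparsity")
})

test_that("thresholded edge sets are nested and never gain weight", {
  set.seed(42)
  for (rep in 1:5) {
    w <- random_weighted_graph(15, density = 0.6)
    cn <- connectome(w)
    lo <- threshold_to_sparsity(cn, 0.10)
    hi <- threshold_to_sparsity(cn, 0.30)
    expect_true(all(lo$weights[lo$weights > 0] ==
                    w[lo$weights > 0]))
    expect_true(all(hi$weights[lo$weights > 0] > 0))
    expect_true(all(lo$weights <= cn$weights))
  }
})

test_that("tied weights are broken deterministically and reproducibly", {
  w <- matrix(0, 5, 5)
  w[upper.tri(w)] <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.2, 0.2, 0.2, 0.2)
  w <- w + t(w)
  cn <- connectome(w)
  a <- threshold_to_sparsity(cn, 0.3)
  b <- threshold_to_sparsity(cn, 0.3)
  expect_identical(a$weights, b$weights)
  expect_equal(sum(a$weights > 0) / 2, 3)
})

test_that("threshold_series covers the inclusive grid", {
  rec <- generate_cohort(small_params(seed = 2, n_nodes = 30))[[1]]
  cn <- build_connectome(rec$streamline_counts, rec$mean_fa)
  s10 <- threshold_series(cn)
  expect_length(s10$networks, 10)
  expect_equal(s10$sparsities, seq(0.05, 0.14, 0.01))
  s16 <- threshold_series(cn, 0.05, 0.20, 0.01)
  expect_length(s16$networks, 16)
  s1 <- threshold_series(cn, 0.10, 0.10, 0.01)
  expect_length(s1$networks, 1)
  expect_error(threshold_series(cn, 0.2, 0.1), "s_min")
  # realized sparsity within one edge slot of each target
  np <- 30 * 29 / 2
  for (t in seq_along(s10$sparsities)) {
    k <- sum(s10$networks[[t]]$weights > 0) / 2
    expect_lte(abs(k - s10$sparsities[t] * np), 1)
  }
})

make_covariate_cohort <- function(seed, n = 12, nodes = 10, age_slope = 0) {
  set.seed(seed)
  age <- sample(55:80, n, replace = TRUE)
  covs <- data.frame(age = age,
                     sex = rep_len(c(0, 1), n),
                     education = sample(5:16, n, replace = TRUE))
  base <- random_weighted_graph(nodes, density = 0.7)
  nets <- lapply(seq_len(n), function(k) {
    w <- base
    nz <- w > 0
    w[nz] <- pmax(w[nz] + age_slope * (age[k] - 65) +
                    stats::rnorm(sum(nz), 0, 0.01), 0.001)
    connectome((w + t(w)) / 2)
  })
  list(networks = nets, covariates = covs)
}

test_that("deconfounding leaves covariate-free cohorts unchanged", {
  cc <- make_covariate_cohort(1, n = 8)
  same <- lapply(seq_len(8), function(k) cc$networks[[1]])
  out <- deconfound_edges(same, cc$covariates[1:8, ])
  for (k in c(1, 5)) expect_equal(out[[k]]$weights, same[[k]]$weights,
                                  tolerance = 1e-10)
})

test_that("a pure linear age effect collapses to the grand mean", {
  n <- 10
  age <- seq(55, 82, length.out = n)
  covs <- data.frame(age = age, sex = rep_len(c(0, 1), n),
                     education = rep(10, n) + rep_len(c(0, 1, 2), n))
  w0 <- matrix(0, 4, 4); w0[1, 2] <- w0[2, 1] <- 1
  nets <- lapply(seq_len(n), function(k) {
    w <- w0 * (0.3 + 0.01 * age[k])
    connectome(w)
  })
  out <- deconfound_edges(nets, covs)
  gm <- mean(vapply(nets, function(cn) cn$weights[1, 2], numeric(1)))
  for (k in seq_len(n))
    expect_equal(out[[k]]$weights[1, 2], gm, tolerance = 1e-10)
})

test_that("deconfounding preserves the across-subject grand mean and zeros", {
  cc <- make_covariate_cohort(7, n = 14, age_slope = 0.004)
  out <- deconfound_edges(cc$networks, cc$covariates)
  y_in <- sapply(cc$networks, function(cn) cn$weights[1, 2])
  y_out <- sapply(out, function(cn) cn$weights[1, 2])
  expect_equal(mean(y_out), mean(y_in), tolerance = 1e-10)
  # an edge absent in a subject stays absent
  nets <- cc$networks
  nets[[3]]$weights[1, 2] <- nets[[3]]$weights[2, 1] <- 0
  out2 <- deconfound_edges(nets, cc$covariates)
  expect_equal(out2[[3]]$weights[1, 2], 0)
})

test_that("rank-deficient covariates are reported by name", {
  cc <- make_covariate_cohort(2, n = 8)
  covs <- cc$covariates
  covs$education <- 2 * covs$age
  expect_error(deconfound_edges(cc$networks, covs), "collinear")
  expect_error(deconfound_edges(cc$networks[1:3], covs[1:3, ]), "4 subjects")
})

test_that("an injected age effect is removed from edge weights", {
  mean_abs_r <- replicate(60, NA_real_)
  for (s in 1:60) {
    cc <- make_covariate_cohort(100 + s, n = 16, nodes = 8,
                                age_slope = 0.008)
    out <- deconfound_edges(cc$networks, cc$covariates)
    w <- sapply(out, function(cn) ut_vec_test(cn$weights))
    keep <- apply(w, 1, function(x) all(x > 0))
    r <- apply(w[keep, , drop = FALSE], 1,
               function(x) stats::cor(x, cc$covariates$age))
    mean_abs_r[s] <- mean(abs(r))
  }
  expect_lt(mean(mean_abs_r), 0.05)
})
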