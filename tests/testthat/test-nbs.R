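stack_from <- function(w_list) lapply(w_list, connectome)

test_that("edgewise t matches hand/oracle computation and sign conventions", {
  # single informative edge across 4+4 subjects
  mk <- function(v) {
    w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- v; connectome(w)
  }
  ga <- lapply(c(0.5, 0.5, 0.6, 0.6), mk)
  gb <- lapply(c(0.3, 0.3, 0.4, 0.4), mk)
  res <- edgewise_t(ga, gb)
  ref <- stats::t.test(c(0.5, 0.5, 0.6, 0.6), c(0.3, 0.3, 0.4, 0.4),
                       var.equal = TRUE, alternative = "greater")
  expect_equal(res$t_matrix[1, 2], unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_matrix[1, 2], ref$p.value, tolerance = 1e-10)
  expect_equal(res$t_matrix, t(res$t_matrix))
  # swapping groups negates t
  res2 <- edgewise_t(gb, ga)
  expect_equal(res2$t_matrix[1, 2], -res$t_matrix[1, 2])
  # identical stacks: t = 0, one-tailed p = 0.5
  res3 <- edgewise_t(ga, ga)
  expect_equal(res3$t_matrix[1, 2], 0)
  expect_equal(res3$p_matrix[1, 2], 0.5)
  # degenerate variance: p = 1
  gc <- lapply(c(0.5, 0.5, 0.5, 0.5), mk)
  res4 <- edgewise_t(gc, gc)
  expect_equal(res4$p_matrix[1, 2], 1)
  # untested (all-zero) edges: p = 1
  expect_equal(res$p_matrix[1, 3], 1)
})

test_that("suprathreshold components are traced correctly", {
  n <- 5
  p <- matrix(1, n, n)
  # suprathreshold edges AB, BC, DE -> components of sizes 2 and 1
  p[1, 2] <- p[2, 1] <- 0.001
  p[2, 3] <- p[3, 2] <- 0.002
  p[4, 5] <- p[5, 4] <- 0.003
  comps <- suprathreshold_components(p, alpha_primary = 0.005)
  expect_length(comps, 2)
  expect_equal(vapply(comps, `[[`, integer(1), "size"), c(2L, 1L))
  expect_equal(comps[[1]]$nodes, c(1L, 2L, 3L))
  expect_length(suprathreshold_components(matrix(1, 4, 4), 0.005), 0)
  # spanning chain of k suprathreshold edges forms one component of size k
  k <- 7
  pc <- matrix(1, k + 1, k + 1)
  for (i in 1:k) pc[i, i + 1] <- pc[i + 1, i] <- 1e-4
  ch <- suprathreshold_components(pc, 0.005)
  expect_length(ch, 1)
  expect_equal(ch[[1]]$size, k)
})

test_that("component extraction agrees with a flood-fill oracle", {
  set.seed(14)
  for (rep in 1:30) {
    n <- sample(5:10, 1)
    p <- matrix(1, n, n)
    up <- which(upper.tri(p))
    hit <- sample(up, size = stats::rbinom(1, length(up), 0.2))
    p[hit] <- stats::runif(length(hit), 0, 0.004)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
    comps <- suprathreshold_components(p, 0.005)
    orac <- oracle_components(p, 0.005)
    expect_equal(length(comps), length(orac))
    sizes <- sort(vapply(comps, `[[`, integer(1), "size"))
    expect_equal(sizes, sort(vapply(orac, function(x) as.integer(x$size),
                                    integer(1))))
    nodesets <- lapply(comps, `[[`, "nodes")
    for (oc in orac)
      expect_true(any(vapply(nodesets, function(ns)
        identical(ns, oc$nodes), logical(1))))
  }
})

test_that("hub rule: degree above mean plus one SD on significant edges", {
  star <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L))
  expect_equal(identify_hubs(star), 1L)      # degrees 3,1,1,1
  ring <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  expect_equal(identify_hubs(ring), integer(0))  # all degrees equal
  expect_equal(identify_hubs(matrix(integer(0), 0, 2)), integer(0))
  # nodes absent from the edge set are ignored entirely
  expect_equal(identify_hubs(rbind(star, c(7L, 8L))), 1L)
})

test_that("NBS recovers a planted component and orders corrected p by size", {
  par <- cohort_params(n_nodes = 24, planted_edges = small_planted(),
                       planted_attenuation = 0.45, global_fa_shift = 0,
                       seed = 31)
  bc <- build_cohort_networks(generate_cohort(par))
  res <- nbs_test(bc$networks, bc$metadata$group, n_perm = 500, seed = 8)
  expect_gt(length(res$components), 0)
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  top <- res$components[[1]]$edges
  expect_gte(sum(key(small_planted()) %in% key(top)), 3)
  expect_lt(res$component_p_corrected[1], 0.05)
  # components sorted by size; corrected p non-decreasing down the list
  sizes <- vapply(res$components, `[[`, integer(1), "size")
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(diff(res$component_p_corrected) >= 0))
  expect_length(res$null_max_sizes, 500)
  expect_identical(res$null_max_sizes,
                   nbs_test(bc$networks, bc$metadata$group, n_perm = 500,
                            seed = 8)$null_max_sizes)
})

test_that("an impossible primary threshold yields no components", {
  par <- small_params(seed = 32, n_nodes = 12)
  bc <- build_cohort_networks(generate_cohort(par))
  res <- nbs_test(bc$networks, bc$metadata$group, alpha_primary = 1e-12,
                  n_perm = 50, seed = 1)
  expect_length(res$components, 0)
  expect_equal(res$sig_edge_count, 0)
  expect_equal(identify_hubs(res$sig_edges), integer(0))
})

test_that("NBS corrected p matches exhaustive 3+3 enumeration", {
  # tiny cohort with a genuine effect on a connected pair of edges
  set.seed(55)
  n <- 6
  mk <- function(bump) {
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- 0.5 + stats::rnorm(n * (n - 1) / 2, 0, 0.05)
    w <- (w + t(w)) / 2; diag(w) <- 0
    w[1, 2] <- w[2, 1] <- w[1, 2] - bump
    w[2, 3] <- w[3, 2] <- w[2, 3] - bump
    w <- pmax(w, 0.01); diag(w) <- 0
    connectome(w)
  }
  nets <- c(lapply(1:3, function(i) mk(0)), lapply(1:3, function(i) mk(0.3)))
  groups <- rep(c("control", "patient"), each = 3)
  alpha <- 0.05
  res <- nbs_test(nets, groups, alpha_primary = alpha, n_perm = 4000,
                  seed = 2, alpha_report = 0.5)
  # oracle: full C(6,3) relabelling of the max component size
  w_stack <- t(vapply(nets, function(cn) cn$weights[upper.tri(cn$weights)],
                      numeric(n * (n - 1) / 2)))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  max_size <- function(idx_a) {
    idx_b <- setdiff(1:6, idx_a)
    pv <- apply(w_stack, 2, function(col) {
      if (stats::sd(col) == 0) return(1)
      suppressWarnings(stats::t.test(col[idx_a], col[idx_b],
                                     var.equal = TRUE,
                                     alternative = "greater")$p.value)
    })
    pm <- matrix(1, n, n)
    pm[pairs] <- pv; pm[pairs[, c(2, 1)]] <- pv
    oc <- oracle_components(pm, alpha)
    if (length(oc) == 0) 0 else max(vapply(oc, function(x) x$size, numeric(1)))
  }
  observed <- max_size(1:3)
  combs <- utils::combn(6, 3)
  null_sizes <- apply(combs, 2, max_size)
  p_ex <- mean(null_sizes >= observed)
  p_mc <- res$component_p_corrected[1]
  expect_lt(abs(p_mc - p_ex), 3 * sqrt(p_ex * (1 - p_ex) / 4000) + 2e-3)
})

test_that("connectogram link export classifies hemispheres and orders rows", {
  node_table <- load_node_labels()
  tmat <- matrix(0, 90, 90)
  edges <- rbind(c(4L, 39L),   # L-L
                 c(49L, 84L),  # R-R
                 c(4L, 49L))   # L-R
  tmat[edges] <- c(3.2, 2.8, 4.1); tmat <- tmat + t(tmat)
  res <- structure(list(sig_edges = edges, t_matrix = tmat),
                   class = "nbs_result")
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- export_connectogram_links(res, node_table, path)
  expect_equal(out$connection_type, c("left_intra", "inter", "right_intra"))
  expect_equal(out$node_i[1], "MFG.L")
  expect_equal(out$lobe_j[1], "subcortical")
  expect_equal(out$t_value, c(3.2, 4.1, 2.8))
  back <- utils::read.delim(path)
  expect_equal(nrow(back), 3)
  # empty result: header-only file
  res0 <- structure(list(sig_edges = matrix(integer(0), 0, 2),
                         t_matrix = tmat), class = "nbs_result")
  p0 <- withr::local_tempfile(fileext = ".tsv")
  export_connectogram_links(res0, node_table, p0)
  expect_equal(length(readLines(p0)), 1)
  resbad <- structure(list(sig_edges = rbind(c(1L, 95L)), t_matrix = tmat),
                      class = "nbs_result")
  expect_error(export_connectogram_links(resbad, node_table, p0), "node")
})
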