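# shared small fixtures for the unit suites

# small-cohort parameters: same structure as the defaults, scaled down in
# node count for fast simulation studies
small_params <- function(seed, n_nodes = 20, planted = NULL, ...) {
  cohort_params(n_nodes = n_nodes,
                planted_edges = planted %||% matrix(integer(0), 0, 2),
                seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# connected 4-edge planted set on a 20-node parcellation
small_planted <- function() rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(2L, 5L))

toy_connectome <- function(w) connectome(w)

# 3-node path A-B-C with unit weights
unit_path3 <- function() {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  connectome(w)
}

complete_unit <- function(n) {
  w <- matrix(1, n, n); diag(w) <- 0
  connectome(w)
}

ut_vec_test <- function(m) m[upper.tri(m)]

build_cohort_networks <- function(records, deconfound = TRUE) {
  meta <- cohort_metadata(records)
  nets <- lapply(records, function(r)
    build_connectome(r$streamline_counts, r$mean_fa))
  if (deconfound) nets <- deconfound_edges(nets, meta)
  list(networks = nets, metadata = meta)
}
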