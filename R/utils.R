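# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Diagnostic logging, silent unless option sivconn.verbose is TRUE
#' @noRd
sivconn_log <- function(...) {
  if (isTRUE(getOption("sivconn.verbose", FALSE))) message(sprintf(...))
}

#' Upper-triangle pair index (i < j) for an n-node undirected graph
#' @noRd
ut_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  # column-major order of upper.tri: sorted by (j, i); reorder to (i, j) lexicographic
  ord <- order(idx[, 1L], idx[, 2L])
  cbind(i = idx[ord, 1L], j = idx[ord, 2L])
}

#' Extract the upper-triangle vector of a symmetric matrix in ut_pairs order
#' @noRd
ut_vec <- function(m) {
  p <- ut_pairs(nrow(m))
  m[cbind(p[, 1L], p[, 2L])]
}

#' Rebuild a symmetric zero-diagonal matrix from its ut_pairs vector
#' @noRd
ut_unvec <- function(v, n) {
  m <- matrix(0, n, n)
  p <- ut_pairs(n)
  m[cbind(p[, 1L], p[, 2L])] <- v
  m[cbind(p[, 2L], p[, 1L])] <- v
  m
}

#' Dense Floyd-Warshall on a matrix of edge lengths (Inf = absent), zero diagonal.
#' Used for small neighbourhood subgraphs where per-call graph construction
#' overhead would dominate.
#' @noRd
fw_dist <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- d[, k]
    cand <- outer(dk, d[k, ], `+`)
    lower <- cand < d
    if (any(lower)) d[lower] <- cand[lower]
  }
  d
}

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
}
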