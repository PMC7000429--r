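# Independent brute-force oracles used to validate the graph-metric and NBS
# implementations on small instances. These deliberately avoid the package's
# own code paths: exhaustive simple-path enumeration for distances, direct
# triangle enumeration for clustering, recursive flood fill for components,
# and full relabelling enumeration for permutation p-values.

# all simple paths: minimal total length with edge length 1/weight
oracle_distance <- function(w, from, to) {
  n <- nrow(w)
  best <- Inf
  recurse <- function(node, visited, len) {
    if (len >= best) return()
    if (node == to) { best <<- len; return() }
    for (nb in which(w[node, ] > 0)) {
      if (!visited[nb]) {
        visited[nb] <- TRUE
        recurse(nb, visited, len + 1 / w[node, nb])
        visited[nb] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n); visited[from] <- TRUE
  recurse(from, visited, 0)
  best
}

oracle_distance_matrix <- function(w) {
  n <- nrow(w)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- oracle_distance(w, i, j)
  d
}

oracle_lp <- function(w) {
  d <- oracle_distance_matrix(w)
  off <- d[row(d) != col(d)]
  if (!any(is.finite(off))) Inf else mean(off[is.finite(off)])
}

oracle_eg <- function(w) {
  n <- nrow(w)
  d <- oracle_distance_matrix(w)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  sum(inv) / (n * (n - 1))
}

oracle_nodal_eg <- function(w) {
  n <- nrow(w)
  d <- oracle_distance_matrix(w)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  rowSums(inv) / (n - 1)
}

# Onnela clustering by direct triangle enumeration
oracle_cp <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(0)
  wh <- w / mx
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      j <- nb[a]; l <- nb[b]
      s <- s + (wh[i, j] * wh[j, l] * wh[l, i])^(1 / 3)
    }
    ci[i] <- 2 * s / (k * (k - 1))
  }
  mean(ci)
}

oracle_nodal_eloc <- function(w) {
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_eg(w[nb, nb, drop = FALSE])
  }, numeric(1))
}

oracle_eloc_printed <- function(w) sum(oracle_nodal_eloc(w)) / (nrow(w) * (nrow(w) - 1))

# recursive flood fill over suprathreshold edges
oracle_components <- function(p_matrix, alpha) {
  n <- nrow(p_matrix)
  adj <- p_matrix < alpha
  diag(adj) <- FALSE
  nodes <- which(rowSums(adj) > 0)
  seen <- rep(FALSE, n)
  comps <- list()
  for (v in nodes) {
    if (seen[v]) next
    members <- c(); queue <- v; seen[v] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      members <- c(members, u)
      for (nb in which(adj[u, ])) if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
    }
    members <- sort(members)
    sub <- adj[members, members, drop = FALSE]
    comps[[length(comps) + 1]] <- list(nodes = members,
                                       size = sum(sub) / 2)
  }
  comps
}

# exhaustive permutation p-value (mean difference) for tiny groups
oracle_perm_p_exhaustive <- function(a, b, tail = "two") {
  pooled <- c(a, b)
  na <- length(a)
  obs <- mean(a) - mean(b)
  combs <- utils::combn(length(pooled), na)
  diffs <- apply(combs, 2, function(ix)
    mean(pooled[ix]) - mean(pooled[-ix]))
  eps <- 1e-12 * (1 + abs(obs))
  n_ext <- switch(tail,
    two = sum(abs(diffs) >= abs(obs) - eps),
    right = sum(diffs >= obs - eps),
    left = sum(diffs <= obs + eps))
  n_ext / ncol(combs)
}

# random weighted graph helper for oracle suites
random_weighted_graph <- function(n, density = 0.5) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < density) w[i, j] <- w[j, i] <- stats::runif(1, 0.1, 1)
  }
  w
}
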