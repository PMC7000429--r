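#' Weighted clustering coefficient (Onnela form)
#'
#' Per node i with degree k_i >= 2, C_i is the sum over neighbour pairs of
#' the geometric mean of the three normalised triangle weights
#' (w-hat = w / max(w) over the network), scaled by 2 / (k_i (k_i - 1));
#' nodes with fewer than two neighbours contribute 0. Returns the mean over
#' all nodes.
#'
#' @param c a `connectome` with >= 3 nodes.
#' @return scalar Cp; 0 (with a warning) on an edgeless network.
#' @export
clustering_coefficient <- function(c) {
  w <- c$weights
  n <- nrow(w)
  if (n < 3) stop("clustering coefficient needs >= 3 nodes", call. = FALSE)
  mx <- max(w)
  if (mx == 0) {
    warning("all-zero network: clustering coefficient is 0")
    return(0)
  }
  a <- (w / mx)^(1 / 3)
  tri2 <- diag(a %*% a %*% a)        # 2x the summed triangle intensity
  k <- rowSums(w > 0)
  ci <- numeric(n)
  ok <- k >= 2
  ci[ok] <- tri2[ok] / (k[ok] * (k[ok] - 1))
  mean(ci)
}

conn_graph <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Weighted shortest path length matrix
#'
#' Edge length is the reciprocal edge weight; L_ij is the minimal summed
#' length over paths (Dijkstra), +Inf for disconnected pairs, 0 on the
#' diagonal.
#'
#' @param c a `connectome`.
#' @return symmetric matrix of path lengths.
#' @export
shortest_path_lengths <- function(c) {
  w <- c$weights
  n <- nrow(w)
  if (n <= 48) {
    # dense Floyd-Warshall beats per-call graph construction at this size
    len <- matrix(Inf, n, n)
    nz <- w > 0
    len[nz] <- 1 / w[nz]
    diag(len) <- 0
    return(fw_dist(len))
  }
  g <- conn_graph(w)
  ew <- igraph::E(g)$weight
  d <- igraph::distances(g, weights = if (length(ew)) 1 / ew else numeric(0),
                         algorithm = "dijkstra")
  dimnames(d) <- NULL
  d
}

#' Characteristic path length
#'
#' Mean of L_ij over connected ordered pairs; disconnected pairs are
#' excluded (their count is reported via the verbose log). Returns +Inf
#' when no pair is connected.
#'
#' @param c a `connectome`.
#' @return scalar Lp.
#' @export
characteristic_path_length <- function(c) {
  d <- shortest_path_lengths(c)
  off <- d[row(d) != col(d)]
  fin <- is.finite(off)
  n_excl <- sum(!fin)
  if (n_excl > 0)
    sivconn_log("characteristic_path_length: excluded %d disconnected pairs",
                n_excl)
  if (!any(fin)) return(Inf)
  mean(off[fin])
}

#' Global efficiency
#'
#' Mean over all N(N-1) ordered pairs of 1/L_ij, with 1/Inf taken as 0.
#'
#' @param c a `connectome`.
#' @return scalar Eglob.
#' @export
global_efficiency <- function(c) {
  n <- nrow(c$weights)
  d <- shortest_path_lengths(c)
  inv <- 1 / d
  inv[!is.finite(d) | d == 0] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal global efficiency
#'
#' Per node i, the mean over the other N-1 nodes of 1/L_ij (harmonic
#' reach); isolated nodes score 0. The vector mean equals
#' [global_efficiency()].
#'
#' @param c a `connectome`.
#' @return numeric vector of length N.
#' @export
nodal_global_efficiency <- function(c) {
  n <- nrow(c$weights)
  d <- shortest_path_lengths(c)
  inv <- 1 / d
  inv[!is.finite(d) | d == 0] <- 0
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

# efficiency of the neighbourhood subgraph of node i (node i excluded),
# subgraph weights taken from the full network
neighbourhood_efficiency <- function(w, i) {
  nb <- which(w[i, ] > 0)
  k <- length(nb)
  if (k < 2) return(0)
  if (k == 2) return(w[nb[1], nb[2]])
  if (k == 3) {
    # closed form: each pair direct or relayed through the third neighbour
    w12 <- w[nb[1], nb[2]]; w13 <- w[nb[1], nb[3]]; w23 <- w[nb[2], nb[3]]
    l12 <- if (w12 > 0) 1 / w12 else Inf
    l13 <- if (w13 > 0) 1 / w13 else Inf
    l23 <- if (w23 > 0) 1 / w23 else Inf
    d12 <- min(l12, l13 + l23); d13 <- min(l13, l12 + l23)
    d23 <- min(l23, l12 + l13)
    inv <- c(if (is.finite(d12)) 1 / d12 else 0,
             if (is.finite(d13)) 1 / d13 else 0,
             if (is.finite(d23)) 1 / d23 else 0)
    return(2 * sum(inv) / (k * (k - 1)))
  }
  sub <- w[nb, nb, drop = FALSE]
  len <- 1 / sub
  len[sub == 0] <- Inf
  diag(len) <- 0
  d <- fw_dist(len)
  inv <- 1 / d
  inv[!is.finite(d) | d == 0] <- 0
  diag(inv) <- 0
  sum(inv) / (k * (k - 1))
}

#' Nodal local efficiency
#'
#' Per node i, the global efficiency of the subgraph induced by i's direct
#' neighbours (i itself excluded), with subgraph edge weights taken from the
#' full network; nodes with fewer than two neighbours score 0.
#'
#' @param c a `connectome`.
#' @return numeric vector of length N.
#' @export
nodal_local_efficiency <- function(c) {
  w <- c$weights
  vapply(seq_len(nrow(w)), function(i) neighbourhood_efficiency(w, i),
         numeric(1))
}

#' Local efficiency
#'
#' Summarises the nodal local efficiencies. The default `"printed"` mode
#' divides their sum by N(N-1); the `"mean"` mode divides by N (the
#' fault-tolerance convention of the wider literature). The two differ only
#' by the constant factor N-1.
#'
#' @param c a `connectome`.
#' @param mode `"printed"` or `"mean"`.
#' @return scalar Eloc.
#' @export
local_efficiency <- function(c, mode = c("printed", "mean")) {
  mode <- match.arg(mode)
  n <- nrow(c$weights)
  s <- sum(nodal_local_efficiency(c))
  if (mode == "printed") s / (n * (n - 1)) else s / n
}

#' Trapezoidal area under a metric curve
#'
#' @param values numeric vector (one value per grid point) or matrix with
#'   one row per node and one column per grid point.
#' @param sparsities the grid.
#' @return scalar, or per-node vector for matrix input; curves with fewer
#'   than two points return 0 with a warning.
#' @export
auc_trapz <- function(values, sparsities) {
  m <- length(sparsities)
  if (m < 2) {
    warning("degenerate curve (<2 grid points): AUC set to 0")
    return(if (is.matrix(values)) numeric(nrow(values)) else 0)
  }
  dx <- diff(sparsities)
  if (is.matrix(values)) {
    mids <- (values[, -1, drop = FALSE] + values[, -m, drop = FALSE]) / 2
    as.numeric(mids %*% dx)
  } else {
    sum(dx * (values[-1] + values[-m]) / 2)
  }
}

#' Metric curves over a threshold series
#'
#' Computes the four global metrics (Cp, Lp, Eglob, Eloc) and the two nodal
#' efficiency profiles at every sparsity level of the series, each with its
#' trapezoidal AUC.
#'
#' @param series a `threshold_series`.
#' @param eloc_mode normalisation mode for [local_efficiency()].
#' @param metrics which curves to compute (any of Cp, Lp, Eglob, Eloc,
#'   nodal_global, nodal_local); defaults to all six.
#' @return named list of `metric_curve` objects, each holding `metric_name`,
#'   `sparsities`, `values` (vector, or node x level matrix) and `auc`.
#' @export
metric_curves <- function(series, eloc_mode = "printed",
                          metrics = c("Cp", "Lp", "Eglob", "Eloc",
                                      "nodal_global", "nodal_local")) {
  if (!inherits(series, "threshold_series") || length(series$networks) == 0)
    stop("series must be a non-empty threshold_series", call. = FALSE)
  metrics <- match.arg(metrics, several.ok = TRUE)
  sp <- series$sparsities
  nets <- series$networks
  n <- nrow(nets[[1]]$weights)
  need_paths <- any(c("Lp", "Eglob", "nodal_global") %in% metrics)
  need_nloc <- any(c("Eloc", "nodal_local") %in% metrics)
  cp <- lp <- eg <- el <- numeric(length(nets))
  ng <- nl <- matrix(0, n, length(nets))
  for (t in seq_along(nets)) {
    cn <- nets[[t]]
    if (need_paths) {
      d <- shortest_path_lengths(cn)
      inv <- 1 / d
      inv[!is.finite(d) | d == 0] <- 0
      diag(inv) <- 0
      off <- d[row(d) != col(d)]
      fin <- is.finite(off)
      lp[t] <- if (any(fin)) mean(off[fin]) else Inf
      eg[t] <- sum(inv) / (n * (n - 1))
      ng[, t] <- rowSums(inv) / (n - 1)
    }
    if ("Cp" %in% metrics) cp[t] <- clustering_coefficient(cn)
    if (need_nloc) {
      nloc <- nodal_local_efficiency(cn)
      nl[, t] <- nloc
      el[t] <- if (eloc_mode == "printed") sum(nloc) / (n * (n - 1))
               else sum(nloc) / n
    }
  }
  curve <- function(name, values) {
    structure(list(metric_name = name, sparsities = sp, values = values,
                   auc = suppressWarnings(auc_trapz(values, sp))),
              class = "metric_curve")
  }
  all <- list(Cp = curve("Cp", cp), Lp = curve("Lp", lp),
              Eglob = curve("Eglob", eg), Eloc = curve("Eloc", el),
              nodal_global = curve("nodal_global", ng),
              nodal_local = curve("nodal_local", nl))
  all[metrics]
}

#' Per-subject global metric AUCs
#'
#' Runs [threshold_series()] and [metric_curves()] for each subject and
#' collects the four global AUCs.
#'
#' @param connectomes list of `connectome`s.
#' @param s_min,s_max,step sparsity grid.
#' @param eloc_mode normalisation mode for Eloc.
#' @param metrics which of the four global metrics to compute.
#' @return data.frame with one column per requested metric (one row per
#'   subject).
#' @export
compute_global_aucs <- function(connectomes, s_min = 0.05, s_max = 0.14,
                                step = 0.01, eloc_mode = "printed",
                                metrics = c("Cp", "Lp", "Eglob", "Eloc")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  rows <- lapply(connectomes, function(cn) {
    cur <- metric_curves(threshold_series(cn, s_min, s_max, step),
                         eloc_mode = eloc_mode, metrics = metrics)
    as.data.frame(lapply(cur, `[[`, "auc"))
  })
  do.call(rbind, rows)
}

#' Per-subject nodal efficiency AUCs
#'
#' @inheritParams compute_global_aucs
#' @return list with matrices `nodal_global` and `nodal_local`
#'   (subjects x nodes).
#' @export
compute_nodal_aucs <- function(connectomes, s_min = 0.05, s_max = 0.14,
                               step = 0.01) {
  res <- lapply(connectomes, function(cn) {
    cur <- metric_curves(threshold_series(cn, s_min, s_max, step))
    list(g = cur$nodal_global$auc, l = cur$nodal_local$auc)
  })
  list(nodal_global = t(vapply(res, `[[`, numeric(length(res[[1]]$g)), "g")),
       nodal_local = t(vapply(res, `[[`, numeric(length(res[[1]]$l)), "l")))
}
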