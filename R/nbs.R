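# vectorised pooled two-sample t over edge columns; returns t vector with
# degenerate-variance edges set to NA
edge_t_vec <- function(w, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  ma <- colMeans(w[idx_a, , drop = FALSE])
  mb <- colMeans(w[idx_b, , drop = FALSE])
  va <- (colMeans(w[idx_a, , drop = FALSE]^2) - ma^2) * na / (na - 1)
  vb <- (colMeans(w[idx_b, , drop = FALSE]^2) - mb^2) * nb / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  tt[sp2 <= 1e-24] <- NA_real_
  tt
}

stack_weights <- function(connectomes) {
  n <- nrow(connectomes[[1]]$weights)
  t(vapply(connectomes, function(cn) {
    if (nrow(cn$weights) != n)
      stop("connectomes must share one parcellation", call. = FALSE)
    ut_vec(cn$weights)
  }, numeric(n * (n - 1) / 2)))
}

#' Edgewise two-sample t statistics between groups
#'
#' Pooled-variance t per edge, computed only for edges nonzero in at least
#' one subject; the default one-tailed direction tests group A > group B
#' (controls greater than patients). Edges with degenerate variance get
#' p = 1 (logged); untested edges get t = 0, p = 1.
#'
#' @param groupA,groupB lists of `connectome`s (group A first, conventionally
#'   controls).
#' @param tail `"right"` (A > B, default), `"left"` or `"two"`.
#' @return list of symmetric matrices `t_matrix` and `p_matrix`.
#' @export
edgewise_t <- function(groupA, groupB, tail = c("right", "left", "two")) {
  tail <- match.arg(tail)
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs >= 2 subjects", call. = FALSE)
  w <- stack_weights(c(groupA, groupB))
  n <- nrow(groupA[[1]]$weights)
  na <- length(groupA)
  tested <- colSums(w != 0) > 0
  tt <- rep(0, ncol(w))
  pp <- rep(1, ncol(w))
  if (any(tested)) {
    tv <- edge_t_vec(w[, tested, drop = FALSE], seq_len(na),
                     na + seq_len(length(groupB)))
    df <- nrow(w) - 2
    n_degen <- sum(is.na(tv))
    if (n_degen > 0)
      sivconn_log("edgewise_t: %d edges with degenerate variance set to p = 1",
                  n_degen)
    pv <- switch(tail,
      right = stats::pt(tv, df, lower.tail = FALSE),
      left = stats::pt(tv, df),
      two = 2 * stats::pt(-abs(tv), df))
    pv[is.na(tv)] <- 1
    tv[is.na(tv)] <- 0
    tt[tested] <- tv
    pp[tested] <- pv
  }
  list(t_matrix = ut_unvec(tt, n),
       p_matrix = ut_unvec(pp, n) + diag(1, n))
}

# union-find connected components over an edge index list;
# returns component id per edge
uf_components <- function(ei, ej, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(ei)) {
    ra <- find(ei[k]); rb <- find(ej[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(ei, find, integer(1))
}

#' Connected components of suprathreshold edges
#'
#' Retains edges with uncorrected p below `alpha_primary` and groups them
#' into connected components; component size is the edge count.
#'
#' @param p_matrix symmetric matrix of uncorrected edge p-values.
#' @param alpha_primary primary (edge-forming) threshold.
#' @return list of components, each with `edges` (k x 2 matrix), `nodes`
#'   and `size`, sorted by decreasing size.
#' @export
suprathreshold_components <- function(p_matrix, alpha_primary = 0.005) {
  n <- nrow(p_matrix)
  pairs <- ut_pairs(n)
  keep <- which(ut_vec(p_matrix) < alpha_primary)
  if (length(keep) == 0) return(list())
  ei <- pairs[keep, 1L]; ej <- pairs[keep, 2L]
  comp <- uf_components(ei, ej, n)
  split_idx <- split(seq_along(keep), comp)
  comps <- lapply(split_idx, function(ix) {
    e <- cbind(i = ei[ix], j = ej[ix])
    list(edges = e, nodes = sort(unique(as.integer(e))), size = nrow(e))
  })
  comps <- comps[order(-vapply(comps, `[[`, integer(1), "size"))]
  names(comps) <- NULL
  comps
}

# max suprathreshold component size (edge count) for a t vector on the
# tested-edge subset, given a t threshold in the chosen direction
max_component_size <- function(tv, t_crit, pairs_i, pairs_j, n_nodes,
                               tail) {
  keep <- switch(tail,
    right = which(!is.na(tv) & tv > t_crit),
    left = which(!is.na(tv) & tv < -t_crit),
    two = which(!is.na(tv) & abs(tv) > t_crit))
  if (length(keep) == 0) return(0L)
  comp <- uf_components(pairs_i[keep], pairs_j[keep], n_nodes)
  max(tabulate(match(comp, unique(comp))))
}

#' Network-based statistic group comparison
#'
#' Three-step NBS: (1) edgewise pooled t between groups in the chosen
#' one-tailed direction, (2) connected components of edges passing the
#' primary threshold, (3) familywise-corrected component p-values against a
#' permutation null of maximal component sizes obtained by reshuffling group
#' labels (one shuffle reused across all edges per permutation). The
#' corrected p for an observed component of size M is
#' (1 + #\{null max >= M\}) / (1 + n_perm) by default; strict `>` comparison
#' is available via `strict_greater = TRUE`.
#'
#' @param connectomes list of `connectome`s for all subjects.
#' @param groups factor/character vector: "control" or "patient" per subject.
#' @param alpha_primary edge-forming uncorrected p threshold.
#' @param n_perm permutation count.
#' @param alpha_report corrected significance level for components.
#' @param tail one-tailed direction; default `"right"` = control > patient.
#' @param seed RNG seed.
#' @param strict_greater compare null sizes with `>` instead of `>=`.
#' @return object of class `nbs_result`: `t_matrix`,
#'   `p_uncorrected_matrix`, `components`, `component_p_corrected`,
#'   `null_max_sizes`, `alpha_primary`, `alpha_report`, `n_perm`, `seed`,
#'   `significant` (logical per component), `sig_edges`, `sig_edge_count`,
#'   `hubs`.
#' @export
nbs_test <- function(connectomes, groups, alpha_primary = 0.005,
                     n_perm = 10000, alpha_report = 0.01,
                     tail = c("right", "left", "two"), seed = NULL,
                     strict_greater = FALSE) {
  tail <- match.arg(tail)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  groups <- as.character(groups)
  if (length(groups) != length(connectomes))
    stop("groups must align with connectomes", call. = FALSE)
  idx_a <- which(groups == "control")
  idx_b <- which(groups == "patient")
  if (length(idx_a) < 2 || length(idx_b) < 2)
    stop("each group needs >= 2 subjects", call. = FALSE)
  n <- nrow(connectomes[[1]]$weights)
  w <- stack_weights(connectomes)
  pairs <- ut_pairs(n)
  tested <- which(colSums(w != 0) > 0)
  wt <- w[, tested, drop = FALSE]
  pi_t <- pairs[tested, 1L]; pj_t <- pairs[tested, 2L]
  s <- nrow(w)
  df <- s - 2
  t_crit <- stats::qt(1 - alpha_primary, df)

  tv <- edge_t_vec(wt, idx_a, idx_b)
  tt_full <- rep(0, ncol(w)); pp_full <- rep(1, ncol(w))
  pv <- switch(tail,
    right = stats::pt(tv, df, lower.tail = FALSE),
    left = stats::pt(tv, df),
    two = 2 * stats::pt(-abs(tv), df))
  pp_full[tested] <- ifelse(is.na(tv), 1, pv)
  tt_full[tested] <- ifelse(is.na(tv), 0, tv)
  p_matrix <- ut_unvec(pp_full, n) + diag(1, n)
  t_matrix <- ut_unvec(tt_full, n)

  comps <- suprathreshold_components(p_matrix, alpha_primary)

  na <- length(idx_a)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      perm_a <- sample.int(s, na)
      perm_b <- setdiff(seq_len(s), perm_a)
      tvk <- edge_t_vec(wt, perm_a, perm_b)
      as.integer(max_component_size(tvk, t_crit, pi_t, pj_t, n, tail))
    }, integer(1))
  })

  sizes <- vapply(comps, `[[`, integer(1), "size")
  p_corr <- vapply(sizes, function(m) {
    hits <- if (strict_greater) sum(null_max > m) else sum(null_max >= m)
    (1 + hits) / (1 + n_perm)
  }, numeric(1))
  significant <- p_corr < alpha_report
  sig_edges <- if (any(significant))
    do.call(rbind, lapply(comps[significant], `[[`, "edges"))
  else matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  hubs <- identify_hubs(sig_edges)

  structure(
    list(t_matrix = t_matrix, p_uncorrected_matrix = p_matrix,
         components = comps, component_p_corrected = p_corr,
         null_max_sizes = null_max, alpha_primary = alpha_primary,
         alpha_report = alpha_report, n_perm = n_perm, seed = seed,
         tail = tail, significant = significant, sig_edges = sig_edges,
         sig_edge_count = nrow(sig_edges), hubs = hubs),
    class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<NBS: %d component(s), %d significant edge(s) at corrected p < %.3g>\n",
              length(x$components), x$sig_edge_count, x$alpha_report))
  invisible(x)
}

#' Identify hub nodes on the significant-edge graph
#'
#' Node degree is computed over the significant edges; among nodes with
#' degree >= 1, hubs are those whose degree exceeds the mean by more than
#' one sample SD.
#'
#' @param sig_edges k x 2 matrix of node pairs.
#' @return sorted integer vector of hub node indices (empty for an empty
#'   edge set or when no degree exceeds the cut).
#' @export
identify_hubs <- function(sig_edges) {
  if (is.null(sig_edges) || nrow(sig_edges) == 0) return(integer(0))
  deg_tab <- table(as.integer(sig_edges))
  deg <- as.integer(deg_tab)
  nodes <- as.integer(names(deg_tab))
  cut <- mean(deg) + stats::sd(deg)
  if (is.na(cut)) return(integer(0))   # single node cannot happen; guard
  sort(nodes[deg > cut])
}

#' Export significant NBS links for connectogram rendering
#'
#' Writes one row per significant edge with its t value, connection type
#' (left_intra / right_intra / inter by hemisphere) and the two lobes, in
#' deterministic (i, j) order. An empty result yields a header-only file.
#'
#' @param result an `nbs_result`.
#' @param node_table data.frame as returned by [load_node_labels()].
#' @param path output TSV path.
#' @return invisibly, the exported data.frame.
#' @export
export_connectogram_links <- function(result, node_table, path) {
  e <- result$sig_edges
  n_nodes <- nrow(node_table)
  if (nrow(e) > 0 && (max(e) > n_nodes || min(e) < 1))
    stop("edge references a node outside the label table", call. = FALSE)
  if (nrow(e) > 0) {
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
    hemi_i <- node_table$hemisphere[e[, 1]]
    hemi_j <- node_table$hemisphere[e[, 2]]
    type <- ifelse(hemi_i != hemi_j, "inter",
                   ifelse(hemi_i == "L", "left_intra", "right_intra"))
    out <- data.frame(
      node_i = node_table$label[e[, 1]],
      node_j = node_table$label[e[, 2]],
      t_value = result$t_matrix[cbind(e[, 1], e[, 2])],
      connection_type = type,
      lobe_i = node_table$lobe[e[, 1]],
      lobe_j = node_table$lobe[e[, 2]],
      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(node_i = character(0), node_j = character(0),
                      t_value = numeric(0), connection_type = character(0),
                      lobe_i = character(0), lobe_j = character(0))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
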