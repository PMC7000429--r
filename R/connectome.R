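#' Weighted structural connectome
#'
#' A connectome is a symmetric, nonnegative, zero-diagonal weighted adjacency
#' matrix over a fixed parcellation, optionally carrying node labels,
#' hemisphere assignments and lobe groupings.
#'
#' @param weights symmetric nonnegative numeric matrix with zero diagonal.
#' @param node_labels character vector of region labels (defaults to "n1"...).
#' @param hemisphere character vector of "L"/"R" per node, or NULL.
#' @param lobe character vector of lobe names per node, or NULL.
#' @param tol asymmetry tolerance; larger deviations raise an error.
#' @return an object of class `connectome`.
#' @export
connectome <- function(weights, node_labels = NULL, hemisphere = NULL,
                       lobe = NULL, tol = 1e-8) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("weights must be a numeric matrix", call. = FALSE)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights must be square", call. = FALSE)
  if (any(!is.finite(weights))) stop("weights must be finite", call. = FALSE)
  if (max(abs(weights - t(weights))) > tol)
    stop("weights asymmetric beyond tolerance", call. = FALSE)
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) {
    if (max(abs(diag(weights))) > tol)
      stop("weights must have a zero diagonal", call. = FALSE)
    diag(weights) <- 0
  }
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  node_labels <- node_labels %||% paste0("n", seq_len(n))
  if (length(node_labels) != n)
    stop("node_labels length must match node count", call. = FALSE)
  structure(
    list(weights = weights, node_labels = as.character(node_labels),
         hemisphere = hemisphere, lobe = lobe),
    class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  cat(sprintf("<connectome: %d nodes, %d edges, sparsity %.3f>\n",
              n, sum(ut_vec(x$weights) > 0), sparsity(x)))
  invisible(x)
}

as_connectome <- function(x, template = NULL) {
  if (inherits(x, "connectome")) return(x)
  connectome(x,
             node_labels = template$node_labels,
             hemisphere = template$hemisphere,
             lobe = template$lobe)
}

#' Network sparsity
#'
#' Fraction of the N(N-1)/2 undirected node pairs joined by a nonzero edge.
#'
#' @param c a `connectome` (or plain symmetric weight matrix).
#' @return a fraction in \[0, 1\].
#' @export
sparsity <- function(c) {
  w <- if (inherits(c, "connectome")) c$weights else c
  n <- nrow(w)
  if (n < 2) stop("sparsity requires >= 2 nodes", call. = FALSE)
  sum(ut_vec(w) > 0) / (n * (n - 1) / 2)
}

#' Load the packaged 90-node parcellation table
#'
#' Ninety regions (45 per hemisphere, nodes 1-45 left and 46-90 right in the
#' R-side 1-based indexing; the file stores 0-based indices) with AAL-style
#' labels and a six-way lobe grouping (frontal, temporal, parietal,
#' medial-temporal, occipital, subcortical) used for connectogram exports.
#'
#' @param path optional path to an alternative node-label TSV.
#' @return data.frame with columns node_index, label, hemisphere, lobe.
#' @export
load_node_labels <- function(path = NULL) {
  path <- path %||% system.file("extdata", "aal90_node_labels.tsv",
                                package = "sivconn", mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_index", "label", "hemisphere", "lobe")
  if (!all(need %in% names(d)))
    stop("node label table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  d[order(d$node_index), , drop = FALSE]
}
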