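#' Build an FA-weighted connectome from streamline counts and mean FA
#'
#' An edge is retained when the streamline count between two regions is at
#' least `min_streamlines` (default 3); its weight is the mean FA along the
#' connecting bundles. All other entries are zero.
#'
#' @param counts symmetric streamline-count matrix with zero diagonal.
#' @param fa symmetric mean-FA matrix, same shape.
#' @param min_streamlines minimum streamline support for an edge.
#' @param node_labels,hemisphere,lobe optional node annotations passed to
#'   [connectome()].
#' @return a `connectome`.
#' @export
build_connectome <- function(counts, fa, min_streamlines = 3,
                             node_labels = NULL, hemisphere = NULL,
                             lobe = NULL) {
  if (!is.matrix(counts) || !is.matrix(fa) ||
      !all(dim(counts) == dim(fa)) || nrow(counts) != ncol(counts))
    stop("counts and fa must be square matrices of identical shape",
         call. = FALSE)
  if (max(abs(counts - t(counts))) > 1e-8 || max(abs(fa - t(fa))) > 1e-8)
    stop("counts and fa must be symmetric", call. = FALSE)
  w <- ifelse(counts >= min_streamlines, fa, 0)
  diag(w) <- 0
  connectome(w, node_labels = node_labels, hemisphere = hemisphere,
             lobe = lobe)
}

#' Remove covariate effects from edge weights by regression
#'
#' For every edge present in at least one subject, fits ordinary least
#' squares of edge weight on \[1, age, sex, education\] across subjects and
#' replaces each weight with its residual plus the edge's across-subject
#' grand mean (the fitted value at the covariate means). Entries that are
#' zero in a subject stay zero; adjusted weights that fall below zero are
#' floored at zero (count reported via the verbose log and the
#' `n_floored` attribute).
#'
#' @param connectomes list of `connectome`s, one per subject, aligned with
#'   the rows of `covariates`.
#' @param covariates data.frame with numeric columns age, sex, education.
#' @return list of adjusted `connectome`s with attribute `n_floored`.
#' @export
deconfound_edges <- function(connectomes, covariates) {
  s <- length(connectomes)
  if (s < 4) stop("need at least 4 subjects (more subjects than regressors)",
                  call. = FALSE)
  need <- c("age", "sex", "education")
  if (!all(need %in% names(covariates)) || nrow(covariates) != s)
    stop("covariates must have one aligned row per subject with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  x <- cbind(1, as.matrix(covariates[, need]))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop <- setdiff(seq_len(ncol(x)), qx$pivot[seq_len(qx$rank)])
    stop("rank-deficient covariate design; collinear columns: ",
         paste(c("intercept", need)[drop], collapse = ", "), call. = FALSE)
  }
  n <- nrow(connectomes[[1]]$weights)
  y <- t(vapply(connectomes, function(cn) ut_vec(cn$weights),
                numeric(n * (n - 1) / 2)))
  res <- qr.resid(qx, y)
  adj <- sweep(res, 2, colMeans(y), `+`)
  adj[y == 0] <- 0
  n_floored <- sum(adj < 0)
  if (n_floored > 0) {
    sivconn_log("deconfound_edges: floored %d negative adjusted weights",
                n_floored)
    adj[adj < 0] <- 0
  }
  out <- lapply(seq_len(s), function(k) {
    cn <- connectomes[[k]]
    cn$weights <- ut_unvec(adj[k, ], n)
    cn
  })
  attr(out, "n_floored") <- n_floored
  out
}

#' Threshold a connectome to a target sparsity
#'
#' Keeps the k = round(target * N(N-1)/2) largest-weight edges (weights
#' preserved), zeroing all others. Ties at the cutoff are broken by
#' lexicographic (i, j) order so runs are reproducible, and edge sets are
#' nested across increasing targets.
#'
#' @param c a `connectome`.
#' @param target sparsity fraction; must not exceed the current sparsity.
#' @return the thresholded `connectome`.
#' @export
threshold_to_sparsity <- function(c, target) {
  w <- c$weights
  n <- nrow(w)
  np <- n * (n - 1) / 2
  if (!is.finite(target) || target <= 0)
    stop("target sparsity must be positive", call. = FALSE)
  v <- ut_vec(w)
  k <- round(target * np)
  avail <- sum(v > 0)
  if (k > avail)
    stop(sprintf(paste0(
      "target sparsity %.3f needs %d edges but only %d are present; ",
      "threshold the raw network at or below its own sparsity (%.3f)"),
      target, k, avail, avail / np), call. = FALSE)
  keep <- order(-v, seq_along(v))[seq_len(k)]
  out <- numeric(length(v))
  out[keep] <- v[keep]
  c$weights <- ut_unvec(out, n)
  c
}

#' Threshold a connectome over a sparsity grid
#'
#' @param c a `connectome`.
#' @param s_min,s_max,step inclusive sparsity grid (defaults 5-14% by 1%,
#'   the range over which whole-brain global metrics are summarised).
#' @return object of class `threshold_series` with elements `sparsities`
#'   and `networks`.
#' @export
threshold_series <- function(c, s_min = 0.05, s_max = 0.14, step = 0.01) {
  if (s_min > s_max || step <= 0)
    stop("require s_min <= s_max and step > 0", call. = FALSE)
  grid <- round(seq(s_min, s_max, by = step), 10)
  structure(
    list(sparsities = grid,
         networks = lapply(grid, function(s) threshold_to_sparsity(c, s))),
    class = "threshold_series")
}
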