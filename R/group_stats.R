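#' Two-sample t statistic from summary statistics
#'
#' Pooled-variance (default) or Welch t computed directly from group means,
#' SDs and sizes, with sign convention mean1 - mean2. Used to reproduce
#' published demographic/clinical t values from summary tables.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @param var_equal pooled variance if TRUE (default), Welch otherwise.
#' @return list with `statistic`, `df` and two-sided `p_value`.
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           var_equal = TRUE) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive", call. = FALSE)
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tt <- (mean1 - mean2) / se
  list(statistic = tt, df = df,
       p_value = 2 * stats::pt(-abs(tt), df))
}

#' Remove covariate effects from a per-subject scalar
#'
#' Residual-plus-grand-mean adjustment, the scalar analogue of
#' [deconfound_edges()]: OLS of the values on \[1, age, sex, education\],
#' keeping the residual plus the overall mean.
#'
#' @param values numeric vector, one value per subject.
#' @param covariates data.frame with columns age, sex, education aligned
#'   with `values`.
#' @return adjusted numeric vector.
#' @export
deconfound_scalar <- function(values, covariates) {
  need <- c("age", "sex", "education")
  if (!all(need %in% names(covariates)) ||
      nrow(covariates) != length(values))
    stop("covariates must have one aligned row per value with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  x <- cbind(1, as.matrix(covariates[, need]))
  if (nrow(x) <= ncol(x))
    stop("need more subjects than regressors", call. = FALSE)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop <- setdiff(seq_len(ncol(x)), qx$pivot[seq_len(qx$rank)])
    stop("rank-deficient covariate design; collinear columns: ",
         paste(c("intercept", need)[drop], collapse = ", "), call. = FALSE)
  }
  as.numeric(qr.resid(qx, values)) + mean(values)
}

#' Group-difference permutation test
#'
#' The statistic is mean(valuesA) - mean(valuesB). Group labels are
#' shuffled preserving group sizes; the p-value uses the add-one rule
#' p = (1 + #extreme) / (1 + n_perm) by default (guaranteeing p in
#' (0, 1\]), or the plain proportion when `add_one = FALSE`.
#'
#' @param valuesA,valuesB numeric vectors (each length >= 2).
#' @param n_perm number of label permutations.
#' @param tail `"two"`, `"right"` (A > B) or `"left"`.
#' @param seed optional RNG seed.
#' @param add_one use the add-one p-value rule.
#' @param statistic_name label stored with the result.
#' @return object of class `permutation_result` with fields
#'   `statistic_name`, `observed_diff`, `null_distribution`, `p_value`,
#'   `n_perm`, `seed`, `tail`.
#' @export
permutation_test <- function(valuesA, valuesB, n_perm = 10000,
                             tail = c("two", "right", "left"),
                             seed = NULL, add_one = TRUE,
                             statistic_name = "mean_diff") {
  tail <- match.arg(tail)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  na <- length(valuesA); nb <- length(valuesB)
  if (na < 2 || nb < 2) stop("each group needs >= 2 subjects", call. = FALSE)
  pooled <- c(valuesA, valuesB)
  obs <- mean(valuesA) - mean(valuesB)
  tot <- sum(pooled)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      sa <- sum(pooled[sample.int(na + nb, na)])
      sa / na - (tot - sa) / nb
    }, numeric(1))
  })
  eps <- 1e-12 * (1 + abs(obs))
  n_extreme <- switch(tail,
    two = sum(abs(null) >= abs(obs) - eps),
    right = sum(null >= obs - eps),
    left = sum(null <= obs + eps))
  p <- if (add_one) (1 + n_extreme) / (1 + n_perm) else n_extreme / n_perm
  structure(
    list(statistic_name = statistic_name, observed_diff = obs,
         null_distribution = null, p_value = p, n_perm = n_perm,
         seed = seed, tail = tail),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation test '%s': diff = %.4g, p = %.4g (%s-tailed, %d perms)>\n",
              x$statistic_name, x$observed_diff, x$p_value, x$tail, x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure over one family of p-values.
#'
#' @param p_values numeric vector in \[0,1\].
#' @param q FDR level.
#' @return list with logical `rejected` and numeric `p_adjusted`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0,1]", call. = FALSE)
  adj <- stats::p.adjust(p_values, method = "BH")
  list(rejected = adj <= q, p_adjusted = adj)
}

#' Standardise scores to zero mean, unit sample SD
#' @param scores numeric vector, length >= 2, nonzero variance.
#' @return z-scores.
#' @export
zscore <- function(scores) {
  if (length(scores) < 2) stop("need >= 2 values", call. = FALSE)
  s <- stats::sd(scores)
  if (s == 0) stop("zero variance: z-scores undefined", call. = FALSE)
  (scores - mean(scores)) / s
}

#' Pearson correlation between a metric and cognitive scores
#'
#' @param metric_auc per-subject metric values.
#' @param score_z per-subject (z-scored) cognitive scores.
#' @return list with `r` and two-sided `p_value` from the t transform.
#' @export
pearson_with_scores <- function(metric_auc, score_z) {
  if (length(metric_auc) != length(score_z) || length(metric_auc) < 3)
    stop("need >= 3 aligned pairs", call. = FALSE)
  if (stats::sd(metric_auc) == 0 || stats::sd(score_z) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(metric_auc, score_z, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
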