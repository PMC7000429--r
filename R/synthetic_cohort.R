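#' Parameters for the synthetic two-group connectome cohort
#'
#' Defines the conditions the generator emulates: a 90-node parcellation with
#' raw network sparsity in the 20-28% band, 14 controls and 13 patients,
#' a patient-group FA attenuation planted on a small connected edge set, a
#' global patient FA decrease driving degraded global topology, additive
#' age/sex/education confounds on edge weights, and cognitive scores coupled
#' to each subject's latent network integrity.
#'
#' @param n_controls,n_patients group sizes.
#' @param n_nodes parcellation size (first half left hemisphere, second right).
#' @param density_range ordered pair in (0,1); every subject's raw sparsity
#'   (fraction of pairs with >= 3 streamlines) falls inside this band.
#' @param fa_mean,fa_sd centre of the edge-level mean-FA distribution over
#'   all candidate pairs (baseline FA increases with tract strength, so
#'   present edges average higher) and the per-subject edge noise SD
#'   (FA units).
#' @param planted_edges integer matrix (k x 2) of 1-based node pairs carrying
#'   the patient-group attenuation; default is a connected 6-edge
#'   fronto-subcortical / parieto-occipital set on the 90-node parcellation.
#' @param planted_attenuation fraction in \[0,1); patient mean FA on planted
#'   edges is multiplied by (1 - planted_attenuation).
#' @param global_fa_shift patient-group mean FA damage fraction. Each subject
#'   carries a latent damage level (0.02 baseline, plus `global_fa_shift` for
#'   patients, plus N(0, `subject_shift_sd`) spread); every edge's FA is
#'   multiplied by 1 minus an exponentially distributed damage factor with
#'   that mean. The heterogeneity (some tracts hit hard, some spared) lowers
#'   the normalised-weight clustering coefficient as well as global
#'   efficiency and raises path length in the patient group.
#' @param subject_shift_sd SD of the latent per-subject damage level, shared
#'   by all of a subject's edges and by their cognitive scores.
#' @param covariate_effect named numeric slopes (age, sex, education) of the
#'   additive confound on edge FA.
#' @param score_noise_sd SD of the score noise added on top of the latent
#'   integrity signal (score points).
#' @param seed integer RNG seed; identical parameters give identical cohorts.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n_controls = 14, n_patients = 13, n_nodes = 90,
                          density_range = c(0.20, 0.28),
                          fa_mean = 0.45, fa_sd = 0.04,
                          planted_edges = NULL,
                          planted_attenuation = 0.3,
                          global_fa_shift = 0.14,
                          subject_shift_sd = 0.05,
                          covariate_effect = c(age = -0.002, sex = 0.005,
                                               education = 0.001),
                          score_noise_sd = 1.0,
                          seed = 1L) {
  chk_count <- function(x, field, min) {
    if (length(x) != 1 || !is.finite(x) || x != round(x) || x < min)
      stop_param(field, sprintf("must be a single integer >= %d", min))
  }
  chk_count(n_controls, "n_controls", 2)
  chk_count(n_patients, "n_patients", 2)
  chk_count(n_nodes, "n_nodes", 4)
  if (length(density_range) != 2 || any(!is.finite(density_range)) ||
      density_range[1] >= density_range[2] ||
      density_range[1] <= 0 || density_range[2] >= 1)
    stop_param("density_range", "must be an ordered pair inside (0,1)")
  if (!is.finite(fa_mean) || fa_mean <= 0 || fa_mean >= 1)
    stop_param("fa_mean", "must lie in (0,1)")
  if (!is.finite(fa_sd) || fa_sd < 0) stop_param("fa_sd", "must be >= 0")
  if (is.null(planted_edges)) {
    planted_edges <- if (n_nodes == 90) default_planted_edges()
                     else matrix(integer(0), 0, 2)
  }
  planted_edges <- as.matrix(planted_edges)
  if (nrow(planted_edges) > 0) {
    if (ncol(planted_edges) != 2 ||
        any(planted_edges != round(planted_edges)) ||
        any(planted_edges < 1) || any(planted_edges > n_nodes) ||
        any(planted_edges[, 1] == planted_edges[, 2]))
      stop_param("planted_edges",
                 "every edge must name two distinct node indices in 1..n_nodes")
  }
  if (!is.finite(planted_attenuation) || planted_attenuation < 0 ||
      planted_attenuation >= 1)
    stop_param("planted_attenuation", "must lie in [0,1)")
  if (!is.finite(global_fa_shift) || global_fa_shift < 0)
    stop_param("global_fa_shift", "must be >= 0")
  if (!is.finite(subject_shift_sd) || subject_shift_sd < 0)
    stop_param("subject_shift_sd", "must be >= 0")
  if (length(covariate_effect) != 3 ||
      !all(c("age", "sex", "education") %in% names(covariate_effect)))
    stop_param("covariate_effect", "must be named slopes for age, sex, education")
  if (!is.finite(score_noise_sd) || score_noise_sd < 0)
    stop_param("score_noise_sd", "must be >= 0")
  chk_count(seed, "seed", 0)
  structure(
    list(n_controls = as.integer(n_controls),
         n_patients = as.integer(n_patients),
         n_nodes = as.integer(n_nodes),
         density_range = as.numeric(density_range),
         fa_mean = fa_mean, fa_sd = fa_sd,
         planted_edges = planted_edges,
         planted_attenuation = planted_attenuation,
         global_fa_shift = global_fa_shift,
         subject_shift_sd = subject_shift_sd,
         covariate_effect = covariate_effect[c("age", "sex", "education")],
         score_noise_sd = score_noise_sd,
         seed = as.integer(seed)),
    class = "cohort_params")
}

# connected 6-edge planted component on the 90-node parcellation:
# THA.L-CAU.L, THA.L-PUT.L, THA.L-MFG.L, MFG.L-IFGtriang.L,
# THA.L-PCUN.L, PCUN.L-MOG.L (1-based node ids of the packaged table)
default_planted_edges <- function() {
  rbind(c(39L, 36L), c(39L, 37L), c(4L, 39L), c(4L, 7L),
        c(34L, 39L), c(26L, 34L))
}

# bounded-rejection truncated normal, rounded to integer years/points
rtrunc_int <- function(mu, sd, lo, hi) {
  for (k in 1:200) {
    x <- stats::rnorm(1, mu, sd)
    if (x >= lo && x <= hi) return(as.integer(round(x)))
  }
  as.integer(round(min(max(mu, lo), hi)))
}

#' Generate a synthetic two-group connectome cohort
#'
#' Each subject receives a streamline-count matrix and a mean-FA matrix over a
#' common spatially smooth backbone (ring-distance connection kernel with
#' cohort- and subject-level lognormal propensity noise), a target raw
#' sparsity drawn uniformly inside the interior of `density_range`, covariates
#' with group-conditional distributions, and MMSE/MoCA scores linear in the
#' subject's latent damage level plus noise. Patients receive heterogeneous
#' multiplicative FA damage (mean fraction `global_fa_shift` on top of the
#' 0.02 baseline damage every subject carries) and a further multiplicative
#' attenuation on the planted edges. Pairs below the backbone cut receive
#' zero-inflated streamline counts in 0-2 so the >= 3-streamline edge rule
#' filters real candidates.
#'
#' @param params a [cohort_params()] object.
#' @return list of subject records (class `subject_record`), controls first;
#'   each carries subject_id, group, age, sex, education, mmse, moca,
#'   streamline_counts and mean_fa.
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params"))
    stop("params must be a cohort_params object", call. = FALSE)
  p <- params
  n <- p$n_nodes
  pairs <- ut_pairs(n)
  np <- nrow(pairs)
  k_planted <- nrow(p$planted_edges)
  planted_idx <- integer(0)
  if (k_planted > 0) {
    a <- pmin(p$planted_edges[, 1], p$planted_edges[, 2])
    b <- pmax(p$planted_edges[, 1], p$planted_edges[, 2])
    key <- paste(pairs[, 1], pairs[, 2])
    planted_idx <- match(paste(a, b), key)
  }

  with_seed(p$seed, {
    ringd <- pmin(abs(pairs[, 1] - pairs[, 2]),
                  n - abs(pairs[, 1] - pairs[, 2]))
    kernel <- exp(-ringd / (n / 10))
    template <- kernel * exp(stats::rnorm(np, 0, 0.6))
    # planted edges emulate reliably tracked tracts: strong template propensity
    if (k_planted > 0)
      template[planted_idx] <- as.numeric(stats::quantile(template, 0.995))
    # edge-level baseline FA: rescaled Beta centred on fa_mean, increasing in
    # tract strength so strong tracts carry high FA and pin the network max
    prank <- rank(template, ties.method = "average") / np
    base_fa <- p$fa_mean + 0.5 * (prank - 0.5) +
      (stats::rbeta(np, 4, 4) - 0.5) * 0.25
    base_fa <- pmin(pmax(base_fa, 0.05), 0.95)

    lo <- p$density_range[1]; hi <- p$density_range[2]
    margin <- 0.1 * (hi - lo)
    groups <- c(rep("control", p$n_controls), rep("patient", p$n_patients))
    ids <- c(sprintf("ctrl%02d", seq_len(p$n_controls)),
             sprintf("pat%02d", seq_len(p$n_patients)))
    slopes <- p$covariate_effect

    lapply(seq_along(groups), function(s) {
      g <- groups[s]
      if (g == "control") {
        age <- rtrunc_int(65.1, 5.0, 58, 76)
        sex <- stats::rbinom(1, 1, 8 / 14)
        edu <- rtrunc_int(10.4, 4.1, 0, 16)
      } else {
        age <- rtrunc_int(68.3, 9.8, 47, 83)
        sex <- stats::rbinom(1, 1, 7 / 13)
        edu <- rtrunc_int(8.5, 4.1, 1, 16)
      }
      # latent damage level: 0.02 baseline, group degradation, subject spread
      delta <- max(0, 0.02 + (g == "patient") * p$global_fa_shift +
                     p$subject_shift_sd * stats::rnorm(1))

      s_target <- stats::runif(1, lo + margin, hi - margin)
      k_edges <- round(s_target * np)
      prop <- template * exp(stats::rnorm(np, 0, 0.30))
      if (k_planted > 0) prop[planted_idx] <- Inf
      sel <- order(prop, decreasing = TRUE)[seq_len(k_edges)]

      counts <- integer(np)
      counts[sel] <- 3L + stats::rnbinom(k_edges, size = 2, mu = 17)
      unsel <- setdiff(seq_len(np), sel)
      nz <- stats::rbinom(length(unsel), 1, 0.15)
      counts[unsel] <- nz * sample(1:2, length(unsel), replace = TRUE,
                                   prob = c(0.7, 0.3))

      fa <- numeric(np)
      nzp <- counts > 0L
      n_nz <- sum(nzp)
      fa[nzp] <- base_fa[nzp] + stats::rnorm(n_nz, 0, p$fa_sd) +
        slopes["age"] * (age - 66.6) + slopes["sex"] * (sex - 0.56) +
        slopes["education"] * (edu - 9.5)
      # heterogeneous multiplicative damage: spared edges keep the network max
      damage <- delta * pmin(stats::rexp(n_nz), 3)
      fa[nzp] <- fa[nzp] * (1 - pmin(damage, 0.9))
      if (g == "patient" && k_planted > 0) {
        att <- intersect(planted_idx, which(nzp))
        fa[att] <- fa[att] * (1 - p$planted_attenuation)
      }
      fa[nzp] <- pmin(pmax(fa[nzp], 0.02), 0.98)

      # scores track total network damage: the latent level above baseline
      # plus the planted component's share of network-mean FA
      eff <- (delta - 0.02) +
        (g == "patient") * p$planted_attenuation * k_planted / np
      noise <- stats::rnorm(2, 0, p$score_noise_sd)
      mmse <- as.integer(round(min(max(28.4 - 35 * eff + noise[1], 0), 30)))
      moca <- as.integer(round(min(max(27.1 - 89 * eff + noise[2], 0), 30)))

      structure(
        list(subject_id = ids[s], group = g, age = age, sex = sex,
             education = edu, mmse = mmse, moca = moca,
             streamline_counts = ut_unvec(counts, n),
             mean_fa = ut_unvec(fa, n),
             # generative ground truth, for validation studies; not written
             # by cohort_to_tables
             truth = list(latent_damage = delta, target_sparsity = s_target)),
        class = "subject_record")
    })
  })
}

#' Per-subject metadata as a data.frame
#' @param records list of subject records.
#' @return data.frame with one row per subject.
#' @export
cohort_metadata <- function(records) {
  if (length(records) == 0) stop("empty record list", call. = FALSE)
  do.call(rbind, lapply(records, function(r)
    data.frame(subject_id = r$subject_id, group = r$group, age = r$age,
               sex = r$sex, education = r$education, mmse = r$mmse,
               moca = r$moca, stringsAsFactors = FALSE)))
}

fmt_full <- function(x) {
  if (all(x == round(x))) format(x, scientific = FALSE, trim = TRUE)
  else formatC(x, digits = 17, format = "g")
}

write_matrix_tsv <- function(m, path) {
  lines <- apply(m, 1, function(row) paste(fmt_full(row), collapse = "\t"))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop(sprintf("failed to write matrix file '%s'", path),
                call. = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("matrix file not found: '%s'", path), call. = FALSE)
  as.matrix(utils::read.table(path, header = FALSE,
                              colClasses = "numeric"))
}

#' Write a cohort to its on-disk tabular layout
#'
#' Writes `metadata.tsv` plus two header-less whitespace-delimited square
#' matrix files per subject (`<subject_id>_counts.tsv`, `<subject_id>_fa.tsv`).
#' Floating-point values are written with full precision so a round-trip read
#' reproduces the cohort exactly.
#'
#' @param records list of subject records.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory path.
#' @export
cohort_to_tables <- function(records, dir) {
  if (length(records) == 0) stop("empty record list", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort_metadata(records)
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (r in records) {
    write_matrix_tsv(r$streamline_counts,
                     file.path(dir, paste0(r$subject_id, "_counts.tsv")))
    write_matrix_tsv(r$mean_fa,
                     file.path(dir, paste0(r$subject_id, "_fa.tsv")))
  }
  invisible(dir)
}

#' Read a cohort back from its tabular layout
#' @param dir directory written by [cohort_to_tables()].
#' @return list of subject records.
#' @export
read_cohort_tables <- function(dir) {
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path))
    stop(sprintf("metadata file not found: '%s'", meta_path), call. = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(k) {
    row <- meta[k, ]
    counts <- read_matrix_tsv(file.path(dir, paste0(row$subject_id,
                                                    "_counts.tsv")))
    fa <- read_matrix_tsv(file.path(dir, paste0(row$subject_id, "_fa.tsv")))
    dimnames(counts) <- NULL; dimnames(fa) <- NULL
    structure(
      list(subject_id = row$subject_id, group = row$group, age = row$age,
           sex = row$sex, education = row$education, mmse = row$mmse,
           moca = row$moca, streamline_counts = counts, mean_fa = fa),
      class = "subject_record")
  })
}
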