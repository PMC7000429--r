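#' Default end-to-end run configuration
#'
#' Collects the pipeline constants in one editable list: the 3-streamline
#' edge rule, the 5-14% sparsity grid in 1% steps, edge- and AUC-level
#' covariate removal, 10,000 permutations for metric and NBS inference, the
#' 0.005 NBS primary threshold with components reported at corrected
#' p < 0.01, FDR at q = 0.05, a two-tailed metric test with a
#' control > patient one-tailed NBS, and an RBF SVM at cost 1.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "sivconn_run",
    input_dir = NULL,
    synthetic = list(n_controls = 14L, n_patients = 13L, n_nodes = 90L,
                     density_range = c(0.20, 0.28), fa_mean = 0.45,
                     fa_sd = 0.04, planted_attenuation = 0.3,
                     global_fa_shift = 0.14, subject_shift_sd = 0.05,
                     score_noise_sd = 1.0),
    min_streamlines = 3,
    sparsity = list(s_min = 0.05, s_max = 0.14, step = 0.01),
    deconfound = list(edges = TRUE, auc = TRUE),
    permutation = list(n_metric = 10000L, n_nbs = 10000L,
                       n_classify = 1000L),
    alpha = list(primary = 0.005, nbs_report = 0.01, fdr_q = 0.05),
    tails = list(metric = "two", nbs = "right"),
    svm = list(cost = 1, gamma = NULL),
    eloc_mode = "printed",
    nodal_tests = FALSE,
    write_cohort = TRUE,
    run_classification = TRUE)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Validate a run configuration
#'
#' @param config configuration list (missing entries filled from
#'   [default_config()]).
#' @return the completed configuration, invisibly on success; errors name
#'   the offending field.
#' @export
validate_config <- function(config) {
  cfg <- merge_config(default_config(), config)
  frac <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0 || x >= 1)
      stop_param(field, "must be a fraction in (0,1)")
  }
  frac(cfg$sparsity$s_min, "sparsity.s_min")
  frac(cfg$sparsity$s_max, "sparsity.s_max")
  if (cfg$sparsity$step <= 0) stop_param("sparsity.step", "must be > 0")
  if (cfg$sparsity$s_min > cfg$sparsity$s_max)
    stop_param("sparsity", "s_min must not exceed s_max")
  frac(cfg$alpha$primary, "alpha.primary")
  frac(cfg$alpha$nbs_report, "alpha.nbs_report")
  frac(cfg$alpha$fdr_q, "alpha.fdr_q")
  for (f in c("n_metric", "n_nbs", "n_classify"))
    if (cfg$permutation[[f]] < 1)
      stop_param(paste0("permutation.", f), "must be >= 1")
  if (!cfg$tails$metric %in% c("two", "right", "left"))
    stop_param("tails.metric", "must be two/right/left")
  if (!cfg$tails$nbs %in% c("two", "right", "left"))
    stop_param("tails.nbs", "must be two/right/left")
  if (cfg$min_streamlines < 0)
    stop_param("min_streamlines", "must be >= 0")
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    stop_param("seed", "must be an integer")
  invisible(cfg)
}

#' Read a YAML run configuration
#' @param path YAML file.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

subject_metric_long <- function(id, curves, nodal = FALSE) {
  sp <- curves$Cp$sparsities
  glob <- do.call(rbind, lapply(c("Cp", "Lp", "Eglob", "Eloc"), function(m)
    data.frame(subject_id = id, metric = m, node = "global", sparsity = sp,
               value = curves[[m]]$values, stringsAsFactors = FALSE)))
  if (!nodal) return(glob)
  nod <- do.call(rbind, lapply(c("nodal_global", "nodal_local"), function(m) {
    v <- curves[[m]]$values
    data.frame(subject_id = id, metric = m,
               node = rep(paste0("n", seq_len(nrow(v))), times = ncol(v)),
               sparsity = rep(sp, each = nrow(v)),
               value = as.numeric(v), stringsAsFactors = FALSE)
  }))
  rbind(glob, nod)
}

#' Run the full connectome group-analysis pipeline
#'
#' Orchestrates cohort acquisition (synthetic generation or reading a
#' cohort directory), network construction with edge-level covariate
#' removal, metric curves and AUCs over the sparsity grid, covariate-
#' adjusted permutation tests with FDR control, brain-behaviour
#' correlations in patients, NBS with connectogram link export, and
#' SVM-LOOCV classification. All stage outputs plus a machine-readable
#' run manifest are written under `output_dir`; reruns with an identical
#' configuration are byte-identical.
#'
#' @param config configuration list or path to a YAML file; missing
#'   entries are filled from [default_config()].
#' @return invisibly, a result bundle (cohort, AUC tables, test results,
#'   NBS result, classification, manifest).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (is.character(config)) read_config(config)
         else validate_config(config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  records <- stage("cohort", {
    if (!is.null(cfg$input_dir)) read_cohort_tables(cfg$input_dir)
    else {
      par <- do.call(cohort_params, c(cfg$synthetic, list(seed = cfg$seed)))
      generate_cohort(par)
    }
  })
  meta <- cohort_metadata(records)
  if (isTRUE(cfg$write_cohort) && is.null(cfg$input_dir))
    stage("cohort", cohort_to_tables(records, file.path(out, "cohort")))

  n_nodes <- nrow(records[[1]]$mean_fa)
  node_table <- if (n_nodes == 90) load_node_labels()
    else data.frame(node_index = seq_len(n_nodes) - 1L,
                    label = paste0("n", seq_len(n_nodes)),
                    hemisphere = rep(c("L", "R"), each = ceiling(n_nodes / 2),
                                     length.out = n_nodes),
                    lobe = "unknown", stringsAsFactors = FALSE)

  nets <- stage("build", {
    built <- lapply(records, function(r)
      build_connectome(r$streamline_counts, r$mean_fa,
                       min_streamlines = cfg$min_streamlines,
                       node_labels = node_table$label,
                       hemisphere = node_table$hemisphere,
                       lobe = node_table$lobe))
    if (isTRUE(cfg$deconfound$edges)) deconfound_edges(built, meta)
    else built
  })

  sg <- cfg$sparsity
  curves_by_subject <- stage("metrics", lapply(nets, function(cn)
    metric_curves(threshold_series(cn, sg$s_min, sg$s_max, sg$step),
                  eloc_mode = cfg$eloc_mode)))
  auc_global <- data.frame(
    subject_id = meta$subject_id, group = meta$group,
    do.call(rbind, lapply(curves_by_subject, function(cu)
      data.frame(Cp = cu$Cp$auc, Lp = cu$Lp$auc, Eglob = cu$Eglob$auc,
                 Eloc = cu$Eloc$auc))))
  stage("metrics", {
    long <- do.call(rbind, lapply(seq_along(records), function(k)
      subject_metric_long(meta$subject_id[k], curves_by_subject[[k]],
                          nodal = isTRUE(cfg$nodal_tests))))
    write_tsv(long, file.path(out, "metrics.tsv"))
    write_tsv(auc_global, file.path(out, "auc_global.tsv"))
  })

  is_ctrl <- meta$group == "control"
  stats_tab <- stage("stats", {
    rows <- lapply(c("Cp", "Lp", "Eglob", "Eloc"), function(m) {
      v <- auc_global[[m]]
      if (isTRUE(cfg$deconfound$auc)) v <- deconfound_scalar(v, meta)
      pt <- permutation_test(v[is_ctrl], v[!is_ctrl],
                             n_perm = cfg$permutation$n_metric,
                             tail = cfg$tails$metric,
                             seed = (cfg$seed + 101) %% 2147483647,
                             statistic_name = m)
      data.frame(metric = m, observed_diff = pt$observed_diff,
                 p_raw = pt$p_value, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    fdr <- fdr_bh(tab$p_raw, q = cfg$alpha$fdr_q)
    tab$p_fdr <- fdr$p_adjusted
    tab$significant <- fdr$rejected
    write_tsv(tab, file.path(out, "stats_global.tsv"))
    tab
  })

  nodal_tab <- NULL
  if (isTRUE(cfg$nodal_tests)) {
    nodal_tab <- stage("stats", {
      rows <- list()
      for (m in c("nodal_global", "nodal_local")) {
        aucs <- t(vapply(curves_by_subject, function(cu) cu[[m]]$auc,
                         numeric(n_nodes)))
        p <- numeric(n_nodes); d <- numeric(n_nodes)
        for (j in seq_len(n_nodes)) {
          v <- aucs[, j]
          if (isTRUE(cfg$deconfound$auc)) v <- deconfound_scalar(v, meta)
          pt <- permutation_test(v[is_ctrl], v[!is_ctrl],
                                 n_perm = cfg$permutation$n_metric,
                                 tail = cfg$tails$metric,
                                 seed = (cfg$seed + 211 + j) %% 2147483647,
                                 statistic_name = paste0(m, "_", j))
          p[j] <- pt$p_value; d[j] <- pt$observed_diff
        }
        fdr <- fdr_bh(p, q = cfg$alpha$fdr_q)
        rows[[m]] <- data.frame(metric = m, node = node_table$label,
                                observed_diff = d, p_raw = p,
                                p_fdr = fdr$p_adjusted,
                                significant = fdr$rejected,
                                stringsAsFactors = FALSE)
      }
      tab <- do.call(rbind, rows)
      write_tsv(tab, file.path(out, "stats_nodal.tsv"))
      tab
    })
  }

  cor_tab <- stage("correlations", {
    pat <- !is_ctrl
    rows <- list()
    for (m in c("Cp", "Lp", "Eglob", "Eloc"))
      for (sc in c("mmse", "moca")) {
        z <- zscore(meta[[sc]][pat])
        r <- pearson_with_scores(auc_global[[m]][pat], z)
        rows[[paste(m, sc)]] <- data.frame(metric = m, score = sc,
                                           r = r$r, p = r$p_value,
                                           stringsAsFactors = FALSE)
      }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    write_tsv(tab, file.path(out, "correlations.tsv"))
    tab
  })

  nbs <- stage("nbs", {
    res <- nbs_test(nets, meta$group, alpha_primary = cfg$alpha$primary,
                    n_perm = cfg$permutation$n_nbs,
                    alpha_report = cfg$alpha$nbs_report,
                    tail = cfg$tails$nbs,
                    seed = (cfg$seed + 307) %% 2147483647)
    comp_tab <- data.frame(
      component_id = seq_along(res$components),
      size = vapply(res$components, `[[`, integer(1), "size"),
      p_corrected = res$component_p_corrected,
      significant = res$significant)
    write_tsv(comp_tab, file.path(out, "nbs_components.tsv"))
    export_connectogram_links(res, node_table,
                              file.path(out, "nbs_links.tsv"))
    res
  })

  cls <- NULL
  if (isTRUE(cfg$run_classification)) {
    cls <- stage("classify", {
      feats <- as.matrix(auc_global[, c("Cp", "Lp", "Eglob", "Eloc")])
      fit <- loocv_svm(feats, meta$group, cost = cfg$svm$cost,
                       gamma = cfg$svm$gamma)
      perm <- accuracy_permutation_test(
        feats, meta$group, n_perm = cfg$permutation$n_classify,
        seed = (cfg$seed + 401) %% 2147483647,
        cost = cfg$svm$cost, gamma = cfg$svm$gamma)
      write_tsv(data.frame(subject_id = meta$subject_id,
                           group = meta$group,
                           prediction = fit$per_subject_prediction),
                file.path(out, "classification.tsv"))
      list(fit = fit, permutation_p = perm$p_value)
    })
  }

  cfg_echo <- cfg
  cfg_echo$output_dir <- NULL   # location-independent manifest
  manifest <- list(
    package = "sivconn",
    package_version = as.character(utils::packageVersion("sivconn")),
    seed = cfg$seed,
    config = cfg_echo,
    counts = list(
      n_subjects = nrow(meta),
      n_controls = sum(is_ctrl),
      n_patients = sum(!is_ctrl),
      n_nodes = n_nodes,
      n_sparsity_levels = length(curves_by_subject[[1]]$Cp$sparsities),
      n_global_metric_tests = nrow(stats_tab),
      n_edges_deconfound_floored =
        as.integer(attr(nets, "n_floored") %||% 0L),
      nbs_components = length(nbs$components),
      nbs_significant_edges = nbs$sig_edge_count),
    classification = if (!is.null(cls)) list(
      accuracy = cls$fit$accuracy, sensitivity = cls$fit$sensitivity,
      specificity = cls$fit$specificity,
      label_permutation_p = cls$permutation_p) else NULL)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(records = records, metadata = meta, networks = nets,
                 auc_global = auc_global, stats_global = stats_tab,
                 stats_nodal = nodal_tab, correlations = cor_tab,
                 nbs = nbs, classification = cls, manifest = manifest))
}
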