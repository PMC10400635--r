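#' Default end-to-end run configuration
#'
#' All thresholds default to the workflow's published operating point:
#' discovery filters 0.80 / 0.50 / 10-fold; grouping 5 ppm / 5 s;
#' product matching 5 ppm; MS2 linking 5 ppm / 10 s, purity 0.5,
#' 3 conserved substructures; co-response network R >= 0.75 at Holm
#' p < 0.05; dose-response network |rho| >= 0.9 at raw p < 0.05;
#' endogenous prefilters blank 20x / QC RSD 30% / missingness 50%/10%/50%
#' with kNN k = 5. Unknown keys in `overrides` are rejected so every
#' effective parameter is auditable.
#'
#' @param overrides named list of parameter overrides.
#' @return a `run_config` list.
#' @export
run_config <- function(overrides = list()) {
  cfg <- list(
    exposed_presence_min = 0.80, control_presence_max = 0.50,
    fold_min = 10,
    group_ppm_tol = 5, group_rt_tol = 5,
    match_ppm_tol = 5,
    ms2_ppm_tol = 5, ms2_rt_tol = 10, plim = 0.5, conserved_min = 3,
    max_steps = 3, max_phase2 = 1,
    pearson_r_min = 0.75, pearson_alpha = 0.05,
    spearman_rho_min = 0.9, spearman_alpha = 0.05,
    blank_fold_min = 20, qc_rsd_max = 0.30, sample_missing_max = 0.50,
    qc_missing_max = 0.10, feature_missing_max = 0.50, knn_k = 5,
    k_max = 8, kmeans_restarts = 20,
    parent_formula = "C22H27FN4O2",
    seed = 1)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys are [run_config()] parameters;
#'   unknown keys are rejected.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' Run the full untargeted ADME/TK workflow
#'
#' Chains the pipeline stages on a loaded peak matrix: discovery of
#' putative xenobiotic-related features, ion-form grouping,
#' biotransformation prediction and product matching, optional MS2
#' evidence, Pearson co-response network, temporal profiling and
#' clustering, endogenous split, prefiltering, PQN, exposure t-tests,
#' imputation + glog + PCA, and the Spearman dose-response network.
#' Every artifact is written under `out_dir` and listed in a manifest
#' with content hashes; the effective parameter set is logged.
#'
#' @param pm a `PeakMatrix`.
#' @param out_dir output directory (created if needed).
#' @param config a [run_config()].
#' @param ms2_library optional list of `ms2_spectrum` (the first
#'   spectrum matching the parent is used as the parent reference).
#' @return invisibly, a list with the stage results and the manifest
#'   data.frame (`artifact`, `path`, `md5`).
#' @export
run_workflow <- function(pm, out_dir, config = run_config(),
                         ms2_library = NULL) {
  stopifnot(inherits(pm, "PeakMatrix"), inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  artifacts <- list()
  put <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    artifacts[[name]] <<- path
  }
  log_lines <- c(sprintf("xenofate run %s", format(Sys.time())),
                 "effective parameters:",
                 sprintf("  %s = %s", names(config),
                         vapply(config, function(v)
                           paste(format(v), collapse = ","), "")))

  # 1. discovery
  disc <- xenobiotic_filter(pm, filter_config(
    config$exposed_presence_min, config$control_presence_max,
    config$fold_min))
  put("discovery_report.tsv", function(p)
    write.table(disc$report, p, sep = "\t", row.names = FALSE,
                quote = FALSE))
  # 2. grouping
  xeno_pm <- if (length(disc$ids)) {
    split_by_feature_ids(pm, disc$ids)$selected
  } else {
    NULL
  }
  groups <- if (!is.null(xeno_pm)) {
    group_features(xeno_pm, config$group_ppm_tol, config$group_rt_tol)
  } else {
    NULL
  }
  if (!is.null(groups)) {
    put("feature_groups.tsv", function(p)
      write.table(groups$members, p, sep = "\t", row.names = FALSE,
                  quote = FALSE))
  }
  # 3. biotransformation prediction + matching
  products <- enumerate_products(config$parent_formula,
                                 max_steps = config$max_steps,
                                 max_phase2 = config$max_phase2)
  put("predicted_products.tsv", function(p)
    write.table(products, p, sep = "\t", row.names = FALSE,
                quote = FALSE))
  annotations <- if (!is.null(groups)) {
    match_products(groups$summary, products,
                   parent = config$parent_formula,
                   ppm_tol = config$match_ppm_tol)
  } else {
    NULL
  }
  if (!is.null(annotations)) {
    put("annotations.tsv", function(p)
      write.table(annotations, p, sep = "\t", row.names = FALSE,
                  quote = FALSE))
  }
  # 4. MS2 evidence
  ms2_evidence <- NULL
  if (!is.null(ms2_library) && !is.null(annotations) &&
      nrow(annotations)) {
    ms2_evidence <- ms2_evidence_table(
      ms2_library, pm, groups, annotations,
      parent_formula = config$parent_formula,
      ppm_tol = config$ms2_ppm_tol, rt_tol = config$ms2_rt_tol,
      plim = config$plim, conserved_min = config$conserved_min)
    if (!is.null(ms2_evidence)) {
      put("ms2_evidence.tsv", function(p)
        write.table(ms2_evidence, p, sep = "\t", row.names = FALSE,
                    quote = FALSE))
    }
  }
  # 5. endogenous split + preprocessing + stats
  endo_split <- split_by_feature_ids(pm, disc$ids)
  pre <- prefilter(endo_split$remainder, disc$ids,
                   preprocess_config(config$blank_fold_min,
                                     config$qc_rsd_max,
                                     config$sample_missing_max,
                                     config$qc_missing_max,
                                     config$feature_missing_max,
                                     config$knn_k))
  put("prefilter_ledger.tsv", function(p)
    write.table(pre$ledger, p, sep = "\t", row.names = FALSE,
                quote = FALSE))
  put("endogenous_matrix.csv", function(p)
    write_peak_matrix(pre$matrix, p))
  norm <- pqn_normalise(pre$matrix)
  stats_tab <- exposure_tests(norm$matrix)
  put("endogenous_stats.tsv", function(p)
    write.table(stats_tab, p, sep = "\t", row.names = FALSE,
                quote = FALSE))
  imputed <- knn_impute(norm$matrix, k = config$knn_k)
  lam <- glog_lambda(
    imputed$intensity[, imputed$samples$class == "QC", drop = FALSE])
  glogged <- glog_transform(imputed$intensity, lam)
  pca <- pca_scores(glogged, n_components = 10)
  put("pca_scores.tsv", function(p)
    write.table(data.frame(sample_id = rownames(pca$scores),
                           pca$scores, check.names = FALSE),
                p, sep = "\t", row.names = FALSE, quote = FALSE))
  # 6. Pearson co-response network over xenobiotic features
  coresponse <- NULL
  if (!is.null(xeno_pm) && nrow(xeno_pm$features) >= 2) {
    xeno_norm <- sweep(
      xeno_pm$intensity[, match(colnames(norm$matrix$intensity),
                                colnames(xeno_pm$intensity)),
                        drop = FALSE],
      2, norm$coefficients, "/")
    cc <- pairwise_correlation(xeno_norm, "pearson")
    p_adj <- cc$p
    p_adj[upper.tri(p_adj)] <- holm_adjust(cc$p[upper.tri(cc$p)])
    p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
    coresponse <- build_network(cc$r, p_adj,
                                r_min = config$pearson_r_min,
                                alpha = config$pearson_alpha,
                                p_raw = cc$p)
    put("coresponse_edges.tsv", function(p)
      write_network(coresponse, p,
                    file.path(out_dir, "coresponse_nodes.tsv"),
                    file.path(out_dir, "coresponse.graphml")))
    artifacts[["coresponse_nodes.tsv"]] <-
      file.path(out_dir, "coresponse_nodes.tsv")
    artifacts[["coresponse.graphml"]] <-
      file.path(out_dir, "coresponse.graphml")
  }
  # 7. temporal clustering of parent + products
  temporal <- NULL
  if (!is.null(xeno_pm) &&
      any(!is.na(xeno_pm$samples$timepoint))) {
    prof <- profile_compounds(xeno_pm)
    if (nrow(prof$profiles) >= 4) {
      km <- elbow_kmeans(prof$profiles,
                         k_max = min(config$k_max,
                                     nrow(prof$profiles) - 1),
                         restarts = config$kmeans_restarts,
                         seed = config$seed)
      temporal <- km
      put("temporal_clusters.tsv", function(p)
        write.table(data.frame(feature_id = names(km$clusters),
                               cluster = km$clusters),
                    p, sep = "\t", row.names = FALSE, quote = FALSE))
      put("temporal_wss.tsv", function(p)
        write.table(km$wss, p, sep = "\t", row.names = FALSE,
                    quote = FALSE))
    }
  }
  # manifest
  manifest <- data.frame(
    artifact = names(artifacts),
    path = unlist(artifacts, use.names = FALSE),
    md5 = unname(tools::md5sum(unlist(artifacts, use.names = FALSE))),
    stringsAsFactors = FALSE)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(discovery = disc, groups = groups, products = products,
                 annotations = annotations, ms2_evidence = ms2_evidence,
                 prefilter = pre, stats = stats_tab, pca = pca,
                 coresponse = coresponse, temporal = temporal,
                 manifest = manifest))
}

# Align library spectra to annotated groups and score fragment-shift
# evidence against the parent spectrum.
ms2_evidence_table <- function(ms2_library, pm, groups, annotations,
                               parent_formula, ppm_tol, rt_tol, plim,
                               conserved_min) {
  spectra <- purity_filter(ms2_library, plim)
  if (!length(spectra)) return(NULL)
  parent_mass <- monoisotopic_mass(parent_formula)
  mh <- ion_rules("positive")
  mh <- mh[mh$name == "[M+H]+", ]
  parent_mz <- ion_mz(parent_mass, mh)
  prec <- vapply(spectra, function(s) s$precursor_mz, numeric(1))
  pi <- which(abs(prec - parent_mz) / parent_mz * 1e6 <= ppm_tol)
  if (!length(pi)) return(NULL)
  parent_spec <- spectra[[pi[1]]]
  links <- link_spectra_to_features(spectra, pm, ppm_tol, rt_tol)
  if (!nrow(links)) return(NULL)
  out <- lapply(seq_len(nrow(annotations)), function(a) {
    gid <- annotations$group_id[a]
    members <- groups$members$feature_id[groups$members$group_id == gid]
    si <- links$spectrum_index[links$feature_id %in% members]
    if (!length(si)) return(NULL)
    delta <- annotations$neutral_mass[a] *
      (1 + annotations$ppm_error[a] / 1e6) - parent_mass
    ev <- align_to_parent(spectra[[si[1]]], parent_spec, delta,
                          ppm_tol, conserved_min)
    data.frame(group_id = gid, formula = annotations$formula[a],
               n_conserved = ev$n_conserved, n_shifted = ev$n_shifted,
               related = ev$related, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out
}
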