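#' Configuration for endogenous prefiltering and preprocessing
#'
#' Defaults are the standard quality thresholds of the workflow: a
#' feature is kept only if its biological median is at least 20x its
#' blank median; features with QC relative standard deviation >= 30% are
#' removed; samples with more than 50% missing values are removed;
#' features missing in >= 10% of QCs or >= 50% of all samples are
#' removed; kNN imputation uses k = 5.
#'
#' @param blank_fold_min minimum biological/blank median ratio (20).
#' @param qc_rsd_max maximum QC relative standard deviation (0.30).
#' @param sample_missing_max maximum fraction missing per sample (0.50).
#' @param qc_missing_max maximum fraction of QCs a feature may be
#'   missing in (0.10).
#' @param feature_missing_max maximum fraction of all samples a feature
#'   may be missing in (0.50).
#' @param knn_k neighbours for kNN imputation (5).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(blank_fold_min = 20, qc_rsd_max = 0.30,
                              sample_missing_max = 0.50,
                              qc_missing_max = 0.10,
                              feature_missing_max = 0.50, knn_k = 5) {
  stopifnot(blank_fold_min > 0, qc_rsd_max > 0, qc_rsd_max <= 1,
            sample_missing_max > 0, sample_missing_max <= 1,
            qc_missing_max > 0, qc_missing_max <= 1,
            feature_missing_max > 0, feature_missing_max <= 1,
            knn_k >= 1)
  structure(list(blank_fold_min = blank_fold_min, qc_rsd_max = qc_rsd_max,
                 sample_missing_max = sample_missing_max,
                 qc_missing_max = qc_missing_max,
                 feature_missing_max = feature_missing_max,
                 knn_k = as.integer(knn_k)),
            class = "preprocess_config")
}

#' Prefilter a peak matrix for endogenous analysis
#'
#' Applies, in order: blank filter (feature removed when its biological
#' median is below `blank_fold_min` times its blank median; skipped with
#' a warning when the matrix has no blanks), QC-RSD filter, sample
#' missingness filter (drops sample columns), feature missingness
#' filters (QC and overall), and removal of the putative
#' xenobiotic-related features. Returns the filtered matrix plus a
#' removal ledger.
#'
#' @param pm a `PeakMatrix` containing QC samples.
#' @param xeno_ids feature ids flagged as xenobiotic-related.
#' @param config a [preprocess_config()].
#' @return list with `matrix` (filtered `PeakMatrix`), `ledger`
#'   (data.frame of rule, n_removed) and `removed` (named list of ids
#'   per rule).
#' @export
prefilter <- function(pm, xeno_ids = character(0),
                      config = preprocess_config()) {
  stopifnot(inherits(pm, "PeakMatrix"))
  if (!any(pm$samples$class == "QC")) stop("no QC samples in matrix")
  removed <- list()
  cur <- pm
  row_median <- function(m) apply(m, 1, function(v) {
    if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  })
  drop_features <- function(pm, drop) {
    suppressWarnings(
      peak_matrix(pm$intensity[!drop, , drop = FALSE],
                  pm$features[!drop, , drop = FALSE], pm$samples))
  }
  bio <- cur$samples$class %in% c("exposed", "control")
  # 1. blank filter
  if (any(cur$samples$class == "blank")) {
    med_bio <- row_median(cur$intensity[, bio, drop = FALSE])
    med_blk <- row_median(
      cur$intensity[, cur$samples$class == "blank", drop = FALSE])
    drop <- !is.na(med_blk) &
      (is.na(med_bio) | med_bio < config$blank_fold_min * med_blk)
    removed$blank <- cur$features$feature_id[drop]
    cur <- drop_features(cur, drop)
  } else {
    warning("no blank samples: blank filter skipped")
    removed$blank <- character(0)
  }
  # 2. QC RSD filter
  qc <- cur$intensity[, cur$samples$class == "QC", drop = FALSE]
  rsd <- apply(qc, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    sd(v) / mean(v)
  })
  drop <- !is.na(rsd) & rsd >= config$qc_rsd_max
  removed$qc_rsd <- cur$features$feature_id[drop]
  cur <- drop_features(cur, drop)
  # 3. sample missingness filter (drops columns)
  miss_s <- colMeans(is.na(cur$intensity))
  drop_s <- miss_s > config$sample_missing_max
  removed$sample_missing <- cur$samples$sample_id[drop_s]
  if (any(drop_s)) {
    cur <- suppressWarnings(
      peak_matrix(cur$intensity[, !drop_s, drop = FALSE], cur$features,
                  cur$samples[!drop_s, , drop = FALSE]))
  }
  # 4. feature missingness filters (QC and overall)
  qc_cols <- cur$samples$class == "QC"
  miss_qc <- rowMeans(is.na(cur$intensity[, qc_cols, drop = FALSE]))
  miss_all <- rowMeans(is.na(cur$intensity))
  drop <- miss_qc >= config$qc_missing_max |
    miss_all >= config$feature_missing_max
  removed$feature_missing <- cur$features$feature_id[drop]
  cur <- drop_features(cur, drop)
  # 5. xenobiotic-related features
  drop <- cur$features$feature_id %in% xeno_ids
  removed$xenobiotic <- cur$features$feature_id[drop]
  cur <- drop_features(cur, drop)
  ledger <- data.frame(
    rule = c("blank", "qc_rsd", "sample_missing", "feature_missing",
             "xenobiotic"),
    n_removed = vapply(removed[c("blank", "qc_rsd", "sample_missing",
                                 "feature_missing", "xenobiotic")],
                       length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(matrix = cur, ledger = ledger, removed = removed)
}

#' Probabilistic quotient normalisation
#'
#' Per sample, the dilution coefficient is the median over
#' `coefficient_source` features of sample/reference intensity
#' quotients; every intensity of the sample is divided by it. The
#' reference defaults to the median QC profile. Coefficients may be
#' computed on one feature subset (e.g. the endogenous features) and
#' applied to the whole matrix, so xenobiotic features are scaled by the
#' endogenous dilution estimate.
#'
#' @param pm a `PeakMatrix`, or a plain features x samples matrix.
#' @param reference reference profile (numeric vector over features);
#'   default median QC profile (requires a `PeakMatrix` with QCs).
#' @param coefficient_source feature ids (or row indices) used to
#'   compute the coefficients; default all features.
#' @return list with `matrix` (normalised, same shape) and
#'   `coefficients` (per sample).
#' @export
pqn_normalise <- function(pm, reference = NULL,
                          coefficient_source = NULL) {
  x <- if (inherits(pm, "PeakMatrix")) pm$intensity else as.matrix(pm)
  if (is.null(reference)) {
    if (!inherits(pm, "PeakMatrix") || !any(pm$samples$class == "QC")) {
      stop("no reference supplied and no QC samples to build one")
    }
    reference <- apply(
      x[, pm$samples$class == "QC", drop = FALSE], 1, median,
      na.rm = TRUE)
  }
  if (all(is.na(reference))) stop("reference profile is entirely missing")
  src <- if (is.null(coefficient_source)) {
    seq_len(nrow(x))
  } else if (is.character(coefficient_source)) {
    match(coefficient_source, rownames(x))
  } else {
    coefficient_source
  }
  coefs <- vapply(seq_len(ncol(x)), function(j) {
    q <- x[src, j] / reference[src]
    q <- q[is.finite(q)]
    if (!length(q)) stop("sample ", colnames(x)[j],
                         " has no usable quotients (all missing?)")
    median(q)
  }, numeric(1))
  out <- sweep(x, 2, coefs, "/")
  if (inherits(pm, "PeakMatrix")) {
    pm$intensity <- out
    out <- pm
  }
  list(matrix = out, coefficients = setNames(coefs, colnames(x)))
}

#' k-nearest-neighbour imputation of missing intensities
#'
#' Feature-wise kNN: for each missing cell, the k features nearest to the
#' target feature (Euclidean distance on rows standardised to unit
#' variance, computed over shared-present samples and scaled to the
#' number of shared columns) that are observed in that sample contribute
#' the average of their observed values. Ties are broken by feature
#' order, so the result is deterministic.
#'
#' @param x features x samples matrix (or `PeakMatrix`) with `NA`s; no
#'   feature may be entirely missing.
#' @param k number of neighbours (default 5).
#' @return completed matrix (or `PeakMatrix`).
#' @export
knn_impute <- function(x, k = 5) {
  pm <- NULL
  if (inherits(x, "PeakMatrix")) {
    pm <- x
    x <- x$intensity
  }
  x <- as.matrix(x)
  if (any(rowSums(!is.na(x)) == 0)) {
    stop("feature(s) with zero observed values cannot be imputed: ",
         paste(rownames(x)[rowSums(!is.na(x)) == 0], collapse = ", "))
  }
  if (!anyNA(x)) {
    if (!is.null(pm)) { pm$intensity <- x; return(pm) }
    return(x)
  }
  rs <- apply(x, 1, sd, na.rm = TRUE)
  rs[is.na(rs) | rs == 0] <- 1
  z <- x / rs
  out <- x
  need <- which(rowSums(is.na(x)) > 0)
  for (i in need) {
    # scaled Euclidean distance to every other feature on shared columns
    diffs <- sweep(z, 2, z[i, ], "-")^2
    shared <- rowSums(!is.na(diffs))
    d <- sqrt(rowMeans(diffs, na.rm = TRUE))
    d[i] <- Inf
    d[shared == 0] <- Inf
    miss_cols <- which(is.na(x[i, ]))
    for (j in miss_cols) {
      cand <- which(!is.na(x[, j]) & is.finite(d))
      if (!length(cand)) next
      cand <- cand[order(d[cand], cand)]
      nb <- cand[seq_len(min(k, length(cand)))]
      out[i, j] <- mean(x[nb, j])
    }
  }
  if (anyNA(out)) {
    # fall back to the feature mean for cells with no usable neighbour
    fm <- rowMeans(x, na.rm = TRUE)
    idx <- which(is.na(out), arr.ind = TRUE)
    out[idx] <- fm[idx[, 1]]
  }
  if (!is.null(pm)) { pm$intensity <- out; return(pm) }
  out
}

#' Generalised logarithm transform
#'
#' `y = ln((x + sqrt(x^2 + lambda)) / 2)`: behaves like `ln(x)` for
#' large intensities and stays finite at zero, stabilising the variance
#' across the intensity range. `lambda` can be tuned on QC replicates
#' with [glog_lambda()].
#'
#' @param x numeric matrix/vector of non-negative intensities.
#' @param lambda transform parameter (> 0).
#' @return transformed values, same shape.
#' @export
glog_transform <- function(x, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0) {
    stop("lambda must be a positive number")
  }
  log((x + sqrt(x^2 + lambda)) / 2)
}

#' Tune the glog lambda on QC replicates
#'
#' Grid search over lambda choosing the value that most nearly equalises
#' the technical (across-QC) variances across features after the
#' transform — i.e. the variance-stabilisation criterion: minimise the
#' variance of log feature-wise QC variances.
#'
#' @param qc features x QC-replicates matrix, complete.
#' @param grid candidate lambda values (default logarithmic grid spanning
#'   the squared intensity range).
#' @return the selected lambda.
#' @export
glog_lambda <- function(qc, grid = NULL) {
  qc <- as.matrix(qc)
  if (is.null(grid)) {
    top <- max(qc, na.rm = TRUE)^2
    grid <- 10^seq(log10(max(top * 1e-12, 1e-6)), log10(top),
                   length.out = 25)
  }
  objective <- vapply(grid, function(lam) {
    v <- apply(glog_transform(qc, lam), 1, var)
    v <- v[is.finite(v) & v > 0]
    if (!length(v)) return(Inf)
    var(log(v))
  }, numeric(1))
  grid[which.min(objective)]
}

#' Per-feature exposure tests (t-test, fold change, BH q-values)
#'
#' Two-sample two-tailed Student's t-test (pooled variance) of exposed
#' vs control per feature, on (typically PQN-normalised) intensities;
#' fold change is the ratio of class medians; q-values by
#' Benjamini-Hochberg.
#'
#' @param pm a `PeakMatrix` (or matrix plus `classes`).
#' @param classes optional character vector of per-sample classes when
#'   `pm` is a plain matrix.
#' @return data.frame `feature_id`, `fold_change`, `p`, `q`.
#' @export
exposure_tests <- function(pm, classes = NULL) {
  if (inherits(pm, "PeakMatrix")) {
    x <- pm$intensity
    classes <- pm$samples$class
    ids <- pm$features$feature_id
  } else {
    x <- as.matrix(pm)
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("F", seq_len(nrow(x)))
  }
  e <- x[, classes == "exposed", drop = FALSE]
  c_ <- x[, classes == "control", drop = FALSE]
  if (ncol(e) < 2 || ncol(c_) < 2) {
    stop("need at least 2 exposed and 2 control samples")
  }
  res <- t(vapply(seq_len(nrow(x)), function(i) {
    ev <- e[i, ][!is.na(e[i, ])]
    cv <- c_[i, ][!is.na(c_[i, ])]
    fold <- median(ev) / median(cv)
    p <- tryCatch(
      t.test(ev, cv, var.equal = TRUE)$p.value,
      error = function(e) NA_real_)
    c(fold, p)
  }, numeric(2)))
  out <- data.frame(feature_id = ids, fold_change = res[, 1],
                    p = res[, 2], stringsAsFactors = FALSE)
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Principal components analysis with a fixed sign convention
#'
#' SVD-based PCA of a complete (typically glog-transformed) matrix,
#' treating samples as observations; columns are mean-centred. For
#' determinism each component is flipped so its largest-magnitude
#' loading is positive.
#'
#' @param x features x samples matrix (complete) or `PeakMatrix`.
#' @param n_components number of components to return (default all).
#' @return list with `scores` (samples x PCs), `loadings`
#'   (features x PCs), `explained` (variance fractions), `center`.
#' @export
pca_scores <- function(x, n_components = NULL) {
  if (inherits(x, "PeakMatrix")) x <- x$intensity
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 samples for PCA")
  if (anyNA(x)) stop("PCA requires a complete matrix (impute first)")
  fit <- prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- if (is.null(n_components)) ncol(fit$rotation) else
    min(n_components, ncol(fit$rotation))
  load <- fit$rotation[, seq_len(k), drop = FALSE]
  scores <- fit$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    m <- which.max(abs(load[, j]))
    if (load[m, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = load,
       explained = (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)],
       center = fit$center)
}
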