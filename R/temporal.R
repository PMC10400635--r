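#' Median time profiles of compounds, scaled to unit variance
#'
#' For each compound (feature), the median intensity across exposed
#' biological replicates is computed at every timepoint, then the
#' profile is centred and scaled to unit variance. Compounds with a
#' constant raw profile cannot be scaled and are flagged (excluded from
#' clustering); a timepoint where a compound is missing in every
#' replicate yields a missing median and also flags the compound.
#'
#' @param pm a `PeakMatrix` whose samples carry `timepoint` labels.
#' @param compound_ids feature ids to profile (default all).
#' @param timepoints ordered vector of timepoint labels (default the
#'   order of first appearance among exposed samples).
#' @param classes sample classes treated as biological replicates
#'   (default `"exposed"`).
#' @return list with `profiles` (compounds x timepoints matrix of scaled
#'   profiles, flagged compounds dropped), `medians` (raw medians for
#'   all requested compounds) and `flagged` (ids excluded and why).
#' @export
profile_compounds <- function(pm, compound_ids = NULL, timepoints = NULL,
                              classes = "exposed") {
  stopifnot(inherits(pm, "PeakMatrix"))
  if (is.null(compound_ids)) compound_ids <- pm$features$feature_id
  use <- pm$samples$class %in% classes & !is.na(pm$samples$timepoint)
  if (!any(use)) stop("no samples of the requested classes with timepoints")
  tp_all <- pm$samples$timepoint[use]
  if (is.null(timepoints)) timepoints <- unique(tp_all)
  idx <- match(compound_ids, pm$features$feature_id)
  if (anyNA(idx)) {
    stop("unknown compound id(s): ",
         paste(compound_ids[is.na(idx)], collapse = ", "))
  }
  x <- pm$intensity[idx, use, drop = FALSE]
  med <- sapply(timepoints, function(tp) {
    cols <- tp_all == tp
    if (!any(cols)) stop("no replicates at timepoint ", tp)
    apply(x[, cols, drop = FALSE], 1, function(v) {
      if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
    })
  })
  med <- matrix(med, nrow = length(compound_ids),
                dimnames = list(compound_ids, timepoints))
  sds <- apply(med, 1, sd)
  flagged <- data.frame(
    feature_id = character(0), reason = character(0),
    stringsAsFactors = FALSE)
  has_na <- rowSums(is.na(med)) > 0
  constant <- !has_na & (is.na(sds) | sds == 0)
  if (any(has_na)) {
    flagged <- rbind(flagged, data.frame(
      feature_id = compound_ids[has_na], reason = "missing timepoint",
      stringsAsFactors = FALSE))
  }
  if (any(constant)) {
    flagged <- rbind(flagged, data.frame(
      feature_id = compound_ids[constant], reason = "constant profile",
      stringsAsFactors = FALSE))
  }
  keep <- !has_na & !constant
  scaled <- t(scale(t(med[keep, , drop = FALSE])))
  dimnames(scaled) <- list(compound_ids[keep], timepoints)
  list(profiles = scaled, medians = med, flagged = flagged)
}

#' k-means clustering of time profiles with automated elbow selection
#'
#' Runs Lloyd's k-means with `restarts` random initialisations for each
#' k up to `k_max`, keeps the best within-cluster sum of squares (WSS)
#' per k, and selects k at the maximum second difference of the
#' log-WSS curve — the automated analogue of reading an elbow plot.
#' Working on the log scale makes the rule sensitive to where the
#' \emph{relative} decrease of WSS flattens; the raw-scale second
#' difference is dominated by the always-large k = 1 to 2 drop. The full
#' WSS curve is returned so the choice can be inspected or overridden
#' with `k`.
#'
#' @param profiles compounds x timepoints matrix of scaled profiles.
#' @param k_max largest k to evaluate (>= 2).
#' @param restarts random restarts per k (default 20).
#' @param seed random seed for initialisation (required for
#'   reproducibility).
#' @param k optional override of the automated choice.
#' @return list with `k` (chosen), `clusters` (named assignment vector),
#'   `centers`, `wss` (curve over k = 1..k_max), `k_elbow` (automated
#'   choice).
#' @export
elbow_kmeans <- function(profiles, k_max = 8, restarts = 20, seed,
                         k = NULL) {
  if (k_max < 2) stop("k_max must be at least 2")
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < k_max + 1) {
    stop("need at least k_max + 1 profiles")
  }
  if (missing(seed)) stop("seed is required for reproducible clustering")
  set.seed(seed)
  fits <- lapply(seq_len(k_max), function(kk) {
    suppressWarnings(
      kmeans(profiles, centers = kk, nstart = restarts, iter.max = 100,
             algorithm = "Lloyd"))
  })
  wss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  k_elbow <- if (k_max >= 3) {
    lw <- log(pmax(wss, max(wss) * 1e-12))
    d2 <- lw[1:(k_max - 2)] - 2 * lw[2:(k_max - 1)] + lw[3:k_max]
    which.max(d2) + 1L
  } else {
    2L
  }
  k_use <- if (is.null(k)) k_elbow else as.integer(k)
  fit <- fits[[k_use]]
  list(k = k_use, clusters = setNames(fit$cluster, rownames(profiles)),
       centers = fit$centers,
       wss = data.frame(k = seq_len(k_max), wss = wss),
       k_elbow = k_elbow)
}

#' One-way ANOVA across timepoints with Tukey HSD post-hoc
#'
#' Tests whether a compound's intensity differs across timepoints, and
#' which timepoint pairs differ, using the studentised-range Tukey
#' honestly-significant-difference test. Timepoints with fewer than 2
#' observations are excluded with a warning.
#'
#' @param values named list: one numeric vector of replicate intensities
#'   per timepoint.
#' @return list with `f`, `p` (ANOVA) and `tukey` (data.frame of pair,
#'   diff, p_adj).
#' @export
timepoint_anova <- function(values) {
  sizes <- vapply(values, length, integer(1))
  if (any(sizes < 2)) {
    warning("excluding timepoint(s) with < 2 observations: ",
            paste(names(values)[sizes < 2], collapse = ", "))
    values <- values[sizes >= 2]
  }
  if (length(values) < 2) stop("need at least 2 timepoints with >= 2 obs")
  df <- data.frame(
    y = unlist(values, use.names = FALSE),
    g = factor(rep(names(values), vapply(values, length, integer(1))),
               levels = names(values)))
  fit <- aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  list(f = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"],
                          stringsAsFactors = FALSE, row.names = NULL))
}
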