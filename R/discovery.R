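#' Configuration for the three xenobiotic-feature intensity filters
#'
#' The defaults encode the workflow's filter thresholds: a feature must be
#' present in at least 80% of exposed biological samples, in at most 50%
#' of biological control samples, and show a >= 10-fold ratio of exposed
#' to control median intensity. For human suspect-screening datasets a
#' 50% exposed-presence threshold is the published configuration
#' (`exposed_presence_min = 0.5`).
#'
#' @param exposed_presence_min minimum fraction of exposed samples in
#'   which the feature is detected (default 0.80).
#' @param control_presence_max maximum fraction of control samples in
#'   which the feature is detected (default 0.50).
#' @param fold_min minimum ratio of exposed to control median intensity
#'   (default 10).
#' @return a `filter_config` list.
#' @export
filter_config <- function(exposed_presence_min = 0.80,
                          control_presence_max = 0.50,
                          fold_min = 10) {
  stopifnot(exposed_presence_min > 0, exposed_presence_min <= 1,
            control_presence_max > 0, control_presence_max <= 1,
            fold_min > 1)
  structure(list(exposed_presence_min = exposed_presence_min,
                 control_presence_max = control_presence_max,
                 fold_min = fold_min),
            class = "filter_config")
}

#' Fraction of non-missing values in a vector
#'
#' Detection ("presence") of a feature in a sample means a non-missing
#' intensity; this returns the detected fraction of a vector.
#'
#' @param values numeric vector, `NA` = not detected.
#' @return fraction in \[0, 1\].
#' @export
presence_fraction <- function(values) {
  if (length(values) == 0) stop("empty vector")
  mean(!is.na(values))
}

#' Isolate putative xenobiotic-related features
#'
#' Applies the three intensity-based filters to the exposed and biological
#' control columns of a peak matrix (QC and blank columns are ignored):
#' \enumerate{
#'   \item presence among exposed samples >= `exposed_presence_min`;
#'   \item presence among control samples <= `control_presence_max`;
#'   \item median(exposed) / median(control) >= `fold_min`, medians over
#'     non-missing values only. A feature never detected in controls has
#'     an infinite fold change and passes filter 3 — for a true
#'     xenobiotic the fold change is infinite in principle.
#' }
#'
#' @param pm a `PeakMatrix` with at least one exposed and one control
#'   sample.
#' @param config a [filter_config()].
#' @return list with `ids` (character vector of features passing all
#'   three filters) and `report` (per-feature data.frame of
#'   `presence_exposed`, `presence_control`, `fold_change` and pass
#'   flags).
#' @export
xenobiotic_filter <- function(pm, config = filter_config()) {
  stopifnot(inherits(pm, "PeakMatrix"), inherits(config, "filter_config"))
  exp_cols <- pm$samples$class == "exposed"
  ctl_cols <- pm$samples$class == "control"
  if (!any(exp_cols)) stop("no exposed samples in matrix")
  if (!any(ctl_cols)) stop("no control samples in matrix")
  xe <- pm$intensity[, exp_cols, drop = FALSE]
  xc <- pm$intensity[, ctl_cols, drop = FALSE]
  pres_e <- rowMeans(!is.na(xe))
  pres_c <- rowMeans(!is.na(xc))
  med_e <- apply(xe, 1, median, na.rm = TRUE)
  med_c <- apply(xc, 1, median, na.rm = TRUE)
  fold <- ifelse(is.na(med_c), Inf,
                 ifelse(is.na(med_e), 0, med_e / med_c))
  p1 <- pres_e >= config$exposed_presence_min
  p2 <- pres_c <= config$control_presence_max
  p3 <- fold >= config$fold_min
  passed <- p1 & p2 & p3
  report <- data.frame(
    feature_id = pm$features$feature_id,
    mz = pm$features$mz, rt = pm$features$rt,
    presence_exposed = pres_e, presence_control = pres_c,
    fold_change = fold,
    passed_presence_exposed = p1, passed_presence_control = p2,
    passed_fold = p3, passed = passed,
    stringsAsFactors = FALSE, row.names = NULL)
  list(ids = pm$features$feature_id[passed], report = report)
}

#' Label samples as exposed or control from a suspect feature
#'
#' For suspect screening with unknown exposures, a sample is labelled
#' exposed to a suspect when the intensity of the suspect's representative
#' feature exceeds `fold` times the median intensity of that feature
#' across all biological samples and QCs, after imputing missing values
#' of the feature with the lowest measured intensity across the whole
#' matrix.
#'
#' @param pm a `PeakMatrix`.
#' @param suspect_feature_id the representative feature of the suspect.
#' @param fold exposure threshold on the ratio to the median (default 10).
#' @return named character vector (`"exposed"`/`"control"`) over the
#'   biological + QC samples.
#' @export
label_exposure_by_suspect <- function(pm, suspect_feature_id, fold = 10) {
  stopifnot(inherits(pm, "PeakMatrix"))
  i <- match(suspect_feature_id, pm$features$feature_id)
  if (is.na(i)) stop("feature not in matrix: ", suspect_feature_id)
  use <- pm$samples$class %in% c("exposed", "control", "QC")
  v <- pm$intensity[i, use]
  global_min <- suppressWarnings(min(pm$intensity, na.rm = TRUE))
  if (!is.finite(global_min)) stop("matrix has no measured intensities")
  v[is.na(v)] <- global_min
  m <- median(v)
  labels <- ifelse(v > fold * m, "exposed", "control")
  names(labels) <- pm$samples$sample_id[use]
  labels
}

#' Assign a Schymanski-style identification confidence level
#'
#' Level 1: accurate mass plus retention time and MS2 match to an
#' authentic standard. Level 2: accurate mass plus MS2 match to a
#' database or in-silico annotated spectrum (no standard). Level 3:
#' accurate mass match to a suspect or predicted structure only.
#' Level 4: unequivocal molecular formula only. A mass match is a
#' prerequisite for any annotation.
#'
#' @param mz_match accurate m/z matches a theoretical m/z.
#' @param rt_standard_match retention time matches an authentic standard.
#' @param ms2_standard_match MS2 spectrum matches an authentic standard.
#' @param ms2_insilico_or_db_match MS2 matches an in-silico annotation or
#'   public spectral database record.
#' @param formula_only the candidate is a molecular formula without a
#'   proposed structure.
#' @return integer level in 1..4.
#' @export
assign_confidence <- function(mz_match,
                              rt_standard_match = FALSE,
                              ms2_standard_match = FALSE,
                              ms2_insilico_or_db_match = FALSE,
                              formula_only = FALSE) {
  if (!isTRUE(mz_match)) stop("no annotation without an accurate mass match")
  if (isTRUE(rt_standard_match) && isTRUE(ms2_standard_match)) return(1L)
  if (isTRUE(ms2_insilico_or_db_match)) return(2L)
  if (isTRUE(formula_only)) return(4L)
  3L
}
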