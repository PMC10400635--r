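#' @importFrom stats median sd var aov TukeyHSD kmeans prcomp t.test p.adjust
#'   phyper pt complete.cases setNames quantile cor rnorm rlnorm runif
#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

SAMPLE_CLASSES <- c("exposed", "control", "QC", "blank")

#' Construct a peak matrix
#'
#' A `PeakMatrix` bundles a feature x sample intensity matrix with feature
#' annotation (m/z, retention time) and sample metadata (class, subject,
#' timepoint). Missing intensities (non-detections) are stored as `NA`;
#' input zeros are treated as missing because XCMS-style matrices encode
#' non-detection as 0 or as an empty cell interchangeably.
#'
#' @param intensity numeric matrix, features in rows, samples in columns.
#'   Zeros are converted to `NA`.
#' @param features data.frame with columns `feature_id`, `mz` (Da, > 0),
#'   `rt` (seconds, >= 0) and optionally `assay`. If `feature_id` is
#'   missing, deterministic ids of the form `M<mz>T<rt>` are built.
#' @param samples data.frame with columns `sample_id`, `class` (one of
#'   `"exposed"`, `"control"`, `"QC"`, `"blank"`) and optionally
#'   `subject`, `timepoint`, `assay`.
#' @return an object of class `PeakMatrix`.
#' @export
peak_matrix <- function(intensity, features, samples) {
  intensity <- as.matrix(intensity)
  mode(intensity) <- "numeric"
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(features$feature_id)) {
    features$feature_id <- make_feature_ids(features$mz, features$rt)
  }
  features$feature_id <- as.character(features$feature_id)
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature_id values: ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]),
               collapse = ", "))
  }
  if (any(!is.finite(features$mz)) || any(features$mz <= 0)) {
    stop("feature m/z values must be positive")
  }
  if (any(!is.finite(features$rt)) || any(features$rt < 0)) {
    stop("feature retention times must be non-negative")
  }
  if (is.null(features$assay)) features$assay <- NA_character_
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id values")
  if (!all(samples$class %in% SAMPLE_CLASSES)) {
    bad <- setdiff(unique(samples$class), SAMPLE_CLASSES)
    stop("unknown sample class(es): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(SAMPLE_CLASSES, collapse = ", "), ")")
  }
  for (col in c("subject", "timepoint", "assay")) {
    if (is.null(samples[[col]])) samples[[col]] <- NA_character_
  }
  if (nrow(intensity) != nrow(features)) {
    stop("intensity has ", nrow(intensity), " rows but ", nrow(features),
         " features are described")
  }
  if (ncol(intensity) != nrow(samples)) {
    stop("intensity has ", ncol(intensity), " columns but ", nrow(samples),
         " samples are described")
  }
  intensity[!is.na(intensity) & intensity == 0] <- NA_real_
  if (any(intensity < 0, na.rm = TRUE)) stop("negative intensities found")
  dimnames(intensity) <- list(features$feature_id, samples$sample_id)
  if (ncol(intensity) > 0 && nrow(intensity) > 0) {
    empty <- colSums(!is.na(intensity)) == 0
    if (any(empty)) {
      warning("sample column(s) entirely missing: ",
              paste(samples$sample_id[empty], collapse = ", "))
    }
  }
  structure(list(intensity = intensity, features = features,
                 samples = samples),
            class = "PeakMatrix")
}

make_feature_ids <- function(mz, rt) {
  ids <- sprintf("M%.4fT%.1f", mz, rt)
  if (anyDuplicated(ids)) {
    dup <- duplicated(ids) | duplicated(ids, fromLast = TRUE)
    ids[dup] <- paste0(ids[dup], "_", seq_len(sum(dup)))
  }
  ids
}

#' @export
print.PeakMatrix <- function(x, ...) {
  cat("PeakMatrix:", nrow(x$features), "features x",
      nrow(x$samples), "samples\n")
  cat("  classes:",
      paste(sprintf("%s=%d", names(table(x$samples$class)),
                    table(x$samples$class)), collapse = ", "), "\n")
  cat("  missing:",
      sprintf("%.1f%%", 100 * mean(is.na(x$intensity))), "\n")
  invisible(x)
}

#' @export
dim.PeakMatrix <- function(x) dim(x$intensity)

#' Read a peak matrix and its sample metadata from delimited text
#'
#' The peak matrix file carries one row per feature with columns
#' `feature_id`, `mz`, `rt` followed by one column per sample; CSV or TSV
#' is auto-detected from the file extension. The metadata file is a CSV
#' with columns `sample_id`, `class`, and optionally `subject`,
#' `timepoint`, `assay`; it must cover every sample column of the matrix.
#' Zeros and empty cells become `NA` (missing).
#'
#' @param path peak matrix file.
#' @param metadata_path sample metadata CSV.
#' @return a [peak_matrix()] object.
#' @export
read_peak_matrix <- function(path, metadata_path) {
  if (!file.exists(path)) stop("peak matrix file not found: ", path)
  if (!file.exists(metadata_path)) {
    stop("metadata file not found: ", metadata_path)
  }
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.delim(path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("feature_id", "mz", "rt")
  if (!all(need %in% names(raw)[1:3])) {
    stop("first three columns must be feature_id, mz, rt; got: ",
         paste(names(raw)[1:3], collapse = ", "))
  }
  sample_cols <- setdiff(names(raw), c(need, "assay"))
  meta <- read.csv(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(meta))) {
    stop("metadata must have sample_id and class columns")
  }
  missing_meta <- setdiff(sample_cols, meta$sample_id)
  if (length(missing_meta)) {
    stop("metadata lacks entries for sample column(s): ",
         paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(sample_cols, meta$sample_id), , drop = FALSE]
  intens <- raw[, sample_cols, drop = FALSE]
  for (j in seq_along(intens)) {
    v <- intens[[j]]
    if (is.character(v)) {
      v[v == ""] <- NA
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("non-numeric intensity at row %d, column '%s': '%s'",
                     bad[1], sample_cols[j], v[bad[1]]))
      }
      v <- vn
    }
    intens[[j]] <- v
  }
  feat <- raw[, intersect(names(raw), c(need, "assay")), drop = FALSE]
  peak_matrix(as.matrix(intens), feat, meta)
}

#' Write a peak matrix (and optionally its metadata) to delimited text
#'
#' Inverse of [read_peak_matrix()]: missing values are written as empty
#' cells so that read-write-read round-trips values and missingness.
#'
#' @param pm a `PeakMatrix`.
#' @param path output matrix file (CSV or TSV by extension).
#' @param metadata_path optional output metadata CSV.
#' @export
write_peak_matrix <- function(pm, path, metadata_path = NULL) {
  stopifnot(inherits(pm, "PeakMatrix"))
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  out <- data.frame(feature_id = pm$features$feature_id,
                    mz = pm$features$mz, rt = pm$features$rt,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pm$intensity, check.names = FALSE))
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
              na = "")
  if (!is.null(metadata_path)) {
    write.csv(pm$samples, metadata_path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Restrict a peak matrix to samples of given classes
#'
#' @param pm a `PeakMatrix`.
#' @param classes character vector of class labels to keep.
#' @return a `PeakMatrix` with the same features and only the matching
#'   sample columns.
#' @export
subset_classes <- function(pm, classes) {
  stopifnot(inherits(pm, "PeakMatrix"), length(classes) > 0)
  keep <- pm$samples$class %in% classes
  if (!any(keep)) {
    stop("no samples of class(es): ", paste(classes, collapse = ", "))
  }
  suppressWarnings(
    peak_matrix(pm$intensity[, keep, drop = FALSE], pm$features,
                pm$samples[keep, , drop = FALSE])
  )
}

#' Partition a peak matrix by feature ids
#'
#' Splits the matrix into the features listed in `ids` (e.g. putative
#' xenobiotic-related features) and the complement (the endogenous
#' matrix), preserving sample columns in both.
#'
#' @param pm a `PeakMatrix`.
#' @param ids character vector of feature ids; must all be present.
#' @return a list with elements `selected` and `remainder`.
#' @export
split_by_feature_ids <- function(pm, ids) {
  stopifnot(inherits(pm, "PeakMatrix"))
  ids <- unique(as.character(ids))
  unknown <- setdiff(ids, pm$features$feature_id)
  if (length(unknown)) {
    stop("unknown feature id(s): ", paste(unknown, collapse = ", "))
  }
  sel <- pm$features$feature_id %in% ids
  take <- function(keep) {
    suppressWarnings(
      peak_matrix(pm$intensity[keep, , drop = FALSE],
                  pm$features[keep, , drop = FALSE], pm$samples)
    )
  }
  list(selected = take(sel), remainder = take(!sel))
}
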