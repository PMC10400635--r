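#' Construct an MS2 spectrum
#'
#' A centroided fragmentation spectrum: precursor m/z (and optionally
#' retention time), a fragment peak list sorted by m/z, and an optional
#' precursor-isolation purity in \[0, 1\].
#'
#' @param precursor_mz precursor m/z in Da.
#' @param fragments two-column matrix or data.frame of fragment `mz` and
#'   `intensity`.
#' @param precursor_rt retention time in seconds (optional).
#' @param purity precursor purity fraction (optional).
#' @param title optional identifier.
#' @return an `ms2_spectrum` object.
#' @export
ms2_spectrum <- function(precursor_mz, fragments, precursor_rt = NA_real_,
                         purity = NA_real_, title = NA_character_) {
  fragments <- as.data.frame(fragments)
  names(fragments)[1:2] <- c("mz", "intensity")
  stopifnot(precursor_mz > 0, all(fragments$intensity >= 0))
  if (!is.na(purity)) stopifnot(purity >= 0, purity <= 1)
  fragments <- fragments[order(fragments$mz), , drop = FALSE]
  rownames(fragments) <- NULL
  structure(list(precursor_mz = precursor_mz, precursor_rt = precursor_rt,
                 fragments = fragments, purity = purity, title = title),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("MS2 spectrum: precursor m/z %.4f, %d fragments",
              x$precursor_mz, nrow(x$fragments)))
  if (!is.na(x$purity)) cat(sprintf(", purity %.2f", x$purity))
  cat("\n")
  invisible(x)
}

#' Filter MS2 spectra on precursor-isolation purity
#'
#' Retains spectra whose purity is at least `plim` (default 0.5, the
#' standard msPurity-style threshold). Spectra without a purity value
#' pass with a warning, since purity cannot be computed from centroided
#' input alone.
#'
#' @param spectra list of `ms2_spectrum`.
#' @param plim minimum purity.
#' @return filtered list.
#' @export
purity_filter <- function(spectra, plim = 0.5) {
  has <- vapply(spectra, function(s) !is.na(s$purity), logical(1))
  if (any(!has)) {
    warning(sum(!has), " spectra lack a purity value and pass unfiltered")
  }
  keep <- !has | vapply(spectra, function(s) isTRUE(s$purity >= plim),
                        logical(1))
  spectra[keep]
}

#' Average replicate MS2 spectra
#'
#' Fragments from all replicates are pooled, sorted by ascending m/z and
#' clustered by single linkage at `ppm_tol`: a fragment joins the current
#' cluster when it is within `ppm_tol` of the previous fragment. Each
#' cluster becomes one peak with intensity-weighted mean m/z and mean
#' intensity.
#'
#' @param replicates non-empty list of `ms2_spectrum` sharing a
#'   precursor.
#' @param ppm_tol linkage tolerance in ppm (default 5).
#' @return an averaged `ms2_spectrum`.
#' @export
average_spectra <- function(replicates, ppm_tol = 5) {
  if (length(replicates) == 0) stop("no spectra to average")
  if (length(replicates) == 1) return(replicates[[1]])
  prec <- vapply(replicates, function(s) s$precursor_mz, numeric(1))
  if (diff(range(prec)) / mean(prec) * 1e6 > ppm_tol) {
    stop("replicates do not share a precursor within tolerance")
  }
  all_fr <- do.call(rbind, lapply(replicates, function(s) s$fragments))
  all_fr <- all_fr[order(all_fr$mz), , drop = FALSE]
  cl <- cumsum(c(TRUE, diff(all_fr$mz) / head(all_fr$mz, -1) * 1e6 >
                   ppm_tol))
  agg <- do.call(rbind, lapply(split(all_fr, cl), function(d) {
    w <- d$intensity
    if (sum(w) == 0) w <- rep(1, nrow(d))
    data.frame(mz = sum(d$mz * w) / sum(w), intensity = mean(d$intensity))
  }))
  ms2_spectrum(mean(prec), agg,
               precursor_rt = mean(vapply(replicates,
                                          function(s) s$precursor_rt,
                                          numeric(1)), na.rm = TRUE),
               purity = suppressWarnings(
                 mean(vapply(replicates, function(s) s$purity,
                             numeric(1)), na.rm = TRUE)))
}

#' Fragment-shift alignment of a candidate spectrum against the parent
#'
#' Substructure evidence that a candidate compound is a biotransformation
#' product of the parent: each parent fragment is \emph{conserved} when a
#' candidate fragment matches it within `ppm_tol` (the substructure is
#' intact), and \emph{shifted} when a candidate fragment matches the
#' parent fragment plus the candidate's mass delta (the substructure
#' carries the modification). Matching is greedy one-to-one by smallest
#' ppm error. The candidate is flagged as related to the parent when at
#' least `conserved_min` parent substructures are conserved (default 3).
#' When `delta` is 0 the shifted count is not meaningful and is reported
#' as 0.
#'
#' @param candidate,parent `ms2_spectrum` objects.
#' @param delta candidate neutral mass minus parent neutral mass (Da).
#' @param ppm_tol fragment match tolerance in ppm (default 5).
#' @param conserved_min minimum conserved substructures for relatedness
#'   (default 3).
#' @return list with `n_conserved`, `n_shifted`, `related`, and the
#'   per-parent-fragment match table.
#' @export
align_to_parent <- function(candidate, parent, delta, ppm_tol = 5,
                            conserved_min = 3) {
  stopifnot(nrow(candidate$fragments) > 0, nrow(parent$fragments) > 0)
  pmz <- parent$fragments$mz
  cmz <- candidate$fragments$mz
  conserved <- greedy_match(pmz, cmz, ppm_tol)
  shifted <- if (abs(delta) < 1e-9) {
    rep(NA_integer_, length(pmz))
  } else {
    greedy_match(pmz + delta, cmz, ppm_tol)
  }
  n_conserved <- sum(!is.na(conserved))
  n_shifted <- sum(!is.na(shifted))
  list(n_conserved = n_conserved, n_shifted = n_shifted,
       related = n_conserved >= conserved_min,
       matches = data.frame(parent_mz = pmz,
                            conserved_mz = cmz[conserved],
                            shifted_mz = cmz[shifted]))
}

# Greedy one-to-one assignment of targets to candidates by smallest ppm
# error; returns, per target, the index of the matched candidate or NA.
greedy_match <- function(target_mz, cand_mz, ppm_tol) {
  pairs <- expand.grid(t = seq_along(target_mz), c = seq_along(cand_mz))
  pairs$ppm <- abs(cand_mz[pairs$c] - target_mz[pairs$t]) /
    target_mz[pairs$t] * 1e6
  pairs <- pairs[pairs$ppm <= ppm_tol, , drop = FALSE]
  pairs <- pairs[order(pairs$ppm), , drop = FALSE]
  out <- rep(NA_integer_, length(target_mz))
  used <- logical(length(cand_mz))
  for (k in seq_len(nrow(pairs))) {
    t <- pairs$t[k]; c <- pairs$c[k]
    if (is.na(out[t]) && !used[c]) {
      out[t] <- c
      used[c] <- TRUE
    }
  }
  out
}

#' Read MS2 spectra from an MGF file
#'
#' Supports BEGIN/END IONS blocks with TITLE, PEPMASS, RTINSECONDS and an
#' optional PURITY annotation.
#'
#' @param path MGF file.
#' @return list of `ms2_spectrum`.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends)) stop("malformed MGF: ", path)
  lapply(seq_along(starts), function(k) {
    block <- lines[(starts[k] + 1):(ends[k] - 1)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- toupper(sub("=.*", "", block[kv]))
    vals <- sub("^[^=]*=", "", block[kv])
    getv <- function(key) if (key %in% keys) vals[match(key, keys)] else NA
    peaks <- block[!kv & nzchar(trimws(block))]
    pm <- do.call(rbind, strsplit(trimws(peaks), "[ \t]+"))
    frag <- data.frame(mz = as.numeric(pm[, 1]),
                       intensity = as.numeric(pm[, 2]))
    ms2_spectrum(
      precursor_mz = as.numeric(strsplit(getv("PEPMASS"), " ")[[1]][1]),
      fragments = frag,
      precursor_rt = suppressWarnings(as.numeric(getv("RTINSECONDS"))),
      purity = suppressWarnings(as.numeric(getv("PURITY"))),
      title = as.character(getv("TITLE")))
  })
}

#' Write MS2 spectra to an MGF file
#'
#' @param spectra list of `ms2_spectrum`.
#' @param path output file.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.na(s$title)) writeLines(paste0("TITLE=", s$title), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    if (!is.na(s$precursor_rt)) {
      writeLines(sprintf("RTINSECONDS=%.3f", s$precursor_rt), con)
    }
    if (!is.na(s$purity)) writeLines(sprintf("PURITY=%.4f", s$purity), con)
    writeLines(sprintf("%.6f %.6g", s$fragments$mz, s$fragments$intensity),
               con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read MS2 spectra from an MSP file
#'
#' Supports Name / PrecursorMZ / RetentionTime / Purity / Num Peaks
#' records with whitespace-separated peak lines.
#'
#' @param path MSP file.
#' @return list of `ms2_spectrum`.
#' @export
read_msp <- function(path) {
  lines <- readLines(path)
  starts <- grep("^Name:", lines, ignore.case = TRUE)
  bounds <- c(starts, length(lines) + 1L)
  lapply(seq_along(starts), function(k) {
    block <- lines[bounds[k]:(bounds[k + 1] - 1L)]
    kv <- grepl("^[A-Za-z][A-Za-z _]*:", block)
    keys <- tolower(gsub(" ", "", sub(":.*", "", block[kv])))
    vals <- trimws(sub("^[^:]*:", "", block[kv]))
    getv <- function(key) if (key %in% keys) vals[match(key, keys)] else NA
    peaks <- block[!kv & nzchar(trimws(block))]
    pm <- do.call(rbind, strsplit(trimws(peaks), "[ \t]+"))
    ms2_spectrum(
      precursor_mz = as.numeric(getv("precursormz")),
      fragments = data.frame(mz = as.numeric(pm[, 1]),
                             intensity = as.numeric(pm[, 2])),
      precursor_rt = suppressWarnings(as.numeric(getv("retentiontime"))),
      purity = suppressWarnings(as.numeric(getv("purity"))),
      title = as.character(getv("name")))
  })
}

#' Write MS2 spectra to an MSP file
#'
#' @param spectra list of `ms2_spectrum`.
#' @param path output file.
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(paste0("Name: ",
                      if (is.na(s$title)) "spectrum" else s$title), con)
    writeLines(sprintf("PrecursorMZ: %.6f", s$precursor_mz), con)
    if (!is.na(s$precursor_rt)) {
      writeLines(sprintf("RetentionTime: %.3f", s$precursor_rt), con)
    }
    if (!is.na(s$purity)) writeLines(sprintf("Purity: %.4f", s$purity), con)
    writeLines(sprintf("Num Peaks: %d", nrow(s$fragments)), con)
    writeLines(sprintf("%.6f %.6g", s$fragments$mz, s$fragments$intensity),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' Link MS2 spectra to peak-matrix features
#'
#' A spectrum is linked to a feature when the precursor m/z is within
#' `ppm_tol` and the precursor retention time within `rt_tol` of the
#' feature (defaults 5 ppm / 10 s).
#'
#' @param spectra list of `ms2_spectrum`.
#' @param pm a `PeakMatrix`.
#' @param ppm_tol precursor mass tolerance (ppm).
#' @param rt_tol retention-time tolerance (seconds).
#' @return data.frame `spectrum_index`, `feature_id`, `ppm_error`,
#'   `rt_error`.
#' @export
link_spectra_to_features <- function(spectra, pm, ppm_tol = 5,
                                     rt_tol = 10) {
  out <- lapply(seq_along(spectra), function(k) {
    s <- spectra[[k]]
    ppm <- (s$precursor_mz - pm$features$mz) / pm$features$mz * 1e6
    drt <- s$precursor_rt - pm$features$rt
    sel <- which(abs(ppm) <= ppm_tol &
                   (is.na(drt) | abs(drt) <= rt_tol))
    if (!length(sel)) return(NULL)
    data.frame(spectrum_index = k,
               feature_id = pm$features$feature_id[sel],
               ppm_error = ppm[sel], rt_error = drt[sel],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(spectrum_index = integer(0),
                      feature_id = character(0), ppm_error = numeric(0),
                      rt_error = numeric(0))
  }
  out
}
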