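#' Ion-form rules for adduct/isotope grouping
#'
#' Each rule maps a neutral mass M to an observed m/z as
#' `mz = (nmer * M + adduct_mass + n13C * 1.003355) / charge`, and is
#' invertible to a neutral-mass estimate. Defaults cover the common
#' singly-charged forms: positive mode \[M+H\]+, \[M+Na\]+, \[M+NH4\]+,
#' \[2M+H\]+ and the 13C1/13C2 isotopologues of \[M+H\]+; negative mode
#' \[M-H\]-, \[M+Cl\]-, \[2M-H\]- and the 13C1 isotopologue of \[M-H\]-.
#'
#' @param polarity `"positive"` or `"negative"`.
#' @return data.frame with columns `name`, `nmer`, `adduct_mass`,
#'   `charge`, `n13C`, `polarity`, `molecular_ion` (whether the form is
#'   the monoisotopic protonated/deprotonated molecule).
#' @export
ion_rules <- function(polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  pos <- data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[2M+H]+",
             "[M+H]+ 13C1", "[M+H]+ 13C2"),
    nmer = c(1, 1, 1, 2, 1, 1),
    adduct_mass = c(PROTON_MASS,
                    MONOISOTOPIC_MASS[["Na"]] - ELECTRON_MASS,
                    monoisotopic_mass(parse_formula("NH4")) - ELECTRON_MASS,
                    PROTON_MASS, PROTON_MASS, PROTON_MASS),
    charge = 1, n13C = c(0, 0, 0, 0, 1, 2),
    molecular_ion = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  neg <- data.frame(
    name = c("[M-H]-", "[M+Cl]-", "[2M-H]-", "[M-H]- 13C1"),
    nmer = c(1, 1, 2, 1),
    adduct_mass = c(-PROTON_MASS,
                    MONOISOTOPIC_MASS[["Cl"]] + ELECTRON_MASS,
                    -PROTON_MASS, -PROTON_MASS),
    charge = 1, n13C = c(0, 0, 0, 1),
    molecular_ion = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  rules <- if (polarity == "positive") pos else neg
  rules$polarity <- polarity
  rules
}

ion_mz <- function(M, rule_row) {
  (rule_row$nmer * M + rule_row$adduct_mass +
     rule_row$n13C * C13_C12_DELTA) / rule_row$charge
}

ion_neutral_mass <- function(mz, rule_row) {
  (mz * rule_row$charge - rule_row$adduct_mass -
     rule_row$n13C * C13_C12_DELTA) / rule_row$nmer
}

#' Group co-eluting features by adduct/isotope ion-form relations
#'
#' Builds a graph over features: two features are linked when they
#' co-elute (|delta RT| <= `rt_tol`) and there is a pair of ion-form
#' rules under which their back-calculated neutral masses agree within
#' `ppm_tol`. Compound groups are the connected components; unexplained
#' features remain singletons. Each grouped member is annotated with its
#' ion form (from the smallest-ppm-error edge), and the group's neutral
#' mass is the median of member estimates. The representative feature is
#' the annotated molecular ion if present, otherwise the member with the
#' highest median intensity.
#'
#' Features not explained by any ion-rule relation (typically
#' singletons) are, when `assume_molecular_ion` is `TRUE`, annotated as
#' the molecular ion with `assumed = TRUE`, so every group carries a
#' neutral-mass estimate for downstream product matching — the same
#' assumption a suspect search makes for a lone feature.
#'
#' @param pm a `PeakMatrix` restricted to one assay/polarity.
#' @param ppm_tol mass tolerance in ppm (default 5).
#' @param rt_tol retention-time tolerance in seconds (default 5).
#' @param rules ion-form rule table from [ion_rules()].
#' @param assume_molecular_ion annotate otherwise unexplained features
#'   as the molecular ion (default `TRUE`).
#' @return list with `summary` (one row per group: `group_id`,
#'   `neutral_mass`, `n_members`, `representative`) and `members` (one
#'   row per feature: `group_id`, `feature_id`, `mz`, `rt`, `ion_form`,
#'   `neutral_mass_est`, `ppm_error`, `representative`).
#' @export
group_features <- function(pm, ppm_tol = 5, rt_tol = 5,
                           rules = ion_rules("positive"),
                           assume_molecular_ion = TRUE) {
  stopifnot(inherits(pm, "PeakMatrix"))
  if (length(unique(rules$polarity)) > 1) {
    stop("mixed polarities in one grouping call")
  }
  feat <- pm$features
  n <- nrow(feat)
  med_int <- apply(pm$intensity, 1, median, na.rm = TRUE)
  # candidate edges: co-eluting pairs whose m/z difference fits a rule pair
  edges <- list()
  if (n >= 2) {
    ord <- order(feat$rt)
    for (a in seq_len(n - 1)) {
      i <- ord[a]
      for (b in seq((a + 1), n)) {
        j <- ord[b]
        if (feat$rt[j] - feat$rt[i] > rt_tol) break
        best <- match_rule_pair(feat$mz[i], feat$mz[j], rules, ppm_tol)
        if (!is.null(best)) {
          edges[[length(edges) + 1L]] <- data.frame(
            i = i, j = j, rule_i = best$rule_i, rule_j = best$rule_j,
            neutral_mass = best$neutral_mass, ppm = best$ppm,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else NULL
  comp <- if (is.null(edges)) {
    seq_len(n)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$i, to = edges$j),
      directed = FALSE, vertices = data.frame(name = seq_len(n)))
    igraph::components(g)$membership[as.character(seq_len(n))]
  }
  # relabel components in order of first appearance for determinism
  comp <- match(comp, unique(comp))
  members <- data.frame(
    feature_id = feat$feature_id, mz = feat$mz, rt = feat$rt,
    component = comp, ion_form = NA_character_,
    neutral_mass_est = NA_real_, ppm_error = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(edges)) {
    # per-feature ion form from its smallest-ppm edge
    by_feat <- rbind(
      data.frame(idx = edges$i, form = edges$rule_i, ppm = abs(edges$ppm),
                 stringsAsFactors = FALSE),
      data.frame(idx = edges$j, form = edges$rule_j, ppm = abs(edges$ppm),
                 stringsAsFactors = FALSE))
    by_feat <- by_feat[order(by_feat$ppm), ]
    by_feat <- by_feat[!duplicated(by_feat$idx), ]
    members$ion_form[by_feat$idx] <- by_feat$form
    rr <- rules[match(members$ion_form, rules$name), ]
    ok <- !is.na(members$ion_form)
    members$neutral_mass_est[ok] <-
      ion_neutral_mass(members$mz[ok], rr[ok, ])
  }
  members$assumed <- FALSE
  if (assume_molecular_ion && any(is.na(members$ion_form))) {
    mol <- rules[rules$molecular_ion, ][1, ]
    na_i <- which(is.na(members$ion_form))
    members$ion_form[na_i] <- mol$name
    members$assumed[na_i] <- TRUE
    members$neutral_mass_est[na_i] <-
      ion_neutral_mass(members$mz[na_i], mol)
  }
  # group summaries
  groups <- split(seq_len(n), comp)
  summary <- do.call(rbind, lapply(names(groups), function(cid) {
    idx <- groups[[cid]]
    nm <- median(members$neutral_mass_est[idx], na.rm = TRUE)
    is_mol <- members$ion_form[idx] %in%
      rules$name[rules$molecular_ion]
    rep_idx <- if (any(is_mol)) {
      idx[is_mol][which.max(med_int[idx[is_mol]])]
    } else {
      idx[which.max(med_int[idx])]
    }
    data.frame(group_id = paste0("G", cid),
               neutral_mass = nm, n_members = length(idx),
               representative = feat$feature_id[rep_idx],
               rt = median(feat$rt[idx]),
               stringsAsFactors = FALSE)
  }))
  members$group_id <- paste0("G", comp)
  members$representative <- members$feature_id %in% summary$representative
  ok <- !is.na(members$neutral_mass_est)
  gm <- summary$neutral_mass[match(members$group_id, summary$group_id)]
  members$ppm_error[ok] <-
    (members$neutral_mass_est[ok] - gm[ok]) / gm[ok] * 1e6
  rownames(summary) <- rownames(members) <- NULL
  list(summary = summary,
       members = members[, c("group_id", "feature_id", "mz", "rt",
                             "ion_form", "assumed", "neutral_mass_est",
                             "ppm_error", "representative")])
}

# Best-matching pair of ion rules explaining two observed m/z values as
# the same neutral compound; NULL if none fits within ppm_tol.
match_rule_pair <- function(mz1, mz2, rules, ppm_tol) {
  best <- NULL
  for (a in seq_len(nrow(rules))) {
    Ma <- ion_neutral_mass(mz1, rules[a, ])
    if (Ma <= 0) next
    for (b in seq_len(nrow(rules))) {
      if (a == b) next
      Mb <- ion_neutral_mass(mz2, rules[b, ])
      if (Mb <= 0) next
      ppm <- (Mb - Ma) / Ma * 1e6
      if (abs(ppm) <= ppm_tol && (is.null(best) || abs(ppm) < abs(best$ppm))) {
        best <- list(rule_i = rules$name[a], rule_j = rules$name[b],
                     neutral_mass = (Ma + Mb) / 2, ppm = ppm)
      }
    }
  }
  best
}
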