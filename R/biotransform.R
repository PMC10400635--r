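# IUPAC monoisotopic atomic masses (Da) for the supported elements.
MONOISOTOPIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151,
  F = 18.99840320,
  Cl = 34.96885271,
  Br = 78.9183376,
  Na = 22.98976928
)

PROTON_MASS <- 1.007276
C13_C12_DELTA <- 1.003355
ELECTRON_MASS <- 0.00054858

#' Parse a molecular formula in Hill notation
#'
#' Supports the elements C, H, N, O, S, P, F, Cl, Br, Na with optional
#' integer counts, e.g. `"C22H27FN4O2"` (sunitinib).
#'
#' @param text formula string.
#' @return named integer vector of element counts, class
#'   `molecular_formula`.
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  s <- gsub("\\s", "", text)
  counts <- integer(0)
  if (nzchar(s)) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)
    toks <- regmatches(s, m)[[1]]
    if (sum(attr(m[[1]], "match.length")) != nchar(s)) {
      stop("cannot parse formula: ", text)
    }
    for (tok in toks) {
      el <- sub("[0-9]*$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% names(MONOISOTOPIC_MASS)) {
        stop("unknown element symbol: ", el)
      }
      counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
    }
  }
  new_formula(counts)
}

new_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (any(counts < 0)) stop("negative element counts")
  structure(as.integer(counts), names = names(counts),
            class = "molecular_formula")
}

#' Format a molecular formula in canonical Hill order
#'
#' Carbon first, hydrogen second, remaining elements alphabetically.
#'
#' @param f a `molecular_formula`.
#' @return character scalar.
#' @export
format_formula <- function(f) {
  if (length(f) == 0) return("")
  els <- names(f)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(el) {
    n <- f[[el]]
    if (n == 1) el else paste0(el, n)
  }, character(1)), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat(format_formula(x), sprintf("(%.6f Da)\n", monoisotopic_mass(x)))
  invisible(x)
}

#' Monoisotopic mass of a molecular formula
#'
#' @param f a `molecular_formula` (or formula string).
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (length(f) == 0) return(0)
  sum(MONOISOTOPIC_MASS[names(f)] * as.numeric(f))
}

#' Define a biotransformation rule
#'
#' A rule is a formula delta: elements added and elements removed, with a
#' metabolic phase label (Phase I functionalisation vs Phase II
#' conjugation).
#'
#' @param name rule name.
#' @param phase `"I"` or `"II"`.
#' @param added,removed formula strings (possibly empty).
#' @return a `transformation_rule` list with the precomputed delta mass.
#' @export
transformation_rule <- function(name, phase, added = "", removed = "") {
  stopifnot(phase %in% c("I", "II"))
  a <- parse_formula(added)
  r <- parse_formula(removed)
  structure(list(name = name, phase = phase, added = a, removed = r,
                 delta_mass = monoisotopic_mass(a) - monoisotopic_mass(r)),
            class = "transformation_rule")
}

#' Default Phase I / Phase II biotransformation rule set
#'
#' Covers the common mammalian reaction vocabulary: oxidation
#' (hydroxylation), N/O-dealkylation (demethylation, de-ethylation),
#' dehydrogenation, saturation, oxidative defluorination, and the
#' conjugations glucuronidation, sulfation, methylation and glycine
#' conjugation. Additional rules (e.g. declared hydrolysis fragments) can
#' be appended or loaded from a file with [read_rule_table()].
#'
#' @return list of [transformation_rule()] objects.
#' @export
default_rules <- function() {
  list(
    transformation_rule("oxidation", "I", added = "O"),
    transformation_rule("demethylation", "I", removed = "CH2"),
    transformation_rule("de-ethylation", "I", removed = "C2H4"),
    transformation_rule("dehydrogenation", "I", removed = "H2"),
    transformation_rule("saturation", "I", added = "H2"),
    transformation_rule("oxidative defluorination", "I",
                        added = "HO", removed = "F"),
    transformation_rule("glucuronidation", "II", added = "C6H8O6"),
    transformation_rule("sulfation", "II", added = "SO3"),
    transformation_rule("methylation", "II", added = "CH2"),
    transformation_rule("glycine conjugation", "II", added = "C2H3NO")
  )
}

#' Read a biotransformation rule table from delimited text
#'
#' Expects columns `name`, `phase`, `added`, `removed` (TSV or CSV by
#' extension); empty cells mean "no atoms".
#'
#' @param path rule file.
#' @return list of [transformation_rule()] objects.
#' @export
read_rule_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE, na.strings = NULL)
  lapply(seq_len(nrow(tab)), function(i) {
    transformation_rule(tab$name[i], tab$phase[i],
                        added = if (is.na(tab$added[i])) "" else tab$added[i],
                        removed = if (is.na(tab$removed[i])) "" else tab$removed[i])
  })
}

#' Apply a transformation rule to a formula
#'
#' @param f a `molecular_formula`.
#' @param rule a `transformation_rule`.
#' @return the transformed `molecular_formula`, or `NULL` if any element
#'   count would become negative (the rule does not apply).
#' @export
apply_rule <- function(f, rule) {
  els <- union(names(f), union(names(rule$added), names(rule$removed)))
  get <- function(x, el) if (el %in% names(x)) x[[el]] else 0L
  counts <- vapply(els, function(el) {
    get(f, el) + get(rule$added, el) - get(rule$removed, el)
  }, integer(1))
  if (any(counts < 0)) return(NULL)
  new_formula(counts)
}

#' Enumerate predicted biotransformation products of a parent formula
#'
#' Breadth-first application of rule sequences up to `max_steps` steps,
#' with at most `max_phase2` Phase II (conjugation) steps — mirroring the
#' step limits of in-silico metabolite prediction engines. Products are
#' deduplicated by molecular formula, keeping the shortest transformation
#' path (ties: fewer Phase II steps, then lexicographic path). The parent
#' itself is excluded.
#'
#' @param parent `molecular_formula` or formula string.
#' @param rules list of [transformation_rule()]s.
#' @param max_steps maximum total number of transformation steps.
#' @param max_phase2 maximum number of Phase II steps.
#' @return data.frame with columns `formula`, `neutral_mass`, `path`
#'   (rule names joined by " > "), `n_steps`, `n_phase1`, `n_phase2`.
#' @export
enumerate_products <- function(parent, rules = default_rules(),
                               max_steps = 3, max_phase2 = 1) {
  stopifnot(length(rules) > 0, max_steps >= 1)
  if (is.character(parent)) parent <- parse_formula(parent)
  parent_key <- format_formula(parent)
  frontier <- list(list(f = parent, path = character(0), p2 = 0L))
  best <- list()  # formula key -> record
  better <- function(a, b) {
    # is a a better (shorter/earlier) path than b?
    if (length(a$path) != length(b$path)) {
      return(length(a$path) < length(b$path))
    }
    if (a$p2 != b$p2) return(a$p2 < b$p2)
    paste(a$path, collapse = ">") < paste(b$path, collapse = ">")
  }
  for (step in seq_len(max_steps)) {
    nxt <- list()
    for (node in frontier) {
      for (rule in rules) {
        if (rule$phase == "II" && node$p2 >= max_phase2) next
        g <- apply_rule(node$f, rule)
        if (is.null(g)) next
        rec <- list(f = g, path = c(node$path, rule$name),
                    p2 = node$p2 + (rule$phase == "II"))
        key <- format_formula(g)
        if (key != parent_key &&
            (is.null(best[[key]]) || better(rec, best[[key]]))) {
          best[[key]] <- rec
        }
        nxt[[length(nxt) + 1L]] <- rec
      }
    }
    frontier <- nxt
  }
  if (length(best) == 0) {
    return(data.frame(formula = character(0), neutral_mass = numeric(0),
                      path = character(0), n_steps = integer(0),
                      n_phase1 = integer(0), n_phase2 = integer(0)))
  }
  recs <- best[order(names(best))]
  out <- data.frame(
    formula = names(recs),
    neutral_mass = vapply(recs, function(r) monoisotopic_mass(r$f),
                          numeric(1)),
    path = vapply(recs, function(r) paste(r$path, collapse = " > "),
                  character(1)),
    n_steps = vapply(recs, function(r) length(r$path), integer(1)),
    n_phase2 = vapply(recs, function(r) r$p2, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out$n_phase1 <- out$n_steps - out$n_phase2
  out[order(out$n_steps, out$formula),
      c("formula", "neutral_mass", "path", "n_steps", "n_phase1",
        "n_phase2")]
}

#' Match predicted products (and the parent) to feature groups
#'
#' A feature group is annotated with every predicted product whose neutral
#' mass lies within `ppm_tol` of the group's neutral-mass estimate;
#' candidates are ranked by absolute ppm error, then shortest
#' transformation path. The parent compound is matched the same way with
#' an empty path.
#'
#' @param groups data.frame of feature groups as returned by
#'   [group_features()] (`summary` element), with columns `group_id` and
#'   `neutral_mass`.
#' @param products data.frame from [enumerate_products()].
#' @param parent optional parent formula (string or `molecular_formula`)
#'   matched alongside the products.
#' @param ppm_tol mass tolerance in ppm (default 5).
#' @return data.frame of annotations: `group_id`, `formula`, `path`,
#'   `neutral_mass`, `ppm_error`, `n_steps`, `n_phase2`, `rank`.
#' @export
match_products <- function(groups, products, parent = NULL, ppm_tol = 5) {
  cand <- products
  if (!is.null(parent)) {
    if (is.character(parent)) parent <- parse_formula(parent)
    cand <- rbind(
      data.frame(formula = format_formula(parent),
                 neutral_mass = monoisotopic_mass(parent),
                 path = "parent", n_steps = 0L, n_phase1 = 0L,
                 n_phase2 = 0L, stringsAsFactors = FALSE),
      cand)
  }
  cand <- cand[!duplicated(cand$formula), , drop = FALSE]
  hits <- lapply(seq_len(nrow(groups)), function(i) {
    gm <- groups$neutral_mass[i]
    if (is.na(gm)) return(NULL)
    ppm <- (gm - cand$neutral_mass) / cand$neutral_mass * 1e6
    sel <- which(abs(ppm) <= ppm_tol)
    if (!length(sel)) return(NULL)
    h <- cand[sel, , drop = FALSE]
    h$ppm_error <- ppm[sel]
    h$group_id <- groups$group_id[i]
    h <- h[order(abs(h$ppm_error), h$n_steps), , drop = FALSE]
    h$rank <- seq_len(nrow(h))
    h
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    return(data.frame(group_id = character(0), formula = character(0),
                      path = character(0), neutral_mass = numeric(0),
                      ppm_error = numeric(0), n_steps = integer(0),
                      n_phase2 = integer(0), rank = integer(0)))
  }
  rownames(hits) <- NULL
  hits[, c("group_id", "formula", "path", "neutral_mass", "ppm_error",
           "n_steps", "n_phase2", "rank")]
}
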