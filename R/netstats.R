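#' Pairwise correlation with p-values over a compounds x samples matrix
#'
#' Computes all pairwise Pearson or Spearman correlations across rows,
#' using pairwise-complete observations. P-values come from the
#' t-distribution transform `t = r * sqrt((n - 2) / (1 - r^2))` on the
#' pairwise-complete sample size (the asymptotic test for Spearman's
#' rho). Pairs with fewer than 3 complete observations, or involving a
#' constant vector, are untested (`NA`).
#'
#' @param x numeric matrix, compounds in rows, samples in columns; `NA`
#'   allowed.
#' @param method `"pearson"` or `"spearman"`.
#' @return list of symmetric matrices `r`, `p`, `n` (complete pairs).
#' @export
pairwise_correlation <- function(x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  r <- suppressWarnings(
    cor(t(x), use = "pairwise.complete.obs", method = method))
  obs <- !is.na(x)
  n <- tcrossprod(obs * 1)
  # constant rows give sd 0 -> NA from cor(); keep as NA
  r[n < 3] <- NA
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p[!is.finite(tt)] <- ifelse(is.na(r[!is.finite(tt)]), NA, 0)
  diag(r) <- 1
  diag(p) <- NA
  dimnames(r) <- dimnames(p) <- dimnames(n) <-
    list(rownames(x), rownames(x))
  list(r = r, p = p, n = n)
}

#' Holm step-down adjustment of p-values
#'
#' Sort ascending, multiply the i-th smallest by (m - i + 1), enforce a
#' monotone non-decreasing cumulative maximum, cap at 1, and restore the
#' original order.
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\] (`NA`
#'   passed through).
#' @return adjusted p-values.
#' @export
holm_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- pvalues
  out[ok] <- p.adjust(pvalues[ok], method = "holm")
  out
}

#' Build a thresholded correlation network
#'
#' Edges join pairs whose absolute coefficient reaches `r_min` and whose
#' p-value (adjusted or raw, as supplied) is below `alpha`. The
#' co-response workflow uses Pearson R >= 0.75 with Holm-adjusted
#' p < 0.05; the dose-response workflow uses Spearman |rho| >= 0.9 with
#' raw p < 0.05 and restricts the network to nodes connected to the
#' parent compound.
#'
#' @param r symmetric coefficient matrix (named).
#' @param p symmetric p-value matrix to threshold (already adjusted if
#'   desired).
#' @param r_min minimum |coefficient|.
#' @param alpha significance threshold.
#' @param p_raw optional raw p matrix recorded on edges alongside `p`.
#' @param restrict_to optional node name: keep only nodes with an edge to
#'   this node (plus the node itself).
#' @param roles optional named character vector of node role labels.
#' @return a `correlation_network`: list with `nodes` (id, role, degree)
#'   and `edges` (source, target, coef, p_raw, p_adj).
#' @export
build_network <- function(r, p, r_min = 0.75, alpha = 0.05, p_raw = NULL,
                          restrict_to = NULL, roles = NULL) {
  stopifnot(all(dim(r) == dim(p)))
  ids <- rownames(r)
  idx <- which(upper.tri(r) & abs(r) >= r_min & p < alpha, arr.ind = TRUE)
  edges <- data.frame(
    source = ids[idx[, 1]], target = ids[idx[, 2]],
    coef = r[idx], p_adj = p[idx],
    p_raw = if (is.null(p_raw)) p[idx] else p_raw[idx],
    stringsAsFactors = FALSE)
  nodes <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(restrict_to)) {
    linked <- union(edges$target[edges$source == restrict_to],
                    edges$source[edges$target == restrict_to])
    keep_nodes <- union(restrict_to, linked)
    edges <- edges[edges$source %in% keep_nodes &
                     edges$target %in% keep_nodes, , drop = FALSE]
    nodes <- nodes[nodes$id %in% keep_nodes, , drop = FALSE]
  }
  nodes$degree <- vapply(nodes$id, function(id) {
    sum(edges$source == id | edges$target == id)
  }, integer(1))
  nodes$role <- if (is.null(roles)) NA_character_ else
    unname(roles[nodes$id])
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 thresholds = list(r_min = r_min, alpha = alpha)),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("Correlation network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges (|coef| >=", x$thresholds$r_min,
      ", p <", x$thresholds$alpha, ")\n")
  invisible(x)
}

#' Export a correlation network
#'
#' Writes an edge-list TSV (`source`, `target`, `coef`, `p_raw`,
#' `p_adj`), a node table TSV (`id`, `degree`, `role`), and optionally a
#' GraphML file for Cytoscape-style visualisation.
#'
#' @param net a `correlation_network`.
#' @param edges_path,nodes_path output TSV paths.
#' @param graphml_path optional GraphML output path.
#' @export
write_network <- function(net, edges_path, nodes_path,
                          graphml_path = NULL) {
  write.table(net$edges[, c("source", "target", "coef", "p_raw", "p_adj")],
              edges_path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(net$nodes, nodes_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      net$edges, directed = FALSE,
      vertices = data.frame(name = net$nodes$id,
                            degree = net$nodes$degree,
                            role = ifelse(is.na(net$nodes$role), "",
                                          net$nodes$role)))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(net)
}

#' One-sided Fisher over-representation analysis
#'
#' For each class, tests whether the class is over-represented in the
#' selected subset relative to the universe: the one-sided Fisher exact
#' p-value is the hypergeometric upper tail P(X >= k) for k class
#' members among n selected, K class members in a universe of N.
#'
#' @param universe named character vector: names are item ids, values
#'   their class labels (e.g. lipid classes); the reference set.
#' @param selected character vector of selected item ids (subset of the
#'   universe), e.g. lipids significantly correlated with the parent.
#' @param alpha enrichment flag threshold (default 0.1).
#' @return data.frame per class: `class`, `K` (universe count), `k`
#'   (selected count), `p`, `enriched`.
#' @export
over_representation <- function(universe, selected, alpha = 0.1) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(selected %in% names(universe))) {
    stop("selected items missing from universe: ",
         paste(setdiff(selected, names(universe)), collapse = ", "))
  }
  N <- length(universe)
  n <- length(selected)
  classes <- sort(unique(universe))
  out <- do.call(rbind, lapply(classes, function(cl) {
    K <- sum(universe == cl)
    k <- sum(universe[selected] == cl)
    p <- hyper_upper_tail(k, K, N, n)
    data.frame(class = cl, K = K, k = k, p = p,
               stringsAsFactors = FALSE)
  }))
  out$enriched <- out$p < alpha
  rownames(out) <- NULL
  out
}

# Hypergeometric upper tail P(X >= k) for k successes among n drawn
# from N with K marked; the one-sided Fisher exact p. Vectorised over k.
hyper_upper_tail <- function(k, K, N, n) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
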