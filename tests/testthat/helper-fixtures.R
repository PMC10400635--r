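# Small in-code fixtures shared across tests.

# A tiny peak matrix: nf features x (ne exposed + nc control + nq QC +
# nb blank) samples, filled from a deterministic seed.
tiny_matrix <- function(nf = 6, ne = 4, nc = 4, nq = 2, nb = 0,
                        seed = 42) {
  set.seed(seed)
  n <- ne + nc + nq + nb
  x <- matrix(exp(rnorm(nf * n, log(1e5), 0.5)), nf, n)
  feats <- data.frame(feature_id = sprintf("F%02d", seq_len(nf)),
                      mz = runif(nf, 100, 900),
                      rt = runif(nf, 30, 600))
  samp <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    class = rep(c("exposed", "control", "QC", "blank"),
                c(ne, nc, nq, nb)),
    stringsAsFactors = FALSE)
  peak_matrix(x, feats, samp)
}

# Literal re-evaluation of the three discovery predicates for one
# feature; the independent oracle for xenobiotic_filter.
oracle_filter_feature <- function(exposed, control, cfg) {
  pe <- sum(!is.na(exposed)) / length(exposed)
  pc <- sum(!is.na(control)) / length(control)
  me <- if (all(is.na(exposed))) NA else median(exposed, na.rm = TRUE)
  mc <- if (all(is.na(control))) NA else median(control, na.rm = TRUE)
  fold <- if (is.na(mc)) Inf else if (is.na(me)) 0 else me / mc
  pe >= cfg$exposed_presence_min &&
    pc <= cfg$control_presence_max &&
    fold >= cfg$fold_min
}

# Random matrix with missingness for the filter-oracle comparison.
random_filter_matrix <- function(nf = 200, ne = 10, nc = 10) {
  n <- ne + nc
  x <- matrix(exp(rnorm(nf * n, log(1e4), 2)), nf, n)
  x[matrix(runif(nf * n) < 0.3, nf, n)] <- NA
  # plant a few near-threshold presence patterns
  x[1, ] <- c(rep(1e6, ne), rep(NA, nc))
  feats <- data.frame(feature_id = sprintf("F%03d", seq_len(nf)),
                      mz = runif(nf, 100, 900), rt = runif(nf, 30, 600))
  samp <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                     class = rep(c("exposed", "control"), c(ne, nc)))
  suppressWarnings(peak_matrix(x, feats, samp))
}

# Adjusted Rand index (independent implementation for cluster scoring).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Brute-force hypergeometric upper tail P(X >= k).
brute_hyper_tail <- function(k, K, N, n) {
  support <- max(0, n - (N - K)):min(K, n)
  sum(vapply(support[support >= k], function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1)))
}
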