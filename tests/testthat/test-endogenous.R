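make_endo_pm <- function(x, classes) {
  nf <- nrow(x)
  suppressWarnings(peak_matrix(
    x,
    data.frame(feature_id = sprintf("F%02d", seq_len(nf)),
               mz = seq(100, 100 + nf - 1), rt = seq(60, 60 + nf - 1)),
    data.frame(sample_id = sprintf("S%02d", seq_len(ncol(x))),
               class = classes)))
}

test_that("prefilter applies each rule and the ledger sums removals", {
  classes <- c(rep("exposed", 3), rep("control", 3), rep("QC", 3),
               "blank")
  x <- rbind(
    c(100, 100, 100, 100, 100, 100, 100, 100, 100, 10),   # blank-fail
    c(1000, 1000, 1000, 1000, 1000, 1000, 100, 1000, 5000, NA), # RSD-fail
    c(500, 500, 500, 500, 500, 500, 500, 500, 500, NA),   # clean
    c(400, 400, 400, 400, 400, 400, 400, 400, 400, NA),   # xeno-listed
    c(300, NA, NA, NA, NA, NA, 300, 300, 300, NA))        # missing-fail
  pm <- make_endo_pm(x, classes)
  res <- prefilter(pm, xeno_ids = "F04")
  expect_setequal(res$matrix$features$feature_id, "F03")
  expect_equal(res$removed$blank, "F01")     # 100 < 20 x 10
  expect_equal(res$removed$qc_rsd, "F02")
  expect_equal(res$removed$feature_missing, "F05")
  expect_equal(res$removed$xenobiotic, "F04")
  total_removed <- nrow(pm$features) - nrow(res$matrix$features)
  expect_equal(sum(res$ledger$n_removed[res$ledger$rule != "sample_missing"]),
               total_removed)
})

test_that("QC features with zero RSD are kept and no-QC input errors", {
  classes <- c("exposed", "exposed", "control", "control", "QC", "QC",
               "QC")
  x <- rbind(c(10, 12, 9, 11, 100, 100, 100))
  pm <- make_endo_pm(x, classes)
  expect_warning(res <- prefilter(pm), "blank filter skipped")
  expect_equal(nrow(res$matrix$features), 1)
  no_qc <- make_endo_pm(x[, 1:4, drop = FALSE], classes[1:4])
  expect_error(prefilter(no_qc), "no QC")
})

test_that("PQN scales a doubled sample back onto the reference", {
  ref <- c(10, 20, 30, 40)
  x <- cbind(ref, 2 * ref, ref)
  colnames(x) <- c("r", "double", "same")
  rownames(x) <- paste0("F", 1:4)
  res <- pqn_normalise(x, reference = ref)
  expect_equal(unname(res$coefficients), c(1, 2, 1))
  expect_equal(unname(res$matrix[, "double"]), ref)
  # self-reference identity
  self <- pqn_normalise(cbind(s = ref), reference = ref)
  expect_equal(unname(self$coefficients), 1)
  expect_equal(unname(self$matrix[, 1]), ref)
})

test_that("PQN coefficients from a feature subset scale all features alike", {
  ref <- rep(100, 6)
  sample <- c(300, 300, 300, 300, 999, 5)  # last two are 'xenobiotic'
  x <- cbind(s = sample)
  rownames(x) <- paste0("F", 1:6)
  res <- pqn_normalise(x, reference = ref,
                       coefficient_source = paste0("F", 1:4))
  expect_equal(unname(res$coefficients), 3)
  expect_equal(unname(res$matrix[5:6, 1]), c(999, 5) / 3)
})

test_that("kNN imputation matches a brute-force reference", {
  naive_knn <- function(x, k) {
    rs <- apply(x, 1, sd, na.rm = TRUE)
    rs[is.na(rs) | rs == 0] <- 1
    z <- x / rs
    out <- x
    for (i in seq_len(nrow(x))) {
      for (j in seq_len(ncol(x))) {
        if (!is.na(x[i, j])) next
        d <- rep(Inf, nrow(x))
        for (l in seq_len(nrow(x))) {
          if (l == i) next
          sh <- !is.na(z[i, ]) & !is.na(z[l, ])
          if (!any(sh)) next
          d[l] <- sqrt(mean((z[i, sh] - z[l, sh])^2))
        }
        cand <- which(!is.na(x[, j]) & is.finite(d))
        cand <- cand[order(d[cand], cand)]
        nb <- cand[seq_len(min(k, length(cand)))]
        if (length(nb)) out[i, j] <- mean(x[nb, j])
      }
    }
    out
  }
  set.seed(21)
  x <- matrix(exp(rnorm(500, log(1e4), 1)), 50, 10)
  x[sample(length(x), 25)] <- NA
  expect_equal(knn_impute(x, k = 5), naive_knn(x, 5), tolerance = 1e-12)
})

test_that("kNN imputation identities and error cases", {
  x <- matrix(1:20, 4, 5)
  expect_equal(knn_impute(x), x)
  # one missing cell among identical features is forced
  y <- matrix(7, 6, 4)
  y[1, 2] <- NA
  expect_equal(knn_impute(y)[1, 2], 7)
  z <- matrix(c(NA, NA, NA, 1, 2, 3), 2, 3, byrow = TRUE)
  rownames(z) <- c("allmiss", "ok")
  expect_error(knn_impute(z), "allmiss")
})

test_that("glog is monotone, finite at zero, and tends to ln(x)", {
  x <- c(0, 0.5, 10, 1e4, 1e7)
  y <- glog_transform(x, lambda = 100)
  expect_true(all(diff(y) > 0))
  expect_true(is.finite(y[1]))
  # lambda -> 0 limit is the plain log for positive x
  expect_equal(glog_transform(x[-1], lambda = 1e-12), log(x[-1]),
               tolerance = 1e-6)
  expect_error(glog_transform(x, lambda = 0), "positive")
  expect_error(glog_transform(x, lambda = -1), "positive")
})

test_that("glog lambda tuning equalises QC variances across intensity", {
  set.seed(31)
  mu <- exp(rnorm(80, log(1e4), 1.5))
  qc <- sapply(1:6, function(i) mu * exp(rnorm(80, 0, 0.05)) +
                 rnorm(80, 0, 50))
  qc[qc < 0] <- 0
  lam <- glog_lambda(qc)
  expect_gt(lam, 0)
  v_raw <- apply(qc, 1, var)
  v_glog <- apply(glog_transform(qc, lam), 1, var)
  spread <- function(v) var(log(v[v > 0]))
  expect_lt(spread(v_glog), spread(v_raw))
})

test_that("exposure tests: null features, strong shifts, BH hand case", {
  set.seed(41)
  n <- 9
  null_f <- rnorm(2 * n, 100, 5)
  shift_f <- c(rnorm(n, 200, 5), rnorm(n, 100, 5))  # 20 SD shift
  x <- rbind(null = null_f, shifted = shift_f)
  classes <- rep(c("exposed", "control"), each = n)
  res <- exposure_tests(x, classes)
  expect_gt(res$p[res$feature_id == "null"], 0.05)
  expect_equal(res$fold_change[res$feature_id == "null"], 1,
               tolerance = 0.1)
  expect_lt(res$q[res$feature_id == "shifted"], 0.05)
  expect_gt(res$fold_change[res$feature_id == "shifted"], 1.5)
  # BH q-values match the hand computation
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  expect_true(is.na(suppressWarnings(
    exposure_tests(rbind(f = rep(1, 8)),
                   rep(c("exposed", "control"), each = 4)))$p))
})

test_that("PCA: collinear data, sign convention, exact reconstruction", {
  t <- seq(-1, 1, length.out = 8)
  line <- rbind(f1 = 3 * t, f2 = -2 * t, f3 = 0.5 * t)
  res <- pca_scores(line)
  expect_gt(res$explained[1], 0.999)
  # sign convention: largest-|loading| entry positive per component
  expect_true(all(apply(res$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  set.seed(51)
  x <- matrix(rnorm(60), 6, 10)
  res2 <- pca_scores(x)
  recon <- res2$loadings %*% t(res2$scores) + res2$center
  expect_lt(max(abs(recon - x)), 1e-8)
  expect_error(pca_scores(x[, 1, drop = FALSE]), "at least 2")
  x[1, 1] <- NA
  expect_error(pca_scores(x), "complete")
})
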