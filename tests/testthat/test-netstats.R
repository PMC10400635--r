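test_that("pairwise correlation recovers exact linear and monotone ties", {
  x <- rbind(a = 1:10, b = 2 * (1:10), c = (1:10)^3)
  cc <- pairwise_correlation(x, "pearson")
  expect_equal(cc$r["a", "b"], 1)
  expect_lt(cc$r["a", "c"], 1)
  cs <- pairwise_correlation(x, "spearman")
  expect_equal(cs$r["a", "c"], 1)  # monotone transform
})

test_that("p-values equal the t-distribution transform of R", {
  set.seed(11)
  x <- rbind(a = rnorm(20), b = rnorm(20))
  cc <- pairwise_correlation(x, "pearson")
  r <- cc$r["a", "b"]
  t_stat <- r * sqrt((20 - 2) / (1 - r^2))
  p_oracle <- 2 * pt(-abs(t_stat), df = 18)
  expect_equal(cc$p["a", "b"], p_oracle, tolerance = 1e-12)
  # agrees with cor.test as an independent route
  expect_equal(cc$p["a", "b"], cor.test(x["a", ], x["b", ])$p.value,
               tolerance = 1e-10)
})

test_that("constant vectors and short overlaps are untested", {
  x <- rbind(a = c(1, 1, 1, 1, 1), b = rnorm(5),
             c = c(1, 2, NA, NA, NA))
  cc <- pairwise_correlation(x)
  expect_true(is.na(cc$r["a", "b"]))
  expect_true(is.na(cc$r["b", "c"]))  # only 2 complete pairs
})

test_that("Holm adjustment matches the hand-applied step-down rule", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.30)), c(0.03, 0.04, 0.30))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # dominates raw p-values and is permutation-equivariant
  set.seed(3)
  p <- runif(20)
  expect_true(all(holm_adjust(p) >= p))
  perm <- sample(20)
  expect_equal(holm_adjust(p)[perm], holm_adjust(p[perm]))
})

test_that("network edges respect both thresholds", {
  r <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  p <- matrix(1e-9, 3, 3)
  net <- build_network(r, p, r_min = 0.75, alpha = 0.05)
  expect_equal(nrow(net$edges), 3)  # complete triangle
  expect_equal(sort(net$nodes$degree), c(2, 2, 2))
  # strong p but sub-threshold coefficient -> no edge
  r2 <- r; r2["a", "b"] <- r2["b", "a"] <- 0.74
  net2 <- build_network(r2, p, r_min = 0.75, alpha = 0.05)
  expect_equal(nrow(net2$edges), 2)
})

test_that("dose-response restriction keeps only parent-linked nodes", {
  ids <- c("parent", "m1", "other")
  r <- diag(3); dimnames(r) <- list(ids, ids)
  r["parent", "m1"] <- r["m1", "parent"] <- 0.95
  r["m1", "other"] <- r["other", "m1"] <- 0.95
  p <- matrix(1e-6, 3, 3, dimnames = list(ids, ids))
  net <- build_network(r, p, r_min = 0.9, alpha = 0.05,
                       restrict_to = "parent")
  expect_setequal(net$nodes$id, c("parent", "m1"))
  expect_equal(nrow(net$edges), 1)
})

test_that("network export writes edge, node and GraphML files", {
  dir <- withr::local_tempdir()
  r <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- matrix(1e-9, 2, 2)
  net <- build_network(r, p)
  write_network(net, file.path(dir, "e.tsv"), file.path(dir, "n.tsv"),
                file.path(dir, "g.graphml"))
  expect_true(file.exists(file.path(dir, "g.graphml")))
  back <- read.delim(file.path(dir, "e.tsv"))
  expect_equal(nrow(back), 1)
})

test_that("over-representation p equals the brute-force tail sum", {
  # N=20, K=5, n=8, k=4
  universe <- setNames(rep(c("lipidA", "other"), c(5, 15)),
                       sprintf("i%02d", 1:20))
  selected <- c(sprintf("i%02d", 1:4), sprintf("i%02d", 6:9))
  res <- over_representation(universe, selected)
  pa <- res$p[res$class == "lipidA"]
  expect_equal(pa, brute_hyper_tail(4, 5, 20, 8), tolerance = 1e-12)
  expect_equal(pa, 0.0578, tolerance = 1e-3)
  # selecting the whole universe leaves nothing enriched
  res_all <- over_representation(universe, names(universe))
  expect_true(all(res_all$p == 1))
  # k = 0 gives p = 1
  res0 <- over_representation(universe, sprintf("i%02d", 6:9))
  expect_equal(res0$p[res0$class == "lipidA"], 1)
  expect_error(over_representation(setNames(character(0), character(0)),
                                   character(0)), "empty universe")
})

test_that("hypergeometric tail matches brute force on all small tables", {
  for (N in c(2, 5, 9, 17, 30)) {
    for (K in 0:N) {
      for (n in c(1, N %/% 2, N)) {
        for (k in 0:min(K, n)) {
          expect_equal(xenofate:::hyper_upper_tail(k, K, N, n),
                       brute_hyper_tail(k, K, N, n), tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("edge sets shrink as thresholds tighten", {
  set.seed(5)
  x <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(paste0("f", 1:10), NULL))
  cc <- pairwise_correlation(x)
  loose <- build_network(cc$r, cc$p, r_min = 0.3, alpha = 0.5)
  tight <- build_network(cc$r, cc$p, r_min = 0.6, alpha = 0.05)
  key <- function(net) paste(net$edges$source, net$edges$target)
  expect_true(all(key(tight) %in% key(loose)))
})
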