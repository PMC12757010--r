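make_outlier_table <- function(n = 50, m = 100, seed = 1) {
  set.seed(seed)
  base <- c(rep(1, 20), rep(0, m - 20))
  x <- t(vapply(seq_len(n - 1), function(i) base + runif(m, 0, 0.01),
                numeric(m)))
  x <- rbind(x, c(rep(0, m - 20), rep(1, 20)))
  rownames(x) <- c(paste0("n", seq_len(n - 1)), "outlier")
  x
}

test_that("forest has the contracted structure", {
  x <- random_composition(10, 40)
  fit <- kadaif(x, t = 5, seed = 3)
  expect_s3_class(fit, "kadaif")
  expect_length(fit$trees, 5)
  expect_equal(fit$n, 10)
  expect_equal(fit$c_n, average_path_length(10))
  expect_equal(fit$params$psi, 10)  # minimum binds at 40 features
  expect_named(fit$scores, rownames(x))
  expect_true(all(fit$scores > 0 & fit$scores <= 1))
  expect_equal(fit$flagged, fit$scores > 0.5)
  expect_error(kadaif(x[1, , drop = FALSE]), "at least 2 samples")
  expect_error(kadaif(-x), "negative")
})

test_that("fits are reproducible by seed and differ across seeds", {
  x <- random_composition(20, 60)
  f1 <- kadaif(x, t = 10, seed = 5)
  f2 <- kadaif(x, t = 10, seed = 5)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$trees, f2$trees)
  f3 <- kadaif(x, t = 10, seed = 6)
  expect_false(identical(f1$scores, f3$scores))
})

test_that("every tree partitions the samples into disjoint leaves", {
  x <- random_composition(15, 50)
  for (fit in list(kadaif(x, t = 8, seed = 7),
                   isolation_forest(x, t = 8, seed = 7),
                   kadaif(x, t = 8, reduction = "pca", seed = 7),
                   kadaif(x, t = 8, max_depth = 3, seed = 7))) {
    for (tree in fit$trees) {
      leaves <- collect_leaves(tree)
      members <- sort(unlist(lapply(leaves, `[[`, "members")))
      expect_equal(members, 1:15)
      depths <- vapply(leaves, `[[`, numeric(1), "depth")
      edge <- vapply(leaves, `[[`, numeric(1), "edge_depth")
      expect_equal(depths, edge)  # stored depth equals edge count
      expect_true(all(depths <= fit$params$max_depth))
      expect_true(all(vapply(leaves, `[[`, numeric(1), "size") >= 1))
    }
  }
})

test_that("stopping rules give the documented leaf layouts", {
  # two distinct samples split into singleton leaves
  x2 <- renormalize_rows(rbind(a = c(1, 0, 0, 1), b = c(0, 1, 1, 0)))
  fit2 <- kadaif(x2, t = 20, psi_min = 4, seed = 8)
  sizes <- unlist(lapply(fit2$trees, function(tr)
    vapply(collect_leaves(tr), `[[`, numeric(1), "size")))
  expect_true(all(sizes == 1))
  # identical rows can never be separated: root stays a leaf
  xk <- matrix(rep(c(0.2, 0.3, 0.5), each = 6), nrow = 6)
  rownames(xk) <- paste0("s", 1:6)
  fitk <- kadaif(xk, t = 10, psi_min = 3, seed = 9)
  expect_true(all(vapply(fitk$trees, function(tr) tr$kind, "") == "leaf"))
  # depth 0 + c(6) for everyone: the 0.5 anchor
  expect_equal(unname(fitk$scores), rep(0.5, 6), tolerance = 1e-12)
  # max_depth = 1 caps every path at one edge
  fit1 <- kadaif(random_composition(12, 30), t = 10, max_depth = 1, seed = 10)
  for (tr in fit1$trees) {
    expect_true(all(vapply(collect_leaves(tr), `[[`, numeric(1),
                           "depth") <= 1))
  }
})

test_that("leaf depth adjustment adds c(leaf size)", {
  x <- random_composition(9, 30)
  fit <- kadaif(x, t = 6, seed = 11)
  for (k in seq_along(fit$trees)) {
    leaves <- collect_leaves(fit$trees[[k]])
    set.seed(kadaif:::derive_seed(fit$params$seed, k))
    dep <- kadaif:::.build_tree_cpp(x, list(
      psi = fit$params$psi, with_replacement = TRUE, r = 1L,
      max_depth = fit$params$max_depth, n_components = 20L, pc_sel = 0L,
      reduction = 0L, renormalize = TRUE, retry_limit = 3L))$depths
    for (lf in leaves) {
      expect_equal(dep[lf$members],
                   rep(lf$depth + average_path_length(lf$size),
                       length(lf$members)),
                   tolerance = 1e-12)
    }
  }
})

test_that("a planted disjoint-support outlier attains the top score", {
  hits <- 0
  for (s in 1:20) {
    fit <- kadaif(make_outlier_table(seed = s), t = 50, seed = 100 + s)
    hits <- hits + (names(which.max(fit$scores)) == "outlier")
  }
  expect_gte(hits / 20, 0.95)
})

test_that("the single-feature baseline isolates a one-feature outlier", {
  set.seed(14)
  x <- matrix(runif(21 * 5, 0.4, 0.6), 21, 5)
  x[21, 3] <- 50
  rownames(x) <- c(paste0("s", 1:20), "outlier")
  fit <- isolation_forest(x, t = 50, seed = 15)
  expect_equal(names(which.max(fit$scores)), "outlier")
  # all-identical table: nothing separates, all scores equal
  xi <- matrix(1, 8, 4, dimnames = list(paste0("s", 1:8), NULL))
  expect_equal(unname(isolation_forest(xi, t = 10, seed = 16)$scores),
               rep(0.5, 8), tolerance = 1e-12)
})

test_that("on one feature the ordination forest and baseline agree", {
  # a single column admits only one split geometry, so both methods must
  # rank the planted outlier first and order samples consistently
  set.seed(17)
  x <- matrix(c(runif(30, 0, 1), 8), ncol = 1,
              dimnames = list(c(paste0("s", 1:30), "outlier"), "f"))
  fk <- kadaif(x, t = 150, reduction = "pca", psi_min = 1, seed = 18)
  fb <- isolation_forest(x, t = 150, seed = 18)
  expect_equal(names(which.max(fk$scores)), "outlier")
  expect_equal(names(which.max(fb$scores)), "outlier")
  expect_gt(cor(fk$scores, fb$scores, method = "spearman"), 0.9)
})

test_that("pca-mode fits score new samples through stored loadings", {
  set.seed(19)
  x <- matrix(rnorm(30 * 12, 10, 3), 30, 12)
  x[x < 0] <- 0
  rownames(x) <- paste0("s", 1:30)
  fit <- kadaif(x, t = 20, reduction = "pca", seed = 20)
  # round-trip: training rows land in their training leaves
  expect_equal(predict(fit, x, type = "depth"), fit$mean_depth,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(predict(fit, x), fit$scores, tolerance = 1e-9,
               ignore_attr = TRUE)
  # a far-away new point scores higher than typical training points
  far <- matrix(rep(100, 12), 1)
  expect_gt(predict(fit, far), median(fit$scores))
  # pcoa mode has no out-of-sample projection
  fitp <- kadaif(random_composition(10, 30), t = 5, seed = 21)
  expect_error(predict(fitp, random_composition(2, 30)), "pca")
})

test_that("report accessors and methods are consistent", {
  x <- random_composition(12, 40)
  fit <- kadaif(x, t = 10, seed = 22)
  df <- as.data.frame(fit)
  expect_equal(df$anomaly_score, unname(fit$scores))
  expect_equal(df$sample_id, rownames(x))
  expect_equal(fitted(fit), fit$scores)
  expect_equal(df$flagged, unname(fit$scores > 0.5))
  expect_output(print(fit), "trees on 12 samples")
  expect_output(print(summary(fit)), "score quantiles")
  expect_equal(anomaly_score(fit$mean_depth, fit$n), fit$scores)
})
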