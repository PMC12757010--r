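test_that("renormalize_rows is idempotent, scale-invariant, zero-preserving", {
  x <- rbind(c(2, 3, 5), c(0, 0, 0), c(1, 1, 2))
  r <- renormalize_rows(x)
  expect_equal(r[1, ], c(0.2, 0.3, 0.5))
  expect_equal(r[2, ], c(0, 0, 0))
  expect_equal(renormalize_rows(r), r)
  expect_equal(renormalize_rows(17.3 * x), r)
  expect_error(renormalize_rows(rbind(c(-1, 2))), "non-negative")
})

test_that("bray_curtis matches hand values and the zero-row conventions", {
  expect_equal(bray_curtis(rbind(c(1, 0), c(0, 1)))[1, 2], 1.0)
  expect_equal(bray_curtis(rbind(c(0.3, 0.7), c(0.3, 0.7)))[1, 2], 0.0)
  expect_equal(bray_curtis(rbind(c(0.5, 0.5), c(0.25, 0.75)))[1, 2], 0.25)
  d <- bray_curtis(rbind(c(0, 0), c(0, 0), c(0.4, 0.6)))
  expect_equal(d[1, 2], 0)  # two empty profiles are indistinguishable
  expect_equal(d[1, 3], 1)  # empty vs non-empty are maximally distinct
  expect_error(bray_curtis(rbind(c(-0.1, 1))), "non-negative")
})

test_that("bray_curtis agrees with the naive loop, vegan, and the engine", {
  skip_if_not_installed("vegan")
  set.seed(42)
  for (i in 1:50) {
    x <- random_composition(10, 8, sparsity = 0.4)
    d <- bray_curtis(x)
    expect_lt(max(abs(d - bc_naive(x))), 1e-12)
    expect_lt(max(abs(d - kadaif:::.bray_curtis_cpp(x))), 1e-12)
    expect_true(isSymmetric(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
  }
  x <- random_composition(12, 9, sparsity = 0)  # vegdist needs positive rows
  expect_lt(max(abs(bray_curtis(x) -
                      as.matrix(vegan::vegdist(x, "bray")))), 1e-12)
})

test_that("pcoa reconstructs Euclidean-embeddable distances", {
  set.seed(7)
  for (i in 1:20) {
    pts <- matrix(rnorm(9 * 4), 9, 4)
    d <- as.matrix(dist(pts))
    ord <- pcoa_reduce(d)
    expect_lt(max(abs(as.matrix(dist(ord$coordinates)) - d)), 1e-9)
  }
  # collinear points embed in one axis
  pts <- cbind(c(0, 1, 3), c(0, 2, 6))
  ord <- pcoa_reduce(as.matrix(dist(pts)))
  expect_equal(ncol(ord$coordinates), 1)
  expect_lt(max(abs(as.matrix(dist(ord$coordinates)) -
                      as.matrix(dist(pts)))), 1e-9)
})

test_that("pcoa agrees with cmdscale and handles degenerate input", {
  set.seed(8)
  pts <- matrix(rnorm(12 * 3), 12, 3)
  d <- as.matrix(dist(pts))
  ord <- pcoa_reduce(d, k = 3)
  cmd <- cmdscale(d, k = 3, eig = TRUE)
  expect_equal(abs(ord$coordinates), abs(cmd$points), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(ord$eigenvalues, cmd$eig[1:3], tolerance = 1e-8)
  # identical samples: no positive eigenvalues -> empty (degenerate) artifact
  empty <- pcoa_reduce(matrix(0, 5, 5))
  expect_equal(ncol(empty$coordinates), 0)
  expect_length(empty$explained, 0)
  expect_error(pcoa_reduce(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("explained-variance fractions are a decreasing probability vector", {
  set.seed(9)
  x <- random_composition(15, 30, sparsity = 0.5)
  ord <- pcoa_reduce(bray_curtis(x))
  expect_true(all(ord$explained >= 0))
  expect_true(all(diff(ord$explained) <= 1e-12))
  expect_equal(sum(ord$explained), 1, tolerance = 1e-9)
  pca <- pca_reduce(matrix(rnorm(60), 20, 3))
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_equal(sum(pca$explained), 1, tolerance = 1e-9)
})

test_that("pca stores a projection that round-trips training samples", {
  set.seed(10)
  x <- matrix(rnorm(40 * 6), 40, 6)
  ord <- pca_reduce(x, k = 4)
  expect_lt(max(abs(project_samples(ord, x) - ord$coordinates)), 1e-9)
  # rank-1 data: one axis, full variance
  line <- outer(seq_len(20), c(1, 2, -0.5))
  ord1 <- pca_reduce(line)
  expect_equal(ord1$explained[1], 1.0, tolerance = 1e-9)
  expect_error(pca_reduce(matrix(1, 1, 3)), "at least 2")
  expect_error(project_samples(pcoa_reduce(matrix(0, 3, 3)), matrix(0, 1, 3)),
               "PCA")
})

test_that("feature subsampling sizes follow max(psi_min, round(f * F))", {
  set.seed(11)
  expect_length(subsample_features(1000), 10)
  expect_length(subsample_features(500), 10)
  expect_length(subsample_features(3000), 30)
  # without replacement the subset cannot exceed F
  expect_length(subsample_features(4, psi_min = 10, with_replacement = FALSE), 4)
  idx <- subsample_features(50, psi_min = 25)
  expect_true(all(idx >= 1 & idx <= 50))
})

test_that("component selection follows the variance-weighted law", {
  set.seed(12)
  draws <- replicate(1e4, select_component(c(0.8, 0.2)))
  freq <- mean(draws == 1)
  expect_lt(abs(freq - 0.8), 0.03)
  chi <- suppressWarnings(
    chisq.test(table(factor(draws, 1:2)), p = c(0.8, 0.2)))
  expect_gt(chi$p.value, 0.01)
  expect_equal(select_component(c(1)), 1L)
  expect_equal(select_component(c(0.5, 0.3, 0.2), mode = "first"), 1L)
  expect_true(is.na(select_component(numeric(0))))
  u <- replicate(2000, select_component(c(0.9, 0.1), mode = "uniform"))
  expect_lt(abs(mean(u == 1) - 0.5), 0.05)
})

test_that("threshold splits are exhaustive, exclusive, and flag degeneracy", {
  set.seed(13)
  sp <- split_on_threshold(c(0, 10))
  expect_false(sp$degenerate)
  expect_equal(sort(c(sp$left, sp$right)), 1:2)
  expect_true(sp$threshold > 0 && sp$threshold < 10)
  expect_true(split_on_threshold(c(3, 3, 3))$degenerate)
  for (i in 1:25) {
    p <- rnorm(8)
    sp <- split_on_threshold(p)
    if (!sp$degenerate) {
      expect_equal(sort(c(sp$left, sp$right)), 1:8)
      expect_length(intersect(sp$left, sp$right), 0)
      expect_true(all(p[sp$left] <= sp$threshold))
      expect_true(all(p[sp$right] > sp$threshold))
    }
  }
  expect_error(split_on_threshold(1), "at least 2")
})
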