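#' Renormalize rows to relative abundances
#'
#' Divides every row with a positive sum by that sum, so rows are proper
#' relative-abundance profiles; all-zero rows are left all-zero.  Applied
#' to every random feature subset before ordination in Bray-Curtis mode,
#' because a subset of columns from a compositional table is no longer
#' compositional on its own.
#'
#' @param x Numeric matrix of non-negative values (samples in rows).
#' @return A matrix of the same shape whose non-zero rows sum to 1.
#' @examples
#' renormalize_rows(rbind(c(2, 3, 5), c(0, 0, 0)))
#' @export
renormalize_rows <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be non-negative")
  rs <- rowSums(x)
  pos <- rs > 0
  x[pos, ] <- x[pos, , drop = FALSE] / rs[pos]
  x
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(u, v) = 1 - 2 \sum_i \min(u_i, v_i) / (\sum_i u_i + \sum_i v_i)}.
#' Two all-zero rows are at distance 0 (they are indistinguishable) and an
#' all-zero row is at distance 1 from any non-zero row; the textbook
#' formula is 0/0 in those cases.
#'
#' @param x Numeric matrix of non-negative abundances, samples in rows.
#' @return A symmetric `nrow(x)` x `nrow(x)` matrix with zero diagonal and
#'   values in `[0, 1]`.
#' @examples
#' bray_curtis(rbind(a = c(0.5, 0.5), b = c(0.25, 0.75)))
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be non-negative")
  n <- nrow(x)
  rs <- rowSums(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    j <- seq_len(n) > i
    if (!any(j)) next
    shared <- colSums(pmin(t(x[j, , drop = FALSE]), x[i, ]))
    denom <- rs[i] + rs[j]
    dij <- ifelse(denom > 0, 1 - 2 * shared / denom, 0)
    d[i, j] <- dij
    d[j, i] <- dij
  }
  d
}

#' Principal Coordinates Analysis (classical MDS)
#'
#' Gower double-centering of the squared distance matrix followed by an
#' eigendecomposition.  Axes with non-positive eigenvalues (Bray-Curtis is
#' not Euclidean-embeddable in general) are discarded; "variance explained"
#' is each positive eigenvalue over the sum of all positive eigenvalues.
#' Eigenvector signs follow a deterministic convention (largest-magnitude
#' coordinate positive) so runs are reproducible across linear-algebra
#' backends.
#'
#' @param d Symmetric, zero-diagonal, non-negative distance matrix.
#' @param k Maximum number of axes to retain (default all positive axes).
#' @return An object of class `kadaif_reduction` with elements
#'   `coordinates` (n x k', axes scaled by sqrt eigenvalue, decreasing),
#'   `eigenvalues`, `explained` (fractions summing to <= 1 over retained
#'   axes), and `mode = "pcoa"`.  Zero retained axes (all points
#'   coincident) yields zero-column coordinates: a degenerate ordination.
#' @examples
#' x <- matrix(runif(40), 8, 5)
#' ord <- pcoa_reduce(bray_curtis(renormalize_rows(x)))
#' head(ord$explained)
#' @export
pcoa_reduce <- function(d, k = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (ncol(d) != n || any(abs(d - t(d)) > 1e-8)) stop("`d` must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  a <- d^2
  rm <- rowMeans(a)
  b <- -0.5 * (a - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(a))
  e <- eigen(b, symmetric = TRUE)
  tol <- max(1e-12, max(e$values) * 1e-9)
  pos <- which(e$values > tol)
  keep <- pos[seq_len(min(length(pos), if (is.null(k)) length(pos) else k, n - 1))]
  ev <- e$values[keep]
  vec <- e$vectors[, keep, drop = FALSE]
  # deterministic signs
  for (j in seq_along(keep)) {
    col <- vec[, j]
    if (col[which.max(abs(col))] < 0) vec[, j] <- -col
  }
  coords <- sweep(vec, 2, sqrt(ev), `*`)
  rownames(coords) <- rownames(d)
  structure(list(
    coordinates = coords,
    eigenvalues = ev,
    explained = if (length(pos)) ev / sum(e$values[pos]) else numeric(0),
    mode = "pcoa"
  ), class = "kadaif_reduction")
}

#' Principal Component Analysis with stored projection
#'
#' Column mean-centering followed by a singular value decomposition.  The
#' feature means and loadings are kept so new samples can be projected onto
#' the same axes -- this is what makes PCA mode (for non-compositional
#' omics tables) support out-of-sample scoring, unlike PCoA.  Loading signs
#' follow the same largest-magnitude-positive convention as [pcoa_reduce()].
#'
#' @param x Numeric matrix, samples in rows (`>= 2` rows).
#' @param k Maximum number of axes to retain.
#' @return A `kadaif_reduction` with `coordinates` (scores), `means`,
#'   `loadings`, `explained`, `mode = "pca"`.
#' @examples
#' ord <- pca_reduce(matrix(rnorm(60), 20, 3), k = 2)
#' pr <- project_samples(ord, matrix(rnorm(6), 2, 3))
#' @export
pca_reduce <- function(x, k = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 samples")
  mu <- colMeans(x)
  cx <- sweep(x, 2, mu)
  sv <- svd(cx)
  tol <- max(1e-12, max(sv$d) * 1e-9)
  pos <- which(sv$d > tol)
  keep <- pos[seq_len(min(length(pos), if (is.null(k)) length(pos) else k))]
  load <- sv$v[, keep, drop = FALSE]
  for (j in seq_along(keep)) {
    col <- load[, j]
    if (col[which.max(abs(col))] < 0) load[, j] <- -col
  }
  vars <- sv$d^2
  structure(list(
    coordinates = cx %*% load,
    means = mu,
    loadings = load,
    explained = if (length(pos)) vars[keep] / sum(vars[pos]) else numeric(0),
    mode = "pca"
  ), class = "kadaif_reduction")
}

#' Project new samples through a fitted PCA reduction
#'
#' @param reduction A `kadaif_reduction` from [pca_reduce()].
#' @param newdata Matrix with the same feature columns as the training data.
#' @return Matrix of coordinates on the retained axes.
#' @export
project_samples <- function(reduction, newdata) {
  if (!inherits(reduction, "kadaif_reduction") || reduction$mode != "pca") {
    stop("out-of-sample projection is only available for PCA reductions")
  }
  newdata <- matrix(newdata, ncol = length(reduction$means))
  sweep(newdata, 2, reduction$means) %*% reduction$loadings
}

#' Draw a random feature subset for one tree node
#'
#' The node subset size is \eqn{\psi = \max(\psi_{min},
#' \mathrm{round}(f \cdot F))} -- by default about 1\% of all features with
#' a floor of 10 -- drawn uniformly, with replacement by default.
#' Duplicate indices from with-replacement draws are kept: a duplicated
#' taxon is simply counted twice in the node's distances.
#'
#' @param n_features Total number of feature columns `F`.
#' @param psi_fraction Fraction of features per node (default 0.01).
#' @param psi_min Minimum subset size (default 10).
#' @param with_replacement Sample with replacement (default `TRUE`); when
#'   `FALSE` the subset size is capped at `F`.
#' @return Integer vector of column indices (possibly with duplicates).
#' @export
subsample_features <- function(n_features, psi_fraction = 0.01, psi_min = 10,
                               with_replacement = TRUE) {
  if (n_features < 1) stop("`n_features` must be >= 1")
  psi <- max(psi_min, round(psi_fraction * n_features))
  if (!with_replacement) psi <- min(psi, n_features)
  sample.int(n_features, psi, replace = with_replacement)
}

#' Choose one ordination axis for a node split
#'
#' Default mode draws one of the first `n_components` retained axes with
#' probability proportional to its variance explained; `"uniform"` draws
#' equiprobably over the same prefix; `"first"` always takes the leading
#' axis.
#'
#' @param explained Non-increasing vector of explained-variance fractions.
#' @param mode One of `"variance_weighted"`, `"uniform"`, `"first"`.
#' @param n_components Length of the candidate prefix (default 20).
#' @return The chosen axis index, or `NA_integer_` when no axis is
#'   available (degenerate node; the caller resamples features).
#' @export
select_component <- function(explained,
                             mode = c("variance_weighted", "uniform", "first"),
                             n_components = 20) {
  mode <- match.arg(mode)
  k <- min(length(explained), n_components)
  if (k == 0) return(NA_integer_)
  if (mode == "first" || k == 1) return(1L)
  if (mode == "uniform") return(sample.int(k, 1))
  sample.int(k, 1, prob = explained[seq_len(k)])
}

#' Split node samples at a uniform random threshold
#'
#' Draws `T ~ U(min(P), max(P))` over the axis projection `P` and
#' partitions into `P <= T` (left) and `P > T` (right).  A constant
#' projection, or a draw landing exactly on the maximum (leaving the right
#' side empty), is reported as degenerate rather than an error, since the
#' tree builder retries such splits with a fresh feature subset.
#'
#' @param projection Numeric vector of per-sample coordinates (length >= 2).
#' @return List with `threshold`, `left`, `right` (index vectors) and
#'   `degenerate` flag.
#' @export
split_on_threshold <- function(projection) {
  if (length(projection) < 2) stop("need at least 2 samples to split")
  mn <- min(projection)
  mx <- max(projection)
  if (!(mx > mn)) {
    return(list(threshold = NA_real_, left = integer(0), right = integer(0),
                degenerate = TRUE))
  }
  thr <- runif(1, mn, mx)
  left <- which(projection <= thr)
  right <- which(projection > thr)
  list(threshold = thr, left = left, right = right,
       degenerate = length(left) == 0 || length(right) == 0)
}
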