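#' Fit a subspace-ordination isolation forest
#'
#' Grows an ensemble of `t` isolation trees on an abundance table.  At
#' every node each tree draws a random feature subset (about 1\% of all
#' features, minimum 10, with replacement), renormalizes it to relative
#' abundances, ordinates the node's samples -- PCoA on Bray-Curtis
#' distances by default, or PCA for non-compositional tables -- picks one
#' of the first `n_components` ordination axes with probability
#' proportional to its variance explained, and splits the samples at a
#' uniform random threshold on that axis.  Recursion stops when a node
#' holds at most `r` samples or the tree reaches `max_depth`.  A sample's
#' anomaly score is \eqn{s(x) = 2^{-E(d(x))/c(n)}} where `E(d(x))` is its
#' average isolation depth across trees (unresolved leaves credited with
#' `c(leaf size)` extra depth) and `c(n)` is [average_path_length()];
#' scores near 1 mark easily isolated -- anomalous -- samples and scores
#' above `flag_threshold` (default 0.5) are flagged.
#'
#' Splitting on ordination axes of feature subsets, rather than single
#' features, lets the forest isolate samples whose anomaly is a
#' coordinated, community-wide compositional shift that no individual
#' taxon reveals, and makes splits robust to the sparsity of individual
#' taxa.
#'
#' @param x Numeric matrix or data frame, samples in rows, features
#'   (taxa) in columns; non-negative counts or relative abundances.  Row
#'   names are used as sample IDs.
#' @param t Number of trees (default 100).
#' @param max_depth Maximum tree depth `l` (default: number of samples).
#' @param psi_fraction,psi_min,with_replacement Feature-subset policy, see
#'   [subsample_features()].
#' @param r Node size at which recursion stops (a node with at most `r`
#'   samples becomes a leaf; default 1).
#' @param n_components Number of candidate ordination axes (default 20).
#' @param pc_selection Axis choice rule: `"variance_weighted"` (default),
#'   `"uniform"`, or `"first"`.
#' @param reduction `"pcoa_braycurtis"` (default; compositional data) or
#'   `"pca"` (general tables; enables out-of-sample [predict.kadaif()]).
#' @param renormalize Renormalize each node's feature subset to relative
#'   abundances.  Defaults to `TRUE` in Bray-Curtis mode and `FALSE` in
#'   PCA mode (where table-level normalization is a preprocessing choice).
#' @param flag_threshold Score above which a sample is flagged (default 0.5).
#' @param retry_limit Degenerate splits (constant projection or one empty
#'   side) are retried with a fresh feature subset this many times before
#'   the node becomes a leaf (default 3).
#' @param seed Master seed; every tree gets an independent substream, so
#'   results are reproducible for a fixed seed.  Drawn from the session
#'   RNG (and recorded) when omitted.
#' @return An object of class `kadaif` with components `scores`
#'   (named, in `(0, 1]`), `mean_depth`, `flagged`, `trees`, `c_n`, `n`,
#'   and `params`, with `print`, `summary`, `predict`, `plot`, `fitted`
#'   and `as.data.frame` methods.
#' @examples
#' x <- simulate_communities(30, 2, n_taxa = 120, anomaly_shift = 6,
#'                           seed = 1)
#' fit <- kadaif(rbind(x$normal, x$anomalous), t = 25, seed = 1)
#' fit
#' which(fit$flagged)
#' @seealso [isolation_forest()] for the single-feature baseline.
#' @export
kadaif <- function(x, t = 100, max_depth = nrow(x), psi_fraction = 0.01,
                   psi_min = 10, with_replacement = TRUE, r = 1,
                   n_components = 20,
                   pc_selection = c("variance_weighted", "uniform", "first"),
                   reduction = c("pcoa_braycurtis", "pca"),
                   renormalize = NULL, flag_threshold = 0.5,
                   retry_limit = 3, seed = NULL) {
  pc_selection <- match.arg(pc_selection)
  reduction <- match.arg(reduction)
  if (is.null(renormalize)) renormalize <- reduction == "pcoa_braycurtis"
  x <- validate_table(x)
  params <- make_params(
    n = nrow(x), n_features = ncol(x), t = t, max_depth = max_depth,
    psi_fraction = psi_fraction, psi_min = psi_min,
    with_replacement = with_replacement, r = r, n_components = n_components,
    pc_selection = pc_selection, reduction = reduction,
    renormalize = renormalize, flag_threshold = flag_threshold,
    retry_limit = retry_limit, seed = seed
  )
  fit_forest(x, params, match.call(), method = "kadaif")
}

#' Fit a standard (single-feature) isolation forest
#'
#' The classical isolation forest: each node splits on one uniformly
#' chosen feature at a threshold uniform over that feature's range in the
#' node.  Shares the stopping rules, depth adjustment and score formula
#' with [kadaif()], so the two are directly comparable; used as the
#' baseline method in the benchmarking scenarios.
#'
#' @inheritParams kadaif
#' @return A `kadaif` object (with `method = "isolation_forest"`).
#' @examples
#' fit <- isolation_forest(matrix(runif(200), 20, 10), t = 25, seed = 1)
#' summary(fit)
#' @export
isolation_forest <- function(x, t = 100, max_depth = nrow(x), r = 1,
                             flag_threshold = 0.5, retry_limit = 3,
                             seed = NULL) {
  x <- validate_table(x)
  params <- make_params(
    n = nrow(x), n_features = ncol(x), t = t, max_depth = max_depth,
    psi_fraction = 0, psi_min = 1, with_replacement = TRUE, r = r,
    n_components = 1, pc_selection = "first", reduction = "single_feature",
    renormalize = FALSE, flag_threshold = flag_threshold,
    retry_limit = retry_limit, seed = seed
  )
  fit_forest(x, params, match.call(), method = "isolation_forest")
}

validate_table <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix or data frame (samples x features)")
  }
  if (anyNA(x)) stop("`x` contains missing values")
  if (any(x < 0)) stop("`x` contains negative abundances")
  if (nrow(x) < 2) stop("need at least 2 samples to fit a forest")
  if (ncol(x) < 1) stop("need at least 1 feature")
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate sample IDs")
  x
}

make_params <- function(n, n_features, t, max_depth, psi_fraction, psi_min,
                        with_replacement, r, n_components, pc_selection,
                        reduction, renormalize, flag_threshold, retry_limit,
                        seed) {
  stopifnot(t >= 1, max_depth >= 1, psi_min >= 0, r >= 1, n_components >= 1,
            psi_fraction >= 0, psi_fraction <= 1, retry_limit >= 0,
            flag_threshold > 0, flag_threshold < 1)
  psi <- max(psi_min, round(psi_fraction * n_features))
  if (!with_replacement) psi <- min(psi, n_features)
  if (is.null(seed)) seed <- sample.int(2147483600L, 1)
  list(t = as.integer(t), max_depth = as.integer(max_depth),
       psi_fraction = psi_fraction, psi_min = as.integer(psi_min),
       psi = as.integer(psi), with_replacement = with_replacement,
       r = as.integer(r), n_components = as.integer(n_components),
       pc_selection = pc_selection, reduction = reduction,
       renormalize = renormalize, flag_threshold = flag_threshold,
       retry_limit = as.integer(retry_limit), seed = as.integer(seed))
}

fit_forest <- function(x, params, call, method) {
  n <- nrow(x)
  cpp_params <- list(
    psi = params$psi,
    with_replacement = params$with_replacement,
    r = params$r,
    max_depth = params$max_depth,
    n_components = params$n_components,
    pc_sel = match(params$pc_selection,
                   c("variance_weighted", "uniform", "first")) - 1L,
    reduction = match(params$reduction,
                      c("pcoa_braycurtis", "pca", "single_feature")) - 1L,
    renormalize = params$renormalize,
    retry_limit = params$retry_limit
  )
  depth_sum <- numeric(n)
  trees <- vector("list", params$t)
  for (i in seq_len(params$t)) {
    set.seed(derive_seed(params$seed, i))
    res <- .build_tree_cpp(x, cpp_params)
    depth_sum <- depth_sum + res$depths
    trees[[i]] <- res$tree
  }
  mean_depth <- depth_sum / params$t
  names(mean_depth) <- rownames(x)
  scores <- anomaly_score(mean_depth, n)
  structure(list(
    call = call,
    method = method,
    params = params,
    n = n,
    n_features = ncol(x),
    c_n = average_path_length(n),
    sample_ids = rownames(x),
    mean_depth = mean_depth,
    scores = scores,
    flagged = scores > params$flag_threshold,
    trees = trees
  ), class = "kadaif")
}

#' @export
print.kadaif <- function(x, ...) {
  label <- if (x$method == "kadaif") {
    sprintf("Subspace-ordination isolation forest (%s)", x$params$reduction)
  } else {
    "Isolation forest (single-feature baseline)"
  }
  cat(label, "\n", sep = "")
  cat(sprintf("  %d trees on %d samples x %d features; psi = %d, c(n) = %.4f\n",
              x$params$t, x$n, x$n_features, x$params$psi, x$c_n))
  cat(sprintf("  anomaly scores: %.3f - %.3f; %d sample(s) flagged (> %.2f)\n",
              min(x$scores), max(x$scores), sum(x$flagged),
              x$params$flag_threshold))
  invisible(x)
}

#' Summarize a fitted isolation forest
#'
#' @param object A `kadaif` fit.
#' @param ... Unused.
#' @return A list with score quantiles, the flag threshold, and the
#'   flagged sample IDs, printed compactly.
#' @export
summary.kadaif <- function(object, ...) {
  structure(list(
    method = object$method,
    n = object$n,
    n_features = object$n_features,
    t = object$params$t,
    score_quantiles = quantile(object$scores, c(0, .25, .5, .75, 1)),
    flag_threshold = object$params$flag_threshold,
    flagged = object$sample_ids[object$flagged]
  ), class = "summary.kadaif")
}

#' @export
print.summary.kadaif <- function(x, ...) {
  cat(sprintf("%s fit: %d samples x %d features, %d trees\n",
              if (x$method == "kadaif") "KADAIF" else "Isolation forest",
              x$n, x$n_features, x$t))
  cat("Anomaly score quantiles:\n")
  print(round(x$score_quantiles, 4))
  if (length(x$flagged)) {
    cat(sprintf("Flagged (> %.2f): %s\n", x$flag_threshold,
                paste(x$flagged, collapse = ", ")))
  } else {
    cat(sprintf("No samples flagged (> %.2f)\n", x$flag_threshold))
  }
  invisible(x)
}

#' @export
fitted.kadaif <- function(object, ...) object$scores

#' Per-sample score report as a data frame
#'
#' @param x A `kadaif` fit.
#' @param ... Unused.
#' @return Data frame with columns `sample_id`, `mean_depth`,
#'   `anomaly_score`, `flagged`.
#' @export
as.data.frame.kadaif <- function(x, ...) {
  data.frame(sample_id = x$sample_ids,
             mean_depth = unname(x$mean_depth),
             anomaly_score = unname(x$scores),
             flagged = unname(x$flagged),
             stringsAsFactors = FALSE)
}

#' Score new samples with a fitted forest
#'
#' Routes each new sample down every stored tree, projecting it through
#' the node's stored feature means and loadings, and converts the average
#' depth to an anomaly score.  Only available for `reduction = "pca"`
#' fits: PCoA embeds only the fitted samples and admits no out-of-sample
#' projection, so in Bray-Curtis mode new samples must be scored by
#' refitting on the enlarged table.
#'
#' @param object A `kadaif` fit with `reduction = "pca"`.
#' @param newdata Matrix or data frame with the same feature columns as
#'   the training table.
#' @param type `"score"` (default) or `"depth"` (mean isolation depth).
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
predict.kadaif <- function(object, newdata, type = c("score", "depth"), ...) {
  type <- match.arg(type)
  if (object$params$reduction != "pca") {
    stop("out-of-sample scoring requires a fit with reduction = \"pca\"; ",
         "in PCoA mode refit on the enlarged table instead")
  }
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_features) {
    stop(sprintf("`newdata` has %d features; the fit used %d",
                 ncol(newdata), object$n_features))
  }
  renorm <- object$params$renormalize
  depths <- vapply(seq_len(nrow(newdata)), function(i) {
    v <- newdata[i, ]
    mean(vapply(object$trees, function(tr) descend_tree(tr, v, renorm),
                numeric(1)))
  }, numeric(1))
  names(depths) <- rownames(newdata)
  if (type == "depth") depths else anomaly_score(depths, object$n)
}

descend_tree <- function(node, v, renorm) {
  depth <- 0
  while (node$kind == "split") {
    sub <- v[node$features]
    if (renorm) {
      s <- sum(sub)
      if (s > 0) sub <- sub / s
    }
    p <- sum((sub - node$means) * node$loading)
    node <- if (p <= node$threshold) node$left else node$right
    depth <- depth + 1
  }
  depth + average_path_length(node$size)
}

#' Plot anomaly scores of a fitted forest
#'
#' Scores in sample order with the flag threshold as a horizontal line;
#' flagged samples are drawn filled.
#'
#' @param x A `kadaif` fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @importFrom graphics abline points
#' @export
plot.kadaif <- function(x, ...) {
  plot(seq_len(x$n), x$scores, ylim = c(0, 1),
       xlab = "sample", ylab = "anomaly score s(x)",
       pch = ifelse(x$flagged, 19, 1), ...)
  abline(h = x$params$flag_threshold, lty = 2)
  invisible(x)
}
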