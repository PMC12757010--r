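# Independent oracles and small fixture builders used across test files.

# Naive double-loop Bray-Curtis, straight from the formula (with the
# package's zero-row conventions applied explicitly).
bc_naive <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      denom <- sum(x[i, ]) + sum(x[j, ])
      d[i, j] <- if (denom > 0) 1 - 2 * sum(pmin(x[i, ], x[j, ])) / denom else 0
    }
  }
  d
}

# Exhaustive concordant-pair ROC AUC (ties get half credit).
auc_pairs <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Random sparse compositional table.
random_composition <- function(n, m, sparsity = 0.3) {
  x <- matrix(rexp(n * m), n, m)
  x[matrix(runif(n * m) < sparsity, n, m)] <- 0
  rownames(x) <- paste0("s", seq_len(n))
  colnames(x) <- paste0("t", seq_len(m))
  renormalize_rows(x)
}

# Collect all leaves of a stored tree.
collect_leaves <- function(node, depth = 0) {
  if (node$kind == "leaf") {
    return(list(list(members = node$members, depth = node$depth,
                     edge_depth = depth, size = node$size)))
  }
  c(collect_leaves(node$left, depth + 1), collect_leaves(node$right, depth + 1))
}
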