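#' Harmonic number
#'
#' Computes \eqn{H(m) = \sum_{i=1}^m 1/i} by direct summation.  Used by
#' [average_path_length()]; summation (rather than the
#' \eqn{\ln m + \gamma} approximation) keeps the normalization constant
#' exact at the sample sizes this package works with.  Results are
#' memoized, and above `m = 1e6` the Euler--Mascheroni approximation
#' \eqn{\ln m + \gamma + 1/(2m)} is used (it agrees with summation to well
#' below 1e-6 at that point).
#'
#' @param m Positive integer (vectorized).
#' @return `sum(1/(1:m))` for each element of `m`.
#' @examples
#' harmonic_number(10)
#' @export
harmonic_number <- function(m) {
  if (any(m < 1) || any(m != floor(m))) {
    stop("`m` must consist of integers >= 1")
  }
  vapply(as.double(m), harmonic_one, numeric(1))
}

.harmonic_cache <- new.env(parent = emptyenv())

harmonic_one <- function(m) {
  if (m > 1e6) {
    # Euler-Mascheroni; error O(1/m^2) ~ 1e-12 here
    return(log(m) + 0.57721566490153286 + 1 / (2 * m))
  }
  key <- as.character(m)
  val <- .harmonic_cache[[key]]
  if (is.null(val)) {
    val <- sum(1 / seq_len(m))
    .harmonic_cache[[key]] <- val
  }
  val
}

#' Expected path length of an unsuccessful binary-search-tree search
#'
#' The normalization constant \eqn{c(n) = 2(H(n-1) - (n-1)/n)}: the average
#' number of random splits needed to isolate an arbitrary point among `n`,
#' used both to normalize isolation depths into anomaly scores and to
#' credit unresolved leaves.  By convention `c(0) = c(1) = 0` (a singleton
#' needs no split).
#'
#' @param n Non-negative integer (vectorized).
#' @return The constant \eqn{c(n)}.
#' @examples
#' average_path_length(2)   # exactly 1
#' average_path_length(256)
#' @export
average_path_length <- function(n) {
  if (any(n < 0) || any(n != floor(n))) {
    stop("`n` must consist of non-negative integers")
  }
  vapply(as.double(n), function(ni) {
    if (ni < 2) return(0)
    2 * (harmonic_one(ni - 1) - (ni - 1) / ni)
  }, numeric(1))
}

#' Convert a mean isolation depth to an anomaly score
#'
#' \eqn{s(x) = 2^{-E(d(x)) / c(n)}}: a sample isolated in, on average, as
#' few splits as a random point (`mean_depth == c(n)`) scores 0.5; samples
#' isolated much earlier approach 1 and are anomaly candidates.
#'
#' @param mean_depth Average isolation depth `E(d(x))` (vectorized,
#'   non-negative).
#' @param n Size of the training set the forest was grown on (`n >= 2`).
#' @return Scores in `(0, 1]`, strictly decreasing in `mean_depth`.
#' @examples
#' n <- 50
#' anomaly_score(average_path_length(n), n)  # 0.5 anchor
#' @export
anomaly_score <- function(mean_depth, n) {
  if (length(n) != 1 || n < 2) stop("`n` must be a single integer >= 2")
  if (any(mean_depth < 0)) stop("`mean_depth` must be non-negative")
  2^(-mean_depth / average_path_length(n))
}
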