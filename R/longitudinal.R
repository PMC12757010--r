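#' Sliding-window anomaly scores for a longitudinal series
#'
#' Real-time dysbiosis scoring: each focal sample is scored by fitting
#' the chosen forest on the samples collected in the `window_days` days
#' preceding it (timestamps in `(t - window_days, t]`, the focal sample
#' included), so the score measures how unusual the sample is relative to
#' the subject's own recent history.  Focal samples with fewer than
#' `min_history` in-window predecessors -- e.g. the head of the series --
#' get `NA`: with too few samples the depth statistics are meaningless.
#' Scoring is causal: a sample's score never depends on later samples,
#' and each focal fit gets its own seed derived from `seed`, so scoring a
#' prefix of the series reproduces the prefix's scores exactly.
#'
#' @param x Feature table (samples x taxa), one row per collected sample.
#' @param time Timestamps, one per row: `Date` or numeric day index.
#'   Rows are processed in time order (ties broken by row name).
#' @param window_days Window length in days (default 60).
#' @param min_history Minimum number of in-window predecessors required to
#'   score a focal sample (default 20).
#' @param method `"kadaif"` (default) or `"baseline_if"`.
#' @param t Trees per forest fit (default 100).
#' @param rolling_k Window (in defined samples) for the smoothed score
#'   column (default 7); see [rolling_mean()].
#' @param seed Master seed.
#' @param ... Extra arguments passed to [kadaif()].
#' @return Data frame, in time order, with columns `sample_id`, `time`,
#'   `n_history`, `score`, `rolling_score`, `defined`.
#' @examples
#' \donttest{
#' sim <- simulate_communities(80, 0, n_taxa = 150, seed = 1)
#' out <- sliding_window_scores(sim$normal, time = seq_len(80),
#'                              min_history = 10, t = 20, seed = 1)
#' head(subset(out, defined))
#' }
#' @export
sliding_window_scores <- function(x, time, window_days = 60,
                                  min_history = 20,
                                  method = c("kadaif", "baseline_if"),
                                  t = 100, rolling_k = 7, seed = NULL, ...) {
  method <- match.arg(method)
  x <- validate_table(x)
  if (length(time) != nrow(x)) stop("`time` must have one entry per sample")
  if (nrow(x) == 0) stop("empty series")
  time_num <- as.numeric(time)
  if (anyNA(time_num)) stop("timestamps must be dates or numbers")
  ord <- order(time_num, rownames(x))
  x <- x[ord, , drop = FALSE]
  time_num <- time_num[ord]
  if (is.null(seed)) seed <- sample.int(2147483600L, 1)

  n <- nrow(x)
  score <- rep(NA_real_, n)
  n_history <- integer(n)
  for (i in seq_len(n)) {
    prev <- which(seq_len(n) < i &
                    time_num > time_num[i] - window_days &
                    time_num <= time_num[i])
    n_history[i] <- length(prev)
    if (length(prev) < min_history) next
    tab <- x[c(prev, i), , drop = FALSE]
    fit_seed <- derive_seed(seed, i)
    fit <- if (method == "kadaif") {
      kadaif(tab, t = t, seed = fit_seed, ...)
    } else {
      isolation_forest(tab, t = t, seed = fit_seed)
    }
    score[i] <- unname(fit$scores[nrow(tab)])
  }
  data.frame(sample_id = rownames(x), time = time[ord],
             n_history = n_history, score = score,
             rolling_score = rolling_mean(score, rolling_k),
             defined = !is.na(score), stringsAsFactors = FALSE)
}

#' Rolling mean over the last defined values
#'
#' Element `i` is the mean of the last `min(m, k)` defined (non-`NA`)
#' values up to and including position `i`, where `m` is how many defined
#' values have been seen so far -- i.e. a trailing average over defined
#' samples, using the available prefix at the series head.  Positions
#' whose own input is `NA` stay `NA`, mirroring the undefined head of a
#' sliding-window score series.
#'
#' @param values Numeric vector, possibly with `NA`s.
#' @param k Window length in defined samples (default 7; `k = 1` is the
#'   identity).
#' @return Numeric vector of the same length.
#' @examples
#' rolling_mean(1:7, k = 7)[7]  # 4
#' @export
rolling_mean <- function(values, k = 7) {
  if (k < 1 || k != floor(k)) stop("`k` must be a positive integer")
  out <- rep(NA_real_, length(values))
  buf <- numeric(0)
  for (i in seq_along(values)) {
    v <- values[i]
    if (is.na(v)) next
    buf <- c(buf, v)
    if (length(buf) > k) buf <- buf[-1]
    out[i] <- mean(buf)
  }
  out
}
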