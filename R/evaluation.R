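#' ROC AUC by the Mann-Whitney formulation
#'
#' The probability that a uniformly chosen anomalous sample's score
#' exceeds a uniformly chosen normal sample's score, with ties counted
#' one half.  Computed from rank sums, so it is exact and invariant under
#' any strictly monotone transform of the scores.
#'
#' @param scores Numeric vector.
#' @param labels Logical (or 0/1) vector, `TRUE` = anomalous; both
#'   classes must be present.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(labels) || anyNA(scores)) {
    stop("`scores` and `labels` must be equal-length and complete")
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties with half credit
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-class anomaly-score distribution summary
#'
#' @param scores Numeric scores.
#' @param labels Logical/0-1 class labels (`TRUE` = anomalous).
#' @param threshold Flagging threshold (default 0.5).
#' @return Data frame with one row per class: n, mean, quartiles, and the
#'   fraction of the class flagged above `threshold`.
#' @export
score_summary <- function(scores, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  cls <- function(keep) {
    s <- scores[keep]
    data.frame(n = length(s), mean = mean(s), q25 = quantile(s, .25),
               median = median(s), q75 = quantile(s, .75),
               flag_rate = mean(s > threshold), row.names = NULL)
  }
  out <- rbind(cls(!labels), cls(labels))
  cbind(class = c("normal", "anomalous"), out)
}

#' Run a scenario x method benchmark grid
#'
#' For each grid cell (anomaly fraction x contamination level/factor) the
#' harness builds `repetitions` independent labeled pools, scores every
#' pool with each method, pools all `repetitions * pool_size` scores with
#' their ground-truth labels, and reports the pooled ROC AUC per cell --
#' the same protocol as repeated-pool mislabeling/contamination
#' benchmarks (50 pools of 50 give 2500 pooled scores).  Pools are
#' derived from the master seed independently of the method, so methods
#' are compared on identical pools.
#'
#' @param scenario One of `"mislabeling"`, `"contamination_mixture"`,
#'   `"contamination_inflation"`.
#' @param methods Character vector from `"kadaif"`, `"baseline_if"`.
#' @param fractions Anomalous-fraction grid (default 0.02).
#' @param levels Contamination levels `p` (mixture) or inflation factors;
#'   ignored for mislabeling.
#' @param repetitions Pools per cell (default 50).
#' @param pool_size Samples per pool (default 50).
#' @param communities Source communities: a `community_sim` or a list with
#'   `normal` and `anomalous` matrices.  When omitted, a strongly shifted
#'   synthetic pair is simulated (200 normal / 100 anomalous samples,
#'   4-fold shift on a disjoint-support 20\% taxon block).
#' @param t Trees per forest (default 100).
#' @param seed Master seed (default 1).
#' @param detail Also return pooled score/label vectors per cell.
#' @param ... Extra arguments passed to [kadaif()].
#' @return Data frame with columns `scenario`, `method`, `fraction`,
#'   `level`, `auc`, `n_scores`, `repetitions`; attribute
#'   `"per_repetition"` holds per-pool AUCs (diagnostic only), and, with
#'   `detail = TRUE`, attribute `"pooled"` the pooled vectors.
#' @examples
#' \donttest{
#' res <- run_benchmark("mislabeling", fractions = 0.1, repetitions = 3,
#'                      t = 20, seed = 1)
#' res$auc
#' }
#' @export
run_benchmark <- function(scenario = c("mislabeling", "contamination_mixture",
                                       "contamination_inflation"),
                          methods = c("kadaif", "baseline_if"),
                          fractions = 0.02, levels = NULL,
                          repetitions = 50, pool_size = 50,
                          communities = NULL, t = 100, seed = 1,
                          detail = FALSE, ...) {
  scenario <- match.arg(scenario)
  methods <- match.arg(methods, c("kadaif", "baseline_if"),
                       several.ok = TRUE)
  stopifnot(repetitions >= 1, length(fractions) >= 1)
  if (is.null(levels)) {
    levels <- if (scenario == "mislabeling") NA_real_ else
      stop(sprintf("`levels` is required for scenario \"%s\"", scenario))
  }
  if (is.null(communities)) {
    communities <- simulate_communities(
      n_normal = 200, n_anomalous = 100, anomaly_shift = 4,
      exclusive_shift = TRUE, seed = derive_seed(seed, 0)
    )
  }
  normal <- communities$normal
  anomalous <- communities$anomalous

  grid <- expand.grid(fraction = fractions, level = levels,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  per_rep <- list()
  pooled <- list()
  for (ci in seq_len(nrow(grid))) {
    fraction <- grid$fraction[ci]
    level <- grid$level[ci]
    cell_scores <- setNames(rep(list(numeric(0)), length(methods)), methods)
    cell_labels <- numeric(0)
    cell_rep_auc <- setNames(rep(list(numeric(0)), length(methods)), methods)
    for (rep_i in seq_len(repetitions)) {
      pool <- switch(scenario,
        mislabeling = mislabeling_pool(
          normal, anomalous, fraction, pool_size,
          seed = derive_seed(seed, ci, rep_i, 1)),
        contamination_mixture = contamination_pool(
          normal, anomalous, fraction, level, pool_size,
          seed = derive_seed(seed, ci, rep_i, 1)),
        contamination_inflation = inflation_pool(
          normal, fraction, level, pool_size = pool_size,
          seed = derive_seed(seed, ci, rep_i, 1))
      )
      cell_labels <- c(cell_labels, pool$labels)
      score_seed <- derive_seed(seed, ci, rep_i, 2)
      for (m in methods) {
        fit <- if (m == "kadaif") {
          kadaif(pool$table, t = t, seed = score_seed, ...)
        } else {
          isolation_forest(pool$table, t = t, seed = score_seed)
        }
        cell_scores[[m]] <- c(cell_scores[[m]], unname(fit$scores))
        cell_rep_auc[[m]] <- c(cell_rep_auc[[m]],
                               roc_auc(fit$scores, pool$labels))
      }
    }
    for (m in methods) {
      rows[[length(rows) + 1]] <- data.frame(
        scenario = scenario, method = m, fraction = fraction, level = level,
        auc = roc_auc(cell_scores[[m]], cell_labels),
        n_scores = length(cell_labels), repetitions = repetitions,
        stringsAsFactors = FALSE)
      per_rep[[length(per_rep) + 1]] <- data.frame(
        scenario = scenario, method = m, fraction = fraction, level = level,
        repetition = seq_len(repetitions), auc = cell_rep_auc[[m]],
        stringsAsFactors = FALSE)
      if (detail) {
        pooled[[paste(m, fraction, level, sep = "_")]] <-
          list(scores = cell_scores[[m]], labels = cell_labels)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "per_repetition") <- do.call(rbind, per_rep)
  if (detail) attr(out, "pooled") <- pooled
  out
}
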