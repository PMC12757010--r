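#' Simulate sparse compositional communities with a planted anomalous group
#'
#' Draws zero-inflated log-normal taxon profiles.  A per-taxon baseline
#' log-abundance `b_j ~ N(log_mean, taxon_sd)` (shared by both groups)
#' gives a realistic rank-abundance curve -- with the default
#' `taxon_sd = 2` taxon abundances span about four orders of magnitude,
#' as real 16S tables do; each sample then adds i.i.d. noise
#' `N(0, log_sd)` on the log scale, zeroes taxa by abundance-dependent
#' dropout, and is renormalized to relative abundances.  Dropout follows
#' `P(zero) = plogis(qlogis(sparsity) - b_j)`: a taxon of average
#' abundance is absent with probability about `sparsity`, rare taxa drop
#' out more often and dominant taxa are consistently present, so samples
#' share a core community the way real 16S tables do.
#' The anomalous group differs in two tunable ways, emulating the two
#' signatures of real dysbiotic groups: a compositional shift
#' (`anomaly_shift` multiplies the baseline abundance of a fixed random
#' block of `shift_taxa_fraction` of the taxa) and over-dispersion
#' (`anomaly_dispersion` multiplies the log-scale noise SD, so anomalous
#' samples scatter in many directions -- the Anna Karenina pattern).  With
#' `exclusive_shift = TRUE` the shifted taxon block is zeroed in normal
#' samples, giving the two groups disjoint support on that block.
#'
#' @param n_normal,n_anomalous Number of samples per group.
#' @param n_taxa Number of taxa (default 500).
#' @param log_mean Mean of per-taxon baseline log-abundances (default 0).
#' @param taxon_sd SD of per-taxon baseline log-abundances (default 2):
#'   controls how steep the rank-abundance curve is.
#' @param log_sd Per-sample log-scale noise SD (default 1).
#' @param sparsity Dropout probability for a taxon of average baseline
#'   abundance (default 0.7, typical of 16S tables); actual per-taxon
#'   dropout is abundance-dependent (see Details).
#' @param shift_taxa_fraction Fraction of taxa in the shifted block
#'   (default 0.2).
#' @param anomaly_shift Multiplicative abundance effect on the shifted
#'   block in anomalous samples (default 1 = no shift).
#' @param anomaly_dispersion Log-SD inflation factor for anomalous samples
#'   (default 1 = none; must be >= 1).
#' @param exclusive_shift Zero the shifted block in normal samples so the
#'   groups have disjoint support there (default `FALSE`).
#' @param seed Optional seed for reproducibility.
#' @return List of class `community_sim` with `normal` and `anomalous`
#'   relative-abundance matrices (rows sum to 1), and `shifted_taxa`, the
#'   indices of the shifted block.
#' @examples
#' sim <- simulate_communities(20, 5, n_taxa = 200, anomaly_shift = 4,
#'                             seed = 42)
#' rowSums(sim$normal)[1:3]
#' @export
simulate_communities <- function(n_normal, n_anomalous, n_taxa = 500,
                                 log_mean = 0, taxon_sd = 2, log_sd = 1,
                                 sparsity = 0.7,
                                 shift_taxa_fraction = 0.2,
                                 anomaly_shift = 1, anomaly_dispersion = 1,
                                 exclusive_shift = FALSE, seed = NULL) {
  stopifnot(n_normal >= 0, n_anomalous >= 0, n_taxa >= 1,
            sparsity >= 0, sparsity < 1, anomaly_dispersion >= 1,
            anomaly_shift > 0, shift_taxa_fraction >= 0,
            shift_taxa_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  baseline <- rnorm(n_taxa, log_mean, taxon_sd)
  n_shift <- round(shift_taxa_fraction * n_taxa)
  shifted <- if (n_shift > 0) sample.int(n_taxa, n_shift) else integer(0)

  draw_group <- function(n, shift, disp, drop_shifted) {
    if (n == 0) {
      return(matrix(numeric(0), 0, n_taxa,
                    dimnames = list(NULL, paste0("taxon", seq_len(n_taxa)))))
    }
    b <- baseline
    if (shift != 1) b[shifted] <- b[shifted] + log(shift)
    logab <- matrix(rnorm(n * n_taxa, 0, log_sd * disp), n, n_taxa,
                    byrow = FALSE)
    ab <- exp(sweep(logab, 2, b, `+`))
    # abundance-dependent dropout: rare taxa vanish, dominant taxa persist
    p_zero <- if (sparsity > 0) {
      stats::plogis(stats::qlogis(sparsity) - (b - log_mean))
    } else {
      rep(0, n_taxa)
    }
    keep <- matrix(rbinom(n * n_taxa, 1, rep(1 - p_zero, each = n)),
                   n, n_taxa)
    ab <- ab * keep
    if (drop_shifted) ab[, shifted] <- 0
    dimnames(ab) <- list(NULL, paste0("taxon", seq_len(n_taxa)))
    renormalize_rows(ab)
  }

  normal <- draw_group(n_normal, 1, 1, exclusive_shift)
  anomalous <- draw_group(n_anomalous, anomaly_shift, anomaly_dispersion,
                          FALSE)
  if (n_normal > 0) rownames(normal) <- paste0("N", seq_len(n_normal))
  if (n_anomalous > 0) rownames(anomalous) <- paste0("A", seq_len(n_anomalous))
  structure(list(normal = normal, anomalous = anomalous,
                 shifted_taxa = sort(shifted)),
            class = "community_sim")
}

# round-half-up count of anomalous pool members, floored at 1
anomaly_count <- function(fraction, pool_size) {
  max(1L, as.integer(floor(fraction * pool_size + 0.5)))
}

new_pool <- function(table, labels, scenario, meta) {
  rownames(table) <- sprintf("pool%03d_%s", seq_len(nrow(table)),
                             ifelse(labels, "anom", "norm"))
  structure(list(table = table, labels = labels, scenario = scenario,
                 meta = meta), class = "labeled_pool")
}

#' @export
print.labeled_pool <- function(x, ...) {
  cat(sprintf("Labeled pool (%s): %d samples x %d features, %d anomalous\n",
              x$scenario, nrow(x$table), ncol(x$table), sum(x$labels)))
  invisible(x)
}

#' Simulate a longitudinal series with a planted disturbance
#'
#' One sample per day for `n_days` days, drawn from the normal community
#' distribution of [simulate_communities()], except during
#' `anomaly_days`, whose samples come from the dispersion-inflated (and
#' optionally shifted) anomalous distribution with the same per-taxon
#' baseline -- emulating a transient dysbiosis episode (dietary change,
#' infection) within an otherwise stable personal microbiome.  Samples
#' are i.i.d. given the group; day-to-day autocorrelation is not
#' modeled.
#'
#' @param n_days Series length in days (default 200).
#' @param anomaly_days Integer vector of disturbed days (default 80:90).
#' @param anomaly_dispersion Log-SD inflation during the disturbance
#'   (default 3).
#' @param anomaly_shift Abundance shift of the disturbed block (default 1:
#'   dispersion-only disturbance).
#' @param ... Further arguments for [simulate_communities()].
#' @param seed Optional seed.
#' @return List of class `longitudinal_sim` with `table` (one row per
#'   day), `day` (1-based day index), and `anomaly_days`.
#' @examples
#' series <- simulate_longitudinal(n_days = 60, anomaly_days = 40:45,
#'                                 n_taxa = 100, seed = 1)
#' dim(series$table)
#' @export
simulate_longitudinal <- function(n_days = 200, anomaly_days = 80:90,
                                  anomaly_dispersion = 3, anomaly_shift = 1,
                                  ..., seed = NULL) {
  stopifnot(n_days >= 1, all(anomaly_days >= 1), all(anomaly_days <= n_days))
  anomaly_days <- sort(unique(anomaly_days))
  k <- length(anomaly_days)
  sim <- simulate_communities(n_days - k, k,
                              anomaly_shift = anomaly_shift,
                              anomaly_dispersion = anomaly_dispersion,
                              ..., seed = seed)
  tab <- matrix(0, n_days, ncol(sim$normal),
                dimnames = list(sprintf("day%03d", seq_len(n_days)),
                                colnames(sim$normal)))
  if (k > 0) tab[anomaly_days, ] <- sim$anomalous
  if (n_days - k > 0) tab[setdiff(seq_len(n_days), anomaly_days), ] <- sim$normal
  structure(list(table = tab, day = seq_len(n_days),
                 anomaly_days = anomaly_days),
            class = "longitudinal_sim")
}

#' Build a mislabeling pool
#'
#' Draws a pool of `pool_size` samples in which most members come from the
#' normal source table and `round(fraction * pool_size)` (at least 1) come
#' from the anomalous source -- the situation where a few samples in an
#' otherwise homogeneous dataset are mislabeled or swapped.  Members are
#' drawn without replacement within a pool and the pool order is shuffled.
#'
#' @param normal,anomalous Source relative-abundance matrices (same
#'   columns), e.g. from [simulate_communities()].
#' @param fraction Anomalous fraction of the pool, in `(0, 0.5]`.
#' @param pool_size Pool size (default 50).
#' @param seed Optional seed.
#' @return A `labeled_pool`: list with `table`, logical `labels`
#'   (`TRUE` = anomalous), `scenario`, `meta`.
#' @examples
#' sim <- simulate_communities(60, 30, n_taxa = 100, seed = 1)
#' pool <- mislabeling_pool(sim$normal, sim$anomalous, fraction = 0.02,
#'                         seed = 2)
#' sum(pool$labels)  # 1
#' @export
mislabeling_pool <- function(normal, anomalous, fraction, pool_size = 50,
                             seed = NULL) {
  stopifnot(fraction > 0, fraction <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  k <- anomaly_count(fraction, pool_size)
  if (nrow(anomalous) < k || nrow(normal) < pool_size - k) {
    stop("not enough source samples for the requested pool")
  }
  tab <- rbind(normal[sample.int(nrow(normal), pool_size - k), , drop = FALSE],
               anomalous[sample.int(nrow(anomalous), k), , drop = FALSE])
  labels <- c(rep(FALSE, pool_size - k), rep(TRUE, k))
  ord <- sample.int(pool_size)
  new_pool(tab[ord, , drop = FALSE], labels[ord], "mislabeling",
           list(fraction = fraction, pool_size = pool_size))
}

#' Mix an anomalous profile into a normal one
#'
#' Returns `(1 - p) * normal + p * anomalous` elementwise: the profile of
#' a normal sample contaminated at level `p` by an anomalous community.
#' When both inputs sum to 1 the mixture does too.
#'
#' @param normal_profile,anomalous_profile Non-negative vectors of equal
#'   length (relative abundances).
#' @param p Contamination level in `[0, 1]`.
#' @return The mixed profile.
#' @examples
#' contaminate_mixture(c(1, 0), c(0, 1), p = 0.3)
#' @export
contaminate_mixture <- function(normal_profile, anomalous_profile, p) {
  if (length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop("contamination level `p` must be in [0, 1]")
  }
  if (length(normal_profile) != length(anomalous_profile)) {
    stop("profiles must have the same length")
  }
  (1 - p) * normal_profile + p * anomalous_profile
}

#' Build a mixture-contamination pool
#'
#' Draws `pool_size` members from the normal source and contaminates
#' `round(fraction * pool_size)` of them at level `p`: each contaminated
#' member is blended ([contaminate_mixture()]) with its own independently
#' drawn anomalous profile.
#'
#' @inheritParams mislabeling_pool
#' @param p Contamination level in `[0, 1]`.
#' @return A `labeled_pool`; `labels` mark the contaminated members.
#' @export
contamination_pool <- function(normal, anomalous, fraction, p,
                               pool_size = 50, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  if (nrow(normal) < pool_size) stop("not enough normal source samples")
  if (nrow(anomalous) < 1) stop("need at least one anomalous source sample")
  k <- anomaly_count(fraction, pool_size)
  tab <- normal[sample.int(nrow(normal), pool_size), , drop = FALSE]
  hit <- sample.int(pool_size, k)
  for (i in hit) {
    partner <- anomalous[sample.int(nrow(anomalous), 1), ]
    tab[i, ] <- contaminate_mixture(tab[i, ], partner, p)
  }
  labels <- seq_len(pool_size) %in% hit
  new_pool(tab, labels, "contamination_mixture",
           list(fraction = fraction, p = p, pool_size = pool_size))
}

#' Inflate a random subset of taxa in a profile
#'
#' Multiplies `max(min_taxa, round(taxa_fraction * n_taxa))` randomly
#' chosen taxa by `factor` and renormalizes, emulating contamination by a
#' few taxa in the sample that bloom and become dominant.  Taxa are drawn
#' uniformly among those present in the profile (inflating an absent
#' taxon would be a no-op), falling back to all taxa if fewer are present
#' than requested.
#'
#' @param profile Non-negative abundance vector.
#' @param taxa_fraction Fraction of taxa to inflate (default 0.01).
#' @param min_taxa Minimum number of inflated taxa (default 5).
#' @param factor Multiplicative inflation factor (>= 1).
#' @return The inflated, renormalized profile.
#' @examples
#' p <- rep(1 / 100, 100)
#' sum(inflate_taxa(p, factor = 20) > 1 / 100)  # 5 inflated taxa
#' @export
inflate_taxa <- function(profile, taxa_fraction = 0.01, min_taxa = 5,
                         factor = 1) {
  if (length(factor) != 1 || is.na(factor) || factor < 1) {
    stop("inflation `factor` must be >= 1")
  }
  if (any(profile < 0)) stop("profile must be non-negative")
  m <- min(length(profile), max(min_taxa, round(taxa_fraction * length(profile))))
  present <- which(profile > 0)
  idx <- if (length(present) >= m) {
    present[sample.int(length(present), m)]
  } else {
    sample.int(length(profile), m)
  }
  profile[idx] <- profile[idx] * factor
  s <- sum(profile)
  if (s > 0) profile <- profile / s
  profile
}

#' Build a taxon-inflation contamination pool
#'
#' Draws `pool_size` members from the normal source; in
#' `round(fraction * pool_size)` of them, about 1\% of taxa (minimum 5)
#' are inflated by `factor` ([inflate_taxa()]).
#'
#' @inheritParams mislabeling_pool
#' @param factor Inflation factor passed to [inflate_taxa()].
#' @param taxa_fraction,min_taxa Passed to [inflate_taxa()].
#' @return A `labeled_pool`; `labels` mark the inflated members.
#' @export
inflation_pool <- function(normal, fraction, factor, taxa_fraction = 0.01,
                           min_taxa = 5, pool_size = 50, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  if (nrow(normal) < pool_size) stop("not enough normal source samples")
  k <- anomaly_count(fraction, pool_size)
  tab <- normal[sample.int(nrow(normal), pool_size), , drop = FALSE]
  hit <- sample.int(pool_size, k)
  for (i in hit) {
    tab[i, ] <- inflate_taxa(tab[i, ], taxa_fraction, min_taxa, factor)
  }
  labels <- seq_len(pool_size) %in% hit
  new_pool(tab, labels, "contamination_inflation",
           list(fraction = fraction, factor = factor, pool_size = pool_size))
}
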