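# Feature enrichment around validated breakpoints.
#
# A window is centered on each breakpoint and the feature bases inside it
# are counted; the null is built by repeatedly drawing pseudo-breakpoints
# uniformly in a control region and recording the mean window density per
# repetition. Enrichment ratio = mean real density / mean pseudo density;
# significance by two-sided one-sample t-test of the per-breakpoint real
# densities against the null grand mean.

# Prefix-sum lookup of merged-feature coverage, for O(1) window densities.
feature_cumsum <- function(feature_intervals, chrom_length) {
  m <- merge_intervals(feature_intervals)
  cov <- integer(chrom_length)
  if (nrow(m)) {
    m[, start := pmax(start, 1L)]
    m[, end := pmin(end, as.integer(chrom_length))]
    for (i in seq_len(nrow(m))) cov[m$start[i]:m$end[i]] <- 1L
  }
  c(0, cumsum(cov))
}

#' Feature density around breakpoints
#'
#' Fraction of window bases covered by (merged) feature intervals; the
#' window is `[pos - window/2, pos + window/2)`, truncated at chromosome
#' ends with the denominator adjusted.
#'
#' @param positions breakpoint positions (1-based).
#' @param feature_intervals data.table with `start`, `end` (overlaps are
#'   merged before counting).
#' @param window window size in bp (> 0).
#' @param chrom_length chromosome length (or a `ReferenceBundle`).
#' @param cum optional precomputed [feature_cumsum()] lookup.
#' @return numeric densities in [0, 1], one per position.
#' @export
feature_density <- function(positions, feature_intervals, window,
                            chrom_length, cum = NULL) {
  if (window <= 0) stopf("window must be positive")
  if (inherits(chrom_length, "ReferenceBundle")) chrom_length <- chrom_length$length
  if (any(positions < 1 | positions > chrom_length))
    stopf("breakpoint outside chromosome")
  cum <- cum %||% feature_cumsum(feature_intervals, chrom_length)
  half <- window / 2
  lo <- pmax(1, ceiling(positions - half))
  hi <- pmin(chrom_length, ceiling(positions + half) - 1)
  (cum[hi + 1] - cum[lo]) / (hi - lo + 1)
}

#' Resampled pseudo-breakpoint null distribution
#'
#' Each repetition draws `n_pseudo` pseudo-breakpoints uniformly in the
#' control region and records the mean feature density of their windows;
#' the returned vector of repetition means is the null distribution of the
#' mean density. Deterministic for a fixed seed.
#'
#' @param feature_intervals feature track (`start`, `end`).
#' @param control_region `c(start, end)` resampling space.
#' @param window window size in bp.
#' @param chrom_length chromosome length (or a `ReferenceBundle`).
#' @param n_pseudo pseudo-breakpoints per repetition (default 10000).
#' @param reps repetitions (default 1000).
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return numeric vector of length `reps` (per-rep mean densities).
#' @export
resample_null <- function(feature_intervals, control_region, window,
                          chrom_length, n_pseudo = 10000L, reps = 1000L,
                          seed = NULL) {
  if (inherits(chrom_length, "ReferenceBundle")) chrom_length <- chrom_length$length
  span <- control_region[2] - control_region[1] + 1
  if (span <= 0) stopf("control region span must be positive")
  if (!is.null(seed)) set.seed(seed)
  cum <- feature_cumsum(feature_intervals, chrom_length)
  vapply(seq_len(reps), function(r) {
    pos <- control_region[1] + floor(runif(n_pseudo) * span)
    mean(feature_density(pos, NULL, window, chrom_length, cum = cum))
  }, numeric(1))
}

#' Enrichment test of real breakpoints against the resampled null
#'
#' Ratio = mean real density / grand mean of the null distribution;
#' two-sided one-sample t-test of the per-breakpoint real densities against
#' the null grand mean. When all real densities are identical the variance
#' is degenerate and p is reported as 1 with a warning.
#'
#' @param breakpoints real breakpoint positions (>= 2).
#' @param feature_intervals feature track.
#' @param window window size in bp.
#' @param chrom_length chromosome length (or a `ReferenceBundle`).
#' @param null output of [resample_null()].
#' @param feature feature name recorded in the result.
#' @return one-row data.table of class `EnrichmentResult`: `feature`,
#'   `window`, `n_breakpoints`, `ratio`, `p_value`, `real_mean`,
#'   `null_mean`, `null_sd`.
#' @export
enrichment_test <- function(breakpoints, feature_intervals, window,
                            chrom_length, null, feature = "feature") {
  if (length(breakpoints) < 2L)
    stopf("need at least 2 real breakpoints for the t-test")
  dens <- feature_density(breakpoints, feature_intervals, window, chrom_length)
  mu0 <- mean(null)
  ratio <- if (mu0 > 0) mean(dens) / mu0 else NA_real_
  if (stats::sd(dens) == 0) {
    warnf("all real breakpoint densities identical; degenerate variance, p = 1")
    p <- 1
  } else {
    p <- t.test(dens, mu = mu0)$p.value
  }
  res <- data.table(feature = feature, window = as.integer(window),
                    n_breakpoints = length(breakpoints), ratio = ratio,
                    p_value = p, real_mean = mean(dens), null_mean = mu0,
                    null_sd = stats::sd(null))
  structure(res, class = c("EnrichmentResult", class(res)))
}

#' Gene-body disruption test
#'
#' Counts breakpoints falling inside (merged) gene bodies and computes the
#' upper-tail binomial probability of at least that many hits under uniform
#' placement, with success probability the gene-body base fraction of the
#' region.
#'
#' @param breakpoints breakpoint positions.
#' @param gene_intervals gene track (`start`, `end`).
#' @param region `c(start, end)` region the breakpoints live in.
#' @return list: `k` (disrupted), `n` (total breakpoints), `gene_fraction`,
#'   `p_value`.
#' @export
gene_disruption_test <- function(breakpoints, gene_intervals, region) {
  if (region[2] <= region[1]) stopf("empty region")
  m <- merge_intervals(gene_intervals)
  frac <- interval_bases(m, region) / (region[2] - region[1] + 1)
  n <- length(breakpoints)
  inside <- vapply(breakpoints, function(p) any(m$start <= p & m$end >= p),
                   logical(1))
  k <- sum(inside)
  p <- if (k == 0L) 1 else pbinom(k - 1L, n, frac, lower.tail = FALSE)
  list(k = k, n = n, gene_fraction = frac, p_value = p)
}
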