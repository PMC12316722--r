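# Read-depth dosage profiles and mini structural typing.
#
# Coverage is counted per non-overlapping bin from the leftmost position of
# each primary alignment, normalized to a non-carrier control from the same
# cohort with the euploid expectation fixed at 2 (so one extra copy reads as
# 3, a hemizygous loss as 1), and samples are classified into one of six
# structural types of the mini complement by nearest expected-dosage
# template.

#' Bin primary-alignment counts
#'
#' Each primary alignment is assigned to exactly one bin by its leftmost
#' mapped position; supplementary and secondary records are ignored so split
#' reads are not double-counted.
#'
#' @param aln alignment data.table (one sample).
#' @param bin_size bin width in bp (> 0).
#' @param chrom_length chromosome length (a `ReferenceBundle` is accepted);
#'   determines the number of bins.
#' @return object of class `CoverageVector`: data.table (`chrom`, `bin`
#'   0-based index, `start`, `end` 1-based inclusive, `count`) with
#'   attributes `bin_size` and `total`.
#' @export
bin_coverage <- function(aln, bin_size, chrom_length) {
  if (bin_size <= 0) stopf("bin_size must be positive")
  if (inherits(chrom_length, "ReferenceBundle")) {
    chrom <- chrom_length$chrom
    chrom_length <- chrom_length$length
  } else {
    chrom <- if (nrow(aln)) aln$rname[1] else "Chr1"
  }
  n_bins <- ceiling(chrom_length / bin_size)
  cov <- data.table(chrom = chrom, bin = seq_len(n_bins) - 1L)
  cov[, start := bin * bin_size + 1L]
  cov[, end := pmin((bin + 1L) * bin_size, as.integer(chrom_length))]
  prim <- aln[is_primary(flag)]
  cnt <- prim[, .N, by = .(bin = (pos - 1L) %/% as.integer(bin_size))]
  cov[cnt, count := i.N, on = "bin"]
  cov[is.na(count), count := 0L]
  setattr(cov, "bin_size", as.integer(bin_size))
  setattr(cov, "total", sum(cov$count))
  setattr(cov, "class", c("CoverageVector", class(cov)))
  cov[]
}

#' Normalize a sample against a non-carrier control
#'
#' Relative dosage per bin: `2 * (sample_count / sample_scale) /
#' (control_count / control_scale)`, so a euploid bin reads 2, one extra
#' copy 3, a hemizygous loss 1. The per-sample scale is the median bin
#' count: on a real-size genome (aneuploid segment a few percent of the
#' genome) this is indistinguishable from total-read scaling, while on the
#' toy genome -- where the mini region is a third of the chromosome -- it
#' keeps the euploid expectation pinned at 2 instead of letting the mini's
#' own reads deflate it. Bins with zero control coverage are flagged
#' missing (NA), not zero.
#'
#' @param sample,control `CoverageVector`s with identical binning.
#' @param exclude optional interval `c(start, end)` of potentially aneuploid
#'   sequence (the mini region); bins overlapping it are left out of the
#'   per-sample scale estimate, which removes the small euploid-level bias
#'   the mini's own reads would otherwise introduce on a toy genome where
#'   the mini region is a large fraction of the chromosome.
#' @return object of class `DosageProfile`: data.table (`chrom`, `bin`,
#'   `start`, `end`, `dosage`) with attribute `bin_size`.
#' @export
normalize_dosage <- function(sample, control, exclude = NULL) {
  if (!identical(attr(sample, "bin_size"), attr(control, "bin_size")) ||
      nrow(sample) != nrow(control))
    stopf("sample and control must share bin size and chromosome set")
  use <- if (is.null(exclude)) rep(TRUE, nrow(sample)) else
    sample$end < exclude[1] | sample$start > exclude[2]
  if (!any(use)) use <- rep(TRUE, nrow(sample))
  ts <- stats::median(sample$count[use]); tc <- stats::median(control$count[use])
  if (ts == 0) ts <- mean(sample$count)
  if (tc == 0) tc <- mean(control$count)
  if (ts == 0 || tc == 0) stopf("cannot normalize with zero coverage")
  prof <- sample[, .(chrom, bin, start, end)]
  prof[, dosage := 2 * (sample$count / ts) / (control$count / tc)]
  prof[control$count == 0L, dosage := NA_real_]
  setattr(prof, "bin_size", attr(sample, "bin_size"))
  setattr(prof, "class", c("DosageProfile", class(prof)))
  prof[]
}

# Restrict a profile to bins fully inside a region c(start, end).
profile_in_region <- function(profile, region) {
  profile[start >= region[1] & end <= region[2]]
}

#' Locate the deleted interval of a rearranged mini
#'
#' Finds the maximal run of consecutive mini-region bins whose dosage sits
#' more than 0.5 dosage units (half a copy step) below the retained-region
#' level; runs shorter than `min_bins` bins are ignored. The dosage track is
#' lightly smoothed (centered rolling mean over `smooth` bins) before the
#' run scan so that single noisy bins at 10x depth do not split a real dip;
#' with the default 3-bin smoother the recovered interval is exact to within
#' one bin on a clean step profile.
#'
#' @param profile a `DosageProfile`.
#' @param mini_region interval searched.
#' @param drop dosage drop defining the dip (default 0.5).
#' @param min_bins minimum run length (default 2).
#' @param smooth rolling-mean width in bins (odd; default 3).
#' @return `c(start, end)` of the dip, or `NULL` when no qualifying run
#'   exists.
#' @export
estimate_deleted_interval <- function(profile, mini_region, drop = 0.5,
                                      min_bins = 2L, smooth = 3L) {
  pm <- profile_in_region(profile, mini_region)
  pm <- pm[!is.na(dosage)]
  if (nrow(pm) < min_bins) return(NULL)
  # retained level from the upper quartile: robust to the dip itself pulling
  # the center down (the deletion analog covers ~20% of mini bins)
  retained <- stats::quantile(pm$dosage, 0.75, names = FALSE)
  sm <- if (smooth > 1L && nrow(pm) > smooth)
    as.numeric(stats::filter(pm$dosage, rep(1 / smooth, smooth), sides = 2))
  else pm$dosage
  sm[is.na(sm)] <- pm$dosage[is.na(sm)]
  low <- sm < (retained - drop)
  r <- rle(low)
  if (!any(r$values & r$lengths >= min_bins)) return(NULL)
  best <- which(r$values & r$lengths == max(r$lengths[r$values]))[1]
  i1 <- sum(r$lengths[seq_len(best - 1)]) + 1L
  i2 <- i1 + r$lengths[best] - 1L
  c(pm$start[i1], pm$end[i2])
}

# Expected dosage template of each mini type: retained-region level
# 2 + n_full + n_deleted, deletion-interval level 2 + n_full.
mini_type_templates <- function() {
  data.table(type = MINI_TYPES,
             n_full = c(0L, 1L, 2L, 0L, 0L, 1L),
             n_deleted = c(0L, 0L, 0L, 1L, 2L, 1L))[,
    `:=`(retained = 2 + n_full + n_deleted, deleted = 2 + n_full)][]
}

#' Classify a sample into one of six mini structural types
#'
#' Nearest expected-dosage template over mini-region bins; the distance is
#' the mean absolute deviation between the observed dosage and the template
#' (retained-region level in {2, 3, 4}; deletion-interval level per the copy
#' arithmetic of the type).
#'
#' @param profile a `DosageProfile`.
#' @param mini_region mini region interval.
#' @param deletion_interval canonical deletion interval of the rearranged
#'   form (template dip location).
#' @param max_missing maximum tolerated fraction of missing mini-region bins
#'   (default 0.2); above it the sample is `UNCLASSIFIABLE`.
#' @return list of class `MiniTypeCall`: `type`, `distance`, `distances`
#'   (named vector over all six types), `retained_level`, `deletion_level`
#'   (mean dosage over the respective bins).
#' @export
classify_mini_type <- function(profile, mini_region, deletion_interval,
                               max_missing = 0.2) {
  pm <- profile_in_region(profile, mini_region)
  if (nrow(pm) == 0L) stopf("profile has no bins inside the mini region")
  miss <- mean(is.na(pm$dosage))
  if (miss > max_missing)
    return(structure(list(type = "UNCLASSIFIABLE", distance = NA_real_,
                          distances = NULL, retained_level = NA_real_,
                          deletion_level = NA_real_),
                     class = "MiniTypeCall"))
  pm <- pm[!is.na(dosage)]
  in_del <- pm$start >= deletion_interval[1] & pm$end <= deletion_interval[2]
  tmpl <- mini_type_templates()
  dists <- vapply(seq_len(nrow(tmpl)), function(i) {
    expected <- fifelse(in_del, tmpl$deleted[i], tmpl$retained[i])
    mean(abs(pm$dosage - expected))
  }, numeric(1))
  names(dists) <- tmpl$type
  best <- which.min(dists)
  structure(list(type = tmpl$type[best], distance = dists[[best]],
                 distances = dists,
                 retained_level = mean(pm$dosage[!in_del]),
                 deletion_level = if (any(in_del)) mean(pm$dosage[in_del]) else NA_real_),
            class = "MiniTypeCall")
}

#' Pattern-based PCA clustering of dosage profiles
#'
#' Projects mini-region dosage vectors (typically at a coarser bin size than
#' the profile plots) onto principal components and clusters the projection
#' hierarchically (Ward linkage); the number of clusters is chosen by mean
#' silhouette width over `k` in 2..`max_k`, with `k = 1` returned when all
#' samples are (numerically) identical.
#'
#' @param profiles named list of `DosageProfile`s on identical bins.
#' @param mini_region interval whose bins feed the PCA.
#' @param max_k largest cluster count considered (default 8).
#' @param n_comp number of principal components retained (default 2, reduced
#'   when fewer samples are available).
#' @return list of class `PcaClusters`: `labels` (named integer), `coords`
#'   (samples x components), `k`, `silhouette` (mean width per candidate k).
#' @export
pca_cluster <- function(profiles, mini_region, max_k = 8L, n_comp = 2L) {
  if (length(profiles) < 2L) stopf("need at least 2 samples to cluster")
  mat <- do.call(rbind, lapply(profiles, function(p)
    profile_in_region(p, mini_region)$dosage))
  rownames(mat) <- names(profiles)
  mat[is.na(mat)] <- 2                       # missing bins assumed euploid
  n <- nrow(mat)
  if (max(dist(mat)) < 1e-8) {
    labels <- stats::setNames(rep(1L, n), rownames(mat))
    coords <- matrix(0, n, 2, dimnames = list(rownames(mat), c("PC1", "PC2")))
    return(structure(list(labels = labels, coords = coords, k = 1L,
                          silhouette = NULL), class = "PcaClusters"))
  }
  n_comp <- min(n_comp, n - 1L, ncol(mat))
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  coords <- pc$x[, seq_len(n_comp), drop = FALSE]
  d <- dist(coords)
  hc <- hclust(d, method = "ward.D2")
  if (n == 2L) {
    labels <- stats::setNames(1:2, rownames(mat))
    return(structure(list(labels = labels, coords = coords, k = 2L,
                          silhouette = NULL), class = "PcaClusters"))
  }
  ks <- 2:min(max_k, n - 1L)
  sil <- vapply(ks, function(k) {
    cl <- cutree(hc, k)
    if (length(unique(cl)) < 2L) return(-Inf)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  k <- ks[which.max(sil)]
  labels <- cutree(hc, k)
  structure(list(labels = labels, coords = coords, k = k,
                 silhouette = stats::setNames(sil, ks)),
            class = "PcaClusters")
}
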