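# Split-read discovery of novel DNA junctions.
#
# A novel junction is an adjacency of two reference loci, evidenced by reads
# whose alignment splits into two segments mapping at least `min_separation`
# bp apart (or on different chromosomes). Candidates are filtered by the two
# thresholds used in the study: carrier exclusivity (support must be
# completely absent from every control) and a minimum cross-junction read
# coverage derived from pseudo-junctions (ordinary bin boundaries).

#' Extract split-read evidence
#'
#' One evidence record per read whose primary and supplementary alignments
#' map at least `min_separation` bp apart on the same chromosome (boundary
#' inclusive) or on different chromosomes. Breakpoint positions are taken at
#' the soft-clipped ends of the two segments; the retained-flank side of
#' each breakpoint records which side of the locus the alignment covers.
#'
#' @param aln alignment data.table (may span several samples; the
#'   `sample_id` column is carried through).
#' @param min_separation minimum distance between the two segment loci
#'   (default 2000 bp).
#' @return data.table of class `SplitReadEvidence`: `read_id`, `sample_id`,
#'   `chrom_a`, `pos_a`, `side_a`, `chrom_b`, `pos_b`, `side_b`,
#'   `orientation`, `separation`; breakpoints in canonical
#'   ascending-position order.
#' @export
extract_split_alignments <- function(aln, min_separation = 2000) {
  empty <- data.table(read_id = character(0), sample_id = character(0),
                      chrom_a = character(0), pos_a = integer(0),
                      side_a = character(0), chrom_b = character(0),
                      pos_b = integer(0), side_b = character(0),
                      orientation = character(0), separation = numeric(0))
  if (nrow(aln) == 0L) return(structure(empty, class = c("SplitReadEvidence", class(empty))))
  sup <- aln[is_supplementary(flag)]
  if (nrow(sup) == 0L) return(structure(empty, class = c("SplitReadEvidence", class(empty))))
  # read identity = qname + mate bit (+ sample when pooled)
  keyof <- function(x) paste0(x$sample_id, "|", x$qname, "|",
                              bitwAnd(as.integer(x$flag), 192L))
  prim <- aln[is_primary(flag)]
  prim <- prim[keyof(prim) %chin% keyof(sup)]
  if (nrow(prim) == 0L) return(structure(empty, class = c("SplitReadEvidence", class(empty))))

  bp <- function(x) {
    cs <- cigar_summary(x$cigar)
    # breakpoint at the clipped end; when both ends are clipped the larger
    # clip marks the junction side
    right_clip <- cs$trail_clip >= cs$lead_clip
    data.table(rid = keyof(x), chrom = x$rname,
               pos = fifelse(right_clip, x$pos + cs$ref_span - 1L, x$pos),
               side = fifelse(right_clip, "left", "right"),
               clipped = cs$lead_clip + cs$trail_clip > 0L,
               sample_id = x$sample_id, qname = x$qname)
  }
  pb <- bp(prim)
  sb <- bp(sup)
  ev <- merge(pb, sb, by = "rid", suffixes = c("_p", "_s"),
              allow.cartesian = TRUE)
  ev <- ev[clipped_p & clipped_s]
  if (nrow(ev) == 0L) return(structure(empty, class = c("SplitReadEvidence", class(empty))))
  ev[, separation := fifelse(chrom_p == chrom_s,
                             abs(as.numeric(pos_p) - as.numeric(pos_s)), Inf)]
  ev <- ev[separation >= min_separation]
  if (nrow(ev) == 0L) return(structure(empty, class = c("SplitReadEvidence", class(empty))))
  a_first <- ev$chrom_p < ev$chrom_s |
    (ev$chrom_p == ev$chrom_s & ev$pos_p <= ev$pos_s)
  out <- data.table(
    read_id = ev$rid,
    sample_id = ev$sample_id_p,
    chrom_a = fifelse(a_first, ev$chrom_p, ev$chrom_s),
    pos_a = fifelse(a_first, ev$pos_p, ev$pos_s),
    side_a = fifelse(a_first, ev$side_p, ev$side_s),
    chrom_b = fifelse(a_first, ev$chrom_s, ev$chrom_p),
    pos_b = fifelse(a_first, ev$pos_s, ev$pos_p),
    side_b = fifelse(a_first, ev$side_s, ev$side_p),
    separation = ev$separation)
  out[, orientation := orientation_from_sides(side_a, side_b)]
  setcolorder(out, c("read_id", "sample_id", "chrom_a", "pos_a", "side_a",
                     "chrom_b", "pos_b", "side_b", "orientation",
                     "separation"))
  structure(out[], class = c("SplitReadEvidence", class(out)))
}

#' Cluster split-read evidence into candidate junctions
#'
#' Evidence records agreeing on chromosomes, retained-flank sides and
#' orientation, and within `tolerance` bp on both breakpoints, are merged;
#' each candidate's position is the (rounded) median of its members.
#'
#' @param evidence output of [extract_split_alignments()].
#' @param tolerance positional tolerance in bp (default 10).
#' @return data.table of class `CandidateJunction`: `junction_id`,
#'   breakpoint pair columns, `orientation`, `n_reads`, `read_ids` (list),
#'   `support` (list of per-sample named counts).
#' @export
cluster_evidence <- function(evidence, tolerance = 10) {
  empty <- data.table(junction_id = character(0), chrom_a = character(0),
                      pos_a = integer(0), side_a = character(0),
                      chrom_b = character(0), pos_b = integer(0),
                      side_b = character(0), orientation = character(0),
                      n_reads = integer(0))
  if (nrow(evidence) == 0L)
    return(structure(empty[, `:=`(read_ids = list(), support = list())],
                     class = c("CandidateJunction", class(empty))))
  ev <- as.data.table(evidence)
  ev[, grp := .GRP, by = .(chrom_a, chrom_b, side_a, side_b, orientation)]
  setorder(ev, grp, pos_a, pos_b)
  # chain clustering on pos_a within each stratum, then refine on pos_b
  ev[, ca := cumsum(c(1L, as.integer(diff(pos_a) > tolerance))), by = grp]
  setorder(ev, grp, ca, pos_b, pos_a)
  ev[, cb := cumsum(c(1L, as.integer(diff(pos_b) > tolerance))),
     by = .(grp, ca)]
  cand <- ev[, .(
    chrom_a = chrom_a[1],
    pos_a = as.integer(round(stats::median(pos_a))),
    side_a = side_a[1],
    chrom_b = chrom_b[1],
    pos_b = as.integer(round(stats::median(pos_b))),
    side_b = side_b[1],
    orientation = orientation[1],
    n_reads = .N,
    read_ids = list(read_id),
    support = list(table_support(sample_id))
  ), by = .(grp, ca, cb)]
  cand[, c("grp", "ca", "cb") := NULL]
  setorder(cand, chrom_a, pos_a, pos_b)
  cand[, junction_id := sprintf("J%03d", .I)]
  setcolorder(cand, c("junction_id", "chrom_a", "pos_a", "side_a",
                      "chrom_b", "pos_b", "side_b", "orientation",
                      "n_reads", "read_ids", "support"))
  structure(cand[], class = c("CandidateJunction", class(cand)))
}

table_support <- function(sample_id) {
  tb <- table(sample_id)
  stats::setNames(as.integer(tb), names(tb))
}

#' Pseudo-junction minimum-support threshold
#'
#' Divides the genome into non-overlapping consecutive bins and treats each
#' internal boundary between consecutive bins as a pseudo-junction: an
#' ordinary locus every genome copy crosses. The threshold is the mean
#' number of primary alignments spanning a boundary, divided by 2 (the
#' genome is diploid; a novel junction is expected on a single copy).
#'
#' @param aln alignment data.table (one sample).
#' @param bin_size bin width (default 5000 bp).
#' @param chrom_length chromosome length (or a `ReferenceBundle`).
#' @return threshold (numeric, reads).
#' @export
pseudo_junction_threshold <- function(aln, bin_size = 5000, chrom_length) {
  if (inherits(chrom_length, "ReferenceBundle")) chrom_length <- chrom_length$length
  if (chrom_length <= 0) stopf("zero-length genome")
  bounds <- seq(bin_size, chrom_length - 1, by = bin_size)
  if (!length(bounds)) stopf("genome shorter than one bin")
  prim <- aln[is_primary(flag)]
  if (nrow(prim) == 0L) return(0)
  cs <- cigar_summary(prim$cigar)
  starts <- prim$pos
  ends <- prim$pos + cs$ref_span - 1L
  # a read spans boundary b (between bases b and b+1) iff start <= b < end
  n_span_start <- findInterval(bounds, sort(starts))
  n_end_before <- findInterval(bounds, sort(ends))   # ends <= b
  spans <- n_span_start - n_end_before
  mean(spans) / 2
}

#' Apply the carrier-exclusivity and coverage filters
#'
#' A candidate is accepted iff its support reaches the threshold in at least
#' one carrier (each carrier judged against its own per-sample threshold)
#' and is exactly zero in every control.
#'
#' @param candidates output of [cluster_evidence()].
#' @param carrier_ids,control_ids sample id character vectors.
#' @param thresholds named numeric vector of per-sample thresholds (a single
#'   unnamed value is recycled to all carriers).
#' @return the candidates table with logical columns `carrier_exclusive`,
#'   `above_threshold`, `accepted`, plus `max_carrier_support`.
#' @export
filter_junctions <- function(candidates, carrier_ids, control_ids,
                             thresholds) {
  cand <- as.data.table(candidates)
  if (length(control_ids) == 0L)
    warnf("no control samples: carrier-exclusivity filter passes vacuously")
  if (is.null(names(thresholds)) && length(thresholds) == 1L)
    thresholds <- stats::setNames(rep(thresholds, length(carrier_ids)),
                                  carrier_ids)
  if (nrow(cand) == 0L) {
    cand[, `:=`(carrier_exclusive = logical(0), above_threshold = logical(0),
                max_carrier_support = numeric(0), accepted = logical(0))]
    return(cand[])
  }
  chk <- lapply(cand$support, function(sup) {
    ctrl <- sum(sup[names(sup) %in% control_ids])
    carr <- sup[names(sup) %in% carrier_ids]
    above <- length(carr) > 0 &&
      any(carr >= thresholds[names(carr)], na.rm = TRUE)
    list(excl = ctrl == 0L, above = above,
         maxc = if (length(carr)) max(carr) else 0L)
  })
  cand[, carrier_exclusive := vapply(chk, `[[`, logical(1), "excl")]
  cand[, above_threshold := vapply(chk, `[[`, logical(1), "above")]
  cand[, max_carrier_support := vapply(chk, `[[`, numeric(1), "maxc")]
  cand[, accepted := carrier_exclusive & above_threshold]
  cand[]
}

#' Chi-square test of junction orientation uniformity
#'
#' Goodness of fit of the three orientation-class counts (head-to-tail,
#' tail-to-tail, head-to-head) against the uniform expectation; upper-tail
#' p-value from the chi-square distribution with 2 degrees of freedom.
#'
#' @param junctions candidate/accepted junction table with an `orientation`
#'   column (or a character vector of orientations).
#' @return list with `statistic`, `p_value`, `counts`.
#' @export
orientation_chisq <- function(junctions) {
  ori <- if (is.character(junctions)) junctions else junctions$orientation
  if (length(ori) == 0L) stopf("orientation test undefined for zero junctions")
  classes <- c("head_to_tail", "tail_to_tail", "head_to_head")
  counts <- vapply(classes, function(cl) sum(ori == cl), integer(1))
  e <- length(ori) / 3
  stat <- sum((counts - e)^2 / e)
  list(statistic = stat, p_value = pchisq(stat, df = 2, lower.tail = FALSE),
       counts = counts)
}

#' Score detected junctions against simulation truth
#'
#' @param junctions junction table (e.g. accepted candidates).
#' @param truth_junctions truth table from [build_mini()].
#' @param tol positional tolerance in bp (default 10).
#' @return list with `recall`, `n_true`, `n_found`, `matched` (logical per
#'   truth junction).
#' @export
score_junctions <- function(junctions, truth_junctions, tol = 10) {
  tj <- as.data.table(truth_junctions)
  if (nrow(tj) == 0L)
    return(list(recall = NA_real_, n_true = 0L, n_found = nrow(junctions),
                matched = logical(0)))
  matched <- vapply(seq_len(nrow(tj)), function(i) {
    any(abs(junctions$pos_a - tj$pos_a[i]) <= tol &
          abs(junctions$pos_b - tj$pos_b[i]) <= tol &
          junctions$orientation == tj$orientation[i])
  }, logical(1))
  list(recall = mean(matched), n_true = nrow(tj), n_found = nrow(junctions),
       matched = matched)
}
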