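# In-silico validation of candidate junctions: assemble the cross-junction
# reads into a contig and require both contig ends to align to the expected
# loci in the expected orientation; assign the junction's haplotype of
# origin from diagnostic SNPs carried by the supporting reads.

#' Collect the cross-junction reads of a candidate
#'
#' Returns the full (stored-orientation) sequence of every read that
#' contributed split evidence to the junction, taken from its primary
#' alignment record.
#'
#' @param junction one row of a `CandidateJunction` table.
#' @param aln alignment data.table the candidates were called from.
#' @return data.table `read_id`, `sample_id`, `seq` (original read
#'   orientation).
#' @export
collect_cross_junction_reads <- function(junction, aln) {
  ids <- junction$read_ids[[1]]
  if (length(ids) == 0L)
    return(data.table(read_id = character(0), sample_id = character(0),
                      seq = character(0)))
  parts <- tstrsplit(ids, "|", fixed = TRUE)
  want <- data.table(sample_id = parts[[1]], qname = parts[[2]],
                     matebit = as.integer(parts[[3]]), read_id = ids)
  prim <- aln[is_primary(flag)]
  prim[, matebit := bitwAnd(as.integer(flag), 192L)]
  hit <- prim[want, on = c("sample_id", "qname", "matebit"), nomatch = NULL]
  # back to original read orientation
  rev <- is_reverse(hit$flag)
  sq <- hit$seq
  sq[rev] <- revcomp_chr(sq[rev])
  data.table(read_id = hit$read_id, sample_id = hit$sample_id, seq = sq)
}

# Longest exact suffix(x)-prefix(y) overlap with length in [min_k, max_k].
best_overlap <- function(x, y, min_k) {
  nx <- nchar(x); ny <- nchar(y)
  kmax <- min(nx, ny)
  if (kmax < min_k) return(0L)
  ks <- kmax:min_k
  hit <- substring(x, nx - ks + 1L, nx) == substring(y, 1L, ks)
  if (!any(hit)) return(0L)
  ks[which(hit)[1]]
}

# Best merge of ordered pair (x, y): the three distinct adjacency types that
# put x first are tried (x tail - y head, x tail - y tail, x head - y head);
# the remaining type is covered by the reverse ordered pair. Returns list(k,
# merged) or k = 0.
best_merge <- function(x, y, rx, ry, min_overlap) {
  cand_y <- c(y, ry, y)
  cand_x <- c(x, x, rx)
  best_k <- 0L; best_m <- NULL
  for (f in 1:3) {
    k <- best_overlap(cand_x[f], cand_y[f], min_overlap)
    if (k > 0L) {
      m <- paste0(cand_x[f], substring(cand_y[f], k + 1L))
      if (k > best_k || (k == best_k && m < best_m)) { best_k <- k; best_m <- m }
    }
  }
  list(k = best_k, merged = best_m)
}

#' Greedy overlap assembly of cross-junction reads
#'
#' Strand-aware greedy merge: at each step the pair of sequences (in any
#' relative orientation) with the longest exact suffix-prefix overlap of at
#' least `min_overlap` bases is merged; sequences contained in another
#' (either strand) are absorbed. Ties break lexicographically so assembly is
#' deterministic. The result is the single longest assembled sequence; if no
#' overlap of `min_overlap` bases exists among two or more remaining
#' sequences the longest is returned flagged fragmentary.
#'
#' @param reads character vector of read sequences, or the table returned by
#'   [collect_cross_junction_reads()].
#' @param min_overlap minimum exact overlap (default 20).
#' @return object of class `Contig`: list with `seq`, `n_reads` (input
#'   reads), `n_merged` (reads absorbed into the returned contig),
#'   `fragmentary`.
#' @export
assemble_contig <- function(reads, min_overlap = 20) {
  seqs <- if (is.character(reads)) reads else reads$seq
  if (length(seqs) == 0L) stopf("no reads to assemble")
  n_input <- length(seqs)
  pool <- unique(seqs)
  weight <- as.integer(table(factor(seqs, levels = pool)))
  rc <- revcomp_chr(pool)

  # absorb sequences contained in a longer one (either strand)
  absorb <- function() {
    ord <- order(nchar(pool))
    drop <- logical(length(pool))
    for (oi in seq_along(ord)) {
      i <- ord[oi]
      for (oj in rev(seq_along(ord))) {
        j <- ord[oj]
        if (i == j || drop[j] || nchar(pool[j]) < nchar(pool[i])) next
        if (nchar(pool[j]) == nchar(pool[i]) && j > i) next
        if (grepl(pool[i], pool[j], fixed = TRUE) ||
            grepl(rc[i], pool[j], fixed = TRUE)) {
          weight[j] <<- weight[j] + weight[i]
          drop[i] <- TRUE
          break
        }
      }
    }
    if (any(drop)) {
      pool <<- pool[!drop]; rc <<- rc[!drop]; weight <<- weight[!drop]
    }
    any(drop)
  }
  absorb()

  n <- length(pool)
  K <- matrix(0L, n, n)
  if (n > 1L) {
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
      K[i, j] <- best_merge(pool[i], pool[j], rc[i], rc[j], min_overlap)$k
  }
  fragmentary <- FALSE
  while (length(pool) > 1L) {
    if (max(K) < min_overlap) { fragmentary <- TRUE; break }
    hits <- which(K == max(K), arr.ind = TRUE)
    # deterministic tie-break: smallest merged string
    merged <- apply(hits, 1L, function(h)
      best_merge(pool[h[1]], pool[h[2]], rc[h[1]], rc[h[2]], min_overlap)$merged)
    pick <- order(merged)[1]
    i <- hits[pick, 1]; j <- hits[pick, 2]
    new_seq <- merged[pick]
    new_w <- weight[i] + weight[j]
    keep <- setdiff(seq_along(pool), c(i, j))
    pool <- c(pool[keep], new_seq)
    rc <- c(rc[keep], revcomp_chr(new_seq))
    weight <- c(weight[keep], new_w)
    K <- K[keep, keep, drop = FALSE]
    if (absorb()) {
      # containment changed the pool; rebuild the (small) matrix
      n <- length(pool)
      K <- matrix(0L, n, n)
      if (n > 1L) for (a in seq_len(n)) for (b in seq_len(n)) if (a != b)
        K[a, b] <- best_merge(pool[a], pool[b], rc[a], rc[b], min_overlap)$k
      next
    }
    n <- length(pool)
    if (n < 2L) break
    K <- rbind(cbind(K, rep(0L, nrow(K))), rep(0L, n))
    for (a in seq_len(n - 1L)) {
      K[a, n] <- best_merge(pool[a], pool[n], rc[a], rc[n], min_overlap)$k
      K[n, a] <- best_merge(pool[n], pool[a], rc[n], rc[a], min_overlap)$k
    }
  }
  pick <- which.max(nchar(pool))
  structure(list(seq = pool[pick], n_reads = n_input,
                 n_merged = weight[pick],
                 fragmentary = fragmentary || length(pool) > 1L),
            class = "Contig")
}

# Expected chimeric sequence across a junction: retained flank of breakpoint
# A (traversed into the junction) followed by retained flank of breakpoint B
# (traversed out of it), each `flank` bp.
expected_chimera <- function(ref, junction, flank = 150) {
  g <- as.character(ref$seq)
  L <- ref$length
  take <- function(pos, side, role) {
    if (role == "a") {
      # approached towards the breakpoint
      if (side == "left") substring(g, max(1, pos - flank + 1), pos)
      else revcomp_chr(substring(g, pos, min(L, pos + flank - 1)))
    } else {
      # leaves the junction
      if (side == "right") substring(g, pos, min(L, pos + flank - 1))
      else revcomp_chr(substring(g, max(1, pos - flank + 1), pos))
    }
  }
  left <- take(junction$pos_a, junction$side_a, "a")
  right <- take(junction$pos_b, junction$side_b, "b")
  list(seq = paste0(left, right), junction_at = nchar(left))
}

#' Validate a contig against the reference at a candidate junction
#'
#' Builds the expected chimeric reference sequence across the junction
#' (retained flank of each breakpoint, `flank` bp per side, honoring the
#' junction's orientation) and locally aligns the contig (both strands)
#' against it. The junction is validated when the alignment spans the
#' chimeric point with at least `anchor` aligned bases and at least
#' `min_identity` identity on each side -- i.e. both contig ends align to
#' the expected regions in the expected orientation. A contig that is a
#' contiguous reference slice matches at most one side and fails.
#'
#' @param contig a `Contig` (or a character sequence).
#' @param ref a `ReferenceBundle`.
#' @param junction one-row junction table (`pos_a`, `side_a`, `pos_b`,
#'   `side_b`).
#' @param anchor minimum aligned bases on each side of the chimeric point
#'   (default 30).
#' @param min_identity minimum per-side identity (default 0.95).
#' @param flank reference flank per side (default 150 bp, which also bounds
#'   the placement tolerance of the contig ends).
#' @return list of class `JunctionValidation`: `validated`, `identity_left`,
#'   `identity_right`, `anchor_left`, `anchor_right`, `end_alignments`
#'   (data.table with the reference interval, strand and identity of each
#'   contig end).
#' @export
validate_contig <- function(contig, ref, junction, anchor = 30,
                            min_identity = 0.95, flank = 150) {
  cseq <- if (inherits(contig, "Contig")) contig$seq else as.character(contig)
  if (nchar(cseq) < 2 * anchor)
    stopf("contig shorter than twice the end-anchor length")
  em <- expected_chimera(ref, junction, flank)
  subj <- Biostrings::DNAString(em$seq)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  try_one <- function(sq) {
    Biostrings::pairwiseAlignment(Biostrings::DNAString(sq), subj,
                                  type = "local", substitutionMatrix = mat,
                                  gapOpening = 4, gapExtension = 1)
  }
  al_f <- try_one(cseq)
  al_r <- try_one(revcomp_chr(cseq))
  al <- if (Biostrings::score(al_f) >= Biostrings::score(al_r)) al_f else al_r
  strand_used <- if (Biostrings::score(al_f) >= Biostrings::score(al_r)) "+" else "-"

  # per-column comparison in subject coordinates
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sbj <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  spos <- Biostrings::start(Biostrings::subject(al)) + cumsum(sbj != "-") - 1L
  aligned <- pat != "-" & sbj != "-"
  matchv <- aligned & pat == sbj
  leftc <- spos <= em$junction_at
  a_left <- sum(aligned & leftc)
  a_right <- sum(aligned & !leftc)
  id_left <- if (a_left) sum(matchv & leftc) / a_left else 0
  id_right <- if (a_right) sum(matchv & !leftc) / a_right else 0
  validated <- a_left >= anchor && a_right >= anchor &&
    id_left >= min_identity && id_right >= min_identity

  ends <- data.table(
    end = c("left", "right"),
    chrom = ref$chrom,
    breakpoint = c(junction$pos_a, junction$pos_b),
    side = c(junction$side_a, junction$side_b),
    aligned_bases = c(a_left, a_right),
    identity = c(id_left, id_right),
    contig_strand = strand_used)
  structure(list(validated = validated, identity_left = id_left,
                 identity_right = id_right, anchor_left = a_left,
                 anchor_right = a_right, end_alignments = ends),
            class = "JunctionValidation")
}

#' Assign the haplotype of origin of a junction
#'
#' Inspects reads that carry split evidence for the junction, plus their
#' mates, restricted to alignments within `window` bp of either breakpoint.
#' Bases at diagnostic SNP sites are tallied: the junction is called
#' `mini_haplotype` when at least two reads support mini alleles and none
#' support the background (symmetrically for `background`); otherwise, or
#' when no informative SNP is covered, the call is `indeterminate`.
#'
#' @param junction one row of a (candidate) junction table.
#' @param snps diagnostic SNP table (`pos`, `background`, `mini`), as in a
#'   `ReferenceBundle` (which is also accepted).
#' @param aln alignment data.table.
#' @param window breakpoint neighbourhood in bp (default 1000).
#' @param min_reads minimum allele-consistent reads for a call (default 2).
#' @return list of class `HaplotypeCall`: `junction_id`, `call`,
#'   `informative_snps`, `reads_mini`, `reads_background`.
#' @export
assign_haplotype <- function(junction, snps, aln, window = 1000,
                             min_reads = 2L) {
  if (inherits(snps, "ReferenceBundle")) snps <- snps$snps
  ids <- junction$read_ids[[1]]
  call_out <- function(call, n_snp, nm, nb)
    structure(list(junction_id = junction$junction_id, call = call,
                   informative_snps = n_snp, reads_mini = nm,
                   reads_background = nb), class = "HaplotypeCall")
  if (length(ids) == 0L) return(call_out("indeterminate", 0L, 0L, 0L))
  parts <- tstrsplit(ids, "|", fixed = TRUE)
  key <- data.table(sample_id = parts[[1]], qname = parts[[2]])
  # evidence reads and their mates
  sub <- aln[unique(key), on = c("sample_id", "qname"), nomatch = NULL]
  sub <- sub[is_primary(flag)]
  if (nrow(sub) == 0L) return(call_out("indeterminate", 0L, 0L, 0L))
  cs <- cigar_summary(sub$cigar)
  sub[, `:=`(astart = pos, aend = pos + cs$ref_span - 1L,
             lead = cs$lead_clip)]
  near <- (sub$astart <= junction$pos_a + window &
             sub$aend >= junction$pos_a - window) |
    (sub$astart <= junction$pos_b + window &
       sub$aend >= junction$pos_b - window)
  sub <- sub[near]
  if (nrow(sub) == 0L) return(call_out("indeterminate", 0L, 0L, 0L))

  snp_near <- snps[(pos >= junction$pos_a - window & pos <= junction$pos_a + window) |
                     (pos >= junction$pos_b - window & pos <= junction$pos_b + window)]
  if (nrow(snp_near) == 0L) return(call_out("indeterminate", 0L, 0L, 0L))

  votes_mini <- 0L; votes_bg <- 0L; n_inf <- 0L
  seen_snp <- integer(0)
  for (r in seq_len(nrow(sub))) {
    cover <- snp_near[pos >= sub$astart[r] & pos <= sub$aend[r]]
    if (nrow(cover) == 0L) next
    off <- sub$lead[r] + (cover$pos - sub$astart[r]) + 1L
    base <- substring(sub$seq[r], off, off)
    m <- base == cover$mini
    b <- base == cover$background
    if (any(m) && !any(b)) votes_mini <- votes_mini + 1L
    if (any(b) && !any(m)) votes_bg <- votes_bg + 1L
    if (any(m | b)) seen_snp <- union(seen_snp, cover$pos[m | b])
  }
  n_inf <- length(seen_snp)
  call <- if (n_inf == 0L) "indeterminate"
  else if (votes_mini >= min_reads && votes_bg == 0L) "mini_haplotype"
  else if (votes_bg >= min_reads && votes_mini == 0L) "background"
  else "indeterminate"
  call_out(call, n_inf, votes_mini, votes_bg)
}
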