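# Synthetic ring-minichromosome cohorts.
#
# The generator emulates the sequencing design of a ring-mini pedigree study
# at toy scale: one chromosome carrying a "mini region" (the source of the
# circular minichromosome) whose centromeric core is repeat-rich and
# gene-poor, paired-end reads at configurable depth, split alignments across
# every novel adjacency of the mini, and diagnostic SNPs separating the mini
# haplotype from the sequenced background. All paper-scale coordinates are
# mapped by a single linear scale factor (default 0.1 relative to Mb
# coordinates of the real chromosome).

#' Generate a toy reference bundle
#'
#' Builds a random reference chromosome together with the interval constants
#' of the mini system (mini region, centromere analog, canonical deletion
#' interval, enrichment control region), gene and repeat annotation tracks
#' with the centromeric contrast needed by enrichment analyses (genes
#' depleted, repeats enriched inside the centromere analog), and a table of
#' diagnostic SNPs distinguishing the mini haplotype from the background.
#'
#' Default coordinates are a 10x linear shrink of the real system: a 2 Mb
#' chromosome whose mini region spans 1.3-1.9 Mb (analog of Chr01 13-19 Mb),
#' centromere analog 1.5-1.7 Mb, canonical deletion 1.6-1.73 Mb, and
#' enrichment control region 1.3-2.0 Mb.
#'
#' @param length chromosome length in bp.
#' @param mini_region integer c(start, end), 1-based inclusive; must lie
#'   within the chromosome.
#' @param centromere centromere analog interval, must lie within
#'   `mini_region`.
#' @param deletion_interval canonical deletion of the rearranged mini form.
#' @param control_region interval used as resampling space for breakpoint
#'   enrichment nulls.
#' @param gene_frac,repeat_frac length-2 numeric `c(outside, inside)`: target
#'   covered fraction outside/inside the centromere analog.
#' @param gene_len,repeat_len mean feature lengths in bp.
#' @param snp_density expected diagnostic SNPs per bp (default 1/500).
#' @param chrom chromosome name used in SAM/annotation output.
#' @param seed integer seed; identical seeds give byte-identical bundles.
#' @return object of class `ReferenceBundle`: list with `seq` (DNAString),
#'   `chrom`, `length`, the interval constants, `genes`, `repeats`
#'   (data.tables with `start`, `end`), `snps` (data.table with `pos`,
#'   `background`, `mini`) and `scale`.
#' @export
generate_reference <- function(length = 2e6,
                               mini_region = c(1300001L, 1900000L),
                               centromere = c(1500001L, 1700000L),
                               deletion_interval = c(1600001L, 1730000L),
                               control_region = c(1300001L, 2000000L),
                               gene_frac = c(outside = 0.30, inside = 0.05),
                               repeat_frac = c(outside = 0.10, inside = 0.60),
                               gene_len = 2000, repeat_len = 500,
                               snp_density = 1 / 500,
                               chrom = "Chr1", seed = 1L) {
  length <- as.integer(length)
  if (mini_region[1] < 1 || mini_region[2] > length || mini_region[1] >= mini_region[2])
    stopf("mini_region [%d, %d] must lie within the chromosome (1..%d)",
          mini_region[1], mini_region[2], length)
  if (centromere[1] < mini_region[1] || centromere[2] > mini_region[2])
    stopf("centromere analog must lie within the mini region")
  if (deletion_interval[1] < mini_region[1] || deletion_interval[2] > mini_region[2])
    stopf("deletion interval must lie within the mini region")
  set.seed(seed)

  seq <- Biostrings::DNAString(paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))

  outside <- list(c(1L, centromere[1] - 1L), c(centromere[2] + 1L, length))
  inside <- list(centromere)
  genes <- rbind(
    place_features(outside, gene_frac[["outside"]], gene_len),
    place_features(inside, gene_frac[["inside"]], gene_len))
  reps <- rbind(
    place_features(outside, repeat_frac[["outside"]], repeat_len),
    place_features(inside, repeat_frac[["inside"]], repeat_len))
  setkey(genes, start); setkey(reps, start)

  n_snp <- round(length * snp_density)
  pos <- sort(sample.int(length, n_snp))
  bg <- substring(as.character(seq), pos, pos)
  alt <- vapply(bg, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1), USE.NAMES = FALSE)
  snps <- data.table(pos = pos, background = bg, mini = alt)

  structure(list(chrom = chrom, length = length, seq = seq,
                 mini_region = as.integer(mini_region),
                 centromere = as.integer(centromere),
                 deletion_interval = as.integer(deletion_interval),
                 control_region = as.integer(control_region),
                 genes = genes, repeats = reps, snps = snps,
                 scale = 0.1, seed = seed),
            class = "ReferenceBundle")
}

# Alternate feature/gap placement hitting a target covered fraction.
# regions: list of c(start, end). Gaps are exponential with mean chosen so
# that mean_len / (mean_len + mean_gap) = frac.
place_features <- function(regions, frac, mean_len) {
  out <- list()
  for (rg in regions) {
    if (rg[2] <= rg[1]) next
    mean_gap <- mean_len * (1 - frac) / frac
    cur <- rg[1]
    starts <- integer(0); ends <- integer(0)
    repeat {
      cur <- cur + round(rexp(1, 1 / mean_gap))
      if (cur > rg[2]) break
      len <- max(50L, round(rnorm(1, mean_len, 0.2 * mean_len)))
      starts <- c(starts, cur)
      ends <- c(ends, min(cur + len - 1L, rg[2]))
      cur <- cur + len
    }
    out[[length(out) + 1L]] <- data.table(start = as.integer(starts),
                                          end = as.integer(ends))
  }
  rbindlist(out)
}

#' Describe a mini complement
#'
#' A sample's minichromosome complement: number of full-ring and deleted-ring
#' copies (at most two copies in total, as observed in the pedigree), the
#' deletion interval of the rearranged form, and any extra rearrangement
#' junctions carried by the deleted form.
#'
#' @param ref a `ReferenceBundle`.
#' @param n_full,n_deleted copies of the full and of the deleted ring form;
#'   each in 0..2 with `n_full + n_deleted <= 2`.
#' @param deletion_interval interval removed in the deleted form (defaults to
#'   the bundle's canonical deletion analog).
#' @param extras `NULL`, `"default"` (an inversion-style pair of junctions in
#'   the retained mini region), or a data.table with columns `pos_a`,
#'   `pos_b`, `orientation` applied in ascending `pos_a` order.
#' @return object of class `MiniConfig`.
#' @export
mini_config <- function(ref, n_full = 0L, n_deleted = 0L,
                        deletion_interval = NULL, extras = NULL) {
  if (!n_full %in% 0:2 || !n_deleted %in% 0:2 || n_full + n_deleted > 2)
    stopf("n_full and n_deleted must be in 0..2 with n_full + n_deleted <= 2")
  deletion_interval <- deletion_interval %||% ref$deletion_interval
  if (deletion_interval[1] <= ref$mini_region[1] ||
      deletion_interval[2] >= ref$mini_region[2])
    stopf("deletion interval must lie strictly within the mini region")
  if (identical(extras, "default")) extras <- default_extras(ref)
  if (!is.null(extras)) {
    extras <- as.data.table(extras)
    stopifnot(all(c("pos_a", "pos_b", "orientation") %in% names(extras)))
    if (any(extras$pos_a < ref$mini_region[1] | extras$pos_a > ref$mini_region[2] |
            extras$pos_b < ref$mini_region[1] | extras$pos_b > ref$mini_region[2]))
      stopf("extra junction breakpoints must lie within the mini region")
    setorder(extras, pos_a)
  }
  structure(list(n_full = as.integer(n_full), n_deleted = as.integer(n_deleted),
                 deletion_interval = as.integer(deletion_interval),
                 extras = extras),
            class = "MiniConfig")
}

#' Default extra rearrangements of the deleted mini form
#'
#' An inversion of a block covering 5\% of the mini span (30 kb at default
#' scale), placed a quarter of the way into the mini region, expressed as
#' its two novel adjacencies (one tail-to-tail, one head-to-head) so that
#' default cohorts exercise all three junction orientation classes.
#' @param ref a `ReferenceBundle`.
#' @return data.table with columns `pos_a`, `pos_b`, `orientation`.
#' @export
default_extras <- function(ref) {
  span <- ref$mini_region[2] - ref$mini_region[1] + 1L
  a <- ref$mini_region[1] + as.integer(round(0.25 * span))
  b <- a + as.integer(round(0.05 * span))
  data.table(pos_a = c(a, a + 1L), pos_b = c(b, b + 1L),
             orientation = c("tail_to_tail", "head_to_head"))
}

#' Mini type label from copy numbers
#' @param n_full,n_deleted copy counts.
#' @return one of `NO_MINI`, `ONE_FULL`, `TWO_FULL`, `ONE_DELETED`,
#'   `TWO_DELETED`, `FULL_PLUS_DELETED`.
#' @export
mini_type_of <- function(n_full, n_deleted) {
  key <- paste(n_full, n_deleted)
  switch(key,
         "0 0" = "NO_MINI", "1 0" = "ONE_FULL", "2 0" = "TWO_FULL",
         "0 1" = "ONE_DELETED", "0 2" = "TWO_DELETED",
         "1 1" = "FULL_PLUS_DELETED",
         stopf("no mini type for n_full=%s, n_deleted=%s", n_full, n_deleted))
}

#' All six mini structural types
#' @export
MINI_TYPES <- c("NO_MINI", "ONE_FULL", "TWO_FULL",
                "ONE_DELETED", "TWO_DELETED", "FULL_PLUS_DELETED")

#' Build the circular mini structure(s) and their junction truth
#'
#' The full form is the mini region excised and circularized (one novel
#' adjacency: the circularization site). The deleted form additionally lacks
#' the deletion interval and carries the configured extra junctions. The
#' structure is composed as an oriented segment walk over the mini region:
#' each event (deletion adjacency or extra junction) contributes exactly one
#' novel adjacency, so the number of truth junctions is
#' 1 (circularization) + 1 (deletion, if a deleted copy exists) + n_extras.
#' Walks that cannot be composed into a single circle (out-of-order
#' breakpoints, strand flips that never return to the forward strand) raise
#' an invalid-configuration error.
#'
#' @param ref a `ReferenceBundle`.
#' @param config a `MiniConfig`.
#' @return list of class `MiniBuild` with `full` and `deleted` structures
#'   (each `NULL` or a list of `segments`, `length`, `seq`), and `junctions`:
#'   a data.table (`chrom`, `pos_a`, `side_a`, `pos_b`, `side_b`,
#'   `orientation`, `name`, `copies`) with breakpoints in canonical
#'   (ascending-position) order; `copies` counts mini copies carrying the
#'   junction in this configuration.
#' @export
build_mini <- function(ref, config) {
  stopifnot(inherits(config, "MiniConfig"))
  mr <- ref$mini_region
  mini_seq_ref <- mini_allele_genome(ref)

  full <- NULL
  if (config$n_full > 0) {
    full <- walk_structure(ref, mini_seq_ref, events = NULL)
  }
  deleted <- NULL
  del_events <- NULL
  if (config$n_deleted > 0) {
    del <- config$deletion_interval
    del_events <- data.table(pos_a = del[1] - 1L, pos_b = del[2] + 1L,
                             orientation = "head_to_tail", name = "deletion")
    if (!is.null(config$extras) && nrow(config$extras)) {
      ex <- copy(config$extras)[, name := paste0("extra_", .I)]
      del_events <- rbind(del_events, ex)
      setorder(del_events, pos_a)
    }
    deleted <- walk_structure(ref, mini_seq_ref, events = del_events)
  }

  junctions <- list()
  circ <- data.table(chrom = ref$chrom, pos_a = mr[2], side_a = "left",
                     pos_b = mr[1], side_b = "right",
                     orientation = "head_to_tail", name = "circularization",
                     copies = config$n_full + config$n_deleted)
  junctions[[1]] <- circ
  if (!is.null(deleted)) {
    junctions[[2]] <- deleted$junctions[, .(chrom = ref$chrom, pos_a, side_a,
                                            pos_b, side_b, orientation, name,
                                            copies = config$n_deleted)]
  }
  jn <- rbindlist(junctions)
  jn <- canonicalize_junctions(jn)
  structure(list(full = full, deleted = deleted, junctions = jn,
                 config = config),
            class = "MiniBuild")
}

# Reference sequence with the mini-haplotype allele substituted at every
# diagnostic SNP. Cached on the bundle environment would be nicer; cheap
# enough to recompute.
mini_allele_genome <- function(ref) {
  Biostrings::replaceLetterAt(ref$seq, at = ref$snps$pos,
                              letter = paste(ref$snps$mini, collapse = ""))
}

# Compose the mini circle as an oriented segment walk. events: data.table
# (pos_a, pos_b, orientation, name) in application order, or NULL.
walk_structure <- function(ref, mini_seq_ref, events = NULL) {
  mr <- ref$mini_region
  segs <- list(); jns <- list()
  cur <- mr[1]; dir <- 1L
  n_ev <- if (is.null(events)) 0L else nrow(events)
  if (n_ev) {
    for (k in seq_len(n_ev)) {
      ev <- events[k]
      if (dir == 1L) {
        if (ev$pos_a < cur)
          stopf("junction '%s' at %d is not composable (walk already at %d)",
                ev$name, ev$pos_a, cur)
        segs[[length(segs) + 1L]] <- data.table(start = cur, end = ev$pos_a, strand = "+")
        side_a <- "left"
        if (ev$orientation == "head_to_tail") { dir2 <- 1L
        } else if (ev$orientation == "tail_to_tail") { dir2 <- -1L
        } else stopf("junction '%s': head_to_head cannot follow a forward segment", ev$name)
      } else {
        if (ev$pos_a > cur)
          stopf("junction '%s' at %d is not composable (reverse walk at %d)",
                ev$name, ev$pos_a, cur)
        segs[[length(segs) + 1L]] <- data.table(start = ev$pos_a, end = cur, strand = "-")
        side_a <- "right"
        if (ev$orientation == "head_to_head") { dir2 <- 1L
        } else if (ev$orientation == "head_to_tail") { dir2 <- -1L
        } else stopf("junction '%s': tail_to_tail cannot follow a reverse segment", ev$name)
      }
      side_b <- if (dir2 == 1L) "right" else "left"
      jns[[length(jns) + 1L]] <- data.table(pos_a = ev$pos_a, side_a = side_a,
                                            pos_b = ev$pos_b, side_b = side_b,
                                            orientation = ev$orientation,
                                            name = ev$name)
      cur <- ev$pos_b; dir <- dir2
    }
  }
  if (dir != 1L)
    stopf("rearrangement walk ends on the reverse strand; the ring cannot close")
  if (cur > mr[2])
    stopf("rearrangement walk overruns the mini region end")
  segs[[length(segs) + 1L]] <- data.table(start = cur, end = mr[2], strand = "+")
  segments <- rbindlist(segs)
  if (any(segments$end < segments$start))
    stopf("rearrangement produces an empty segment; junctions overlap")
  segments[, len := end - start + 1L]
  segments[, cum_end := cumsum(len)]
  segments[, cum_start := cum_end - len + 1L]

  pieces <- lapply(seq_len(nrow(segments)), function(i) {
    s <- Biostrings::subseq(mini_seq_ref, segments$start[i], segments$end[i])
    if (segments$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    s
  })
  seq <- Reduce(Biostrings::xscat, pieces)
  list(segments = segments, length = sum(segments$len), seq = seq,
       junctions = if (length(jns)) rbindlist(jns) else
         data.table(pos_a = integer(0), side_a = character(0),
                    pos_b = integer(0), side_b = character(0),
                    orientation = character(0), name = character(0)))
}

# Put pos_a <= pos_b, swapping sides when needed (orientation is symmetric).
canonicalize_junctions <- function(jn) {
  jn <- copy(jn)
  swap <- jn$pos_b < jn$pos_a
  if (any(swap)) {
    tmp_p <- jn$pos_a[swap]; tmp_s <- jn$side_a[swap]
    jn[swap, `:=`(pos_a = pos_b, side_a = side_b)]
    jn[swap, `:=`(pos_b = tmp_p, side_b = tmp_s)]
  }
  setorder(jn, pos_a, pos_b)
  jn[]
}

#' Expected split-read support of a junction
#'
#' Expected number of reads crossing a junction with at least `min_anchor`
#' aligned bases on each side, for a junction present on `copies` mini copies
#' in a sample sequenced at total euploid depth `depth` (each genome copy
#' contributes depth/2).
#' @param depth total sequencing depth (euploid coverage).
#' @param copies mini copies carrying the junction.
#' @param read_len read length in bp.
#' @param min_anchor minimum aligned bases per side for a split alignment to
#'   be emitted.
#' @return expected read count (numeric).
#' @export
expected_junction_support <- function(depth, copies, read_len = 150,
                                      min_anchor = 20) {
  copies * (depth / 2) * (read_len - 2 * min_anchor + 1) / read_len
}

#' Simulate paired-end alignments for one individual
#'
#' Emits the background genome at two copies and each mini copy at one copy,
#' so that the expected normalized dosage over the retained mini region is
#' `2 + copies`. Reads crossing a mini junction are emitted as split
#' alignments (primary plus supplementary records with soft clips and SA
#' tags), provided each side retains at least `min_anchor` aligned bases.
#' Reads drawn from the mini carry the mini-haplotype allele at every
#' diagnostic SNP they cover. Deterministic for a fixed seed.
#'
#' @param ref a `ReferenceBundle`.
#' @param config a `MiniConfig`.
#' @param depth total euploid sequencing depth (default 10).
#' @param read_len read length (default 150).
#' @param insert_mean mean fragment length (default 400, sd = 0.1 * mean,
#'   truncated below at `read_len`).
#' @param error_rate per-base substitution rate (default 0).
#' @param min_anchor minimum aligned bases per split segment (default 20).
#' @param sample_id sample name recorded on every alignment.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return list with `alignments` (data.table of SAM fields: `qname`,
#'   `flag`, `rname`, `pos`, `mapq`, `cigar`, `rnext`, `pnext`, `tlen`,
#'   `seq`, `qual`, `sa`, `sample_id`) and `truth` (list: `sample_id`,
#'   `mini_type`, `junctions` with per-junction `copies`, `config`).
#' @export
simulate_individual <- function(ref, config, depth = 10, read_len = 150,
                                insert_mean = 400, error_rate = 0,
                                min_anchor = 20, sample_id = "S1",
                                seed = NULL) {
  if (depth <= 0) stopf("depth must be positive")
  if (read_len <= 0) stopf("read_len must be positive")
  if (!is.null(seed)) set.seed(seed)
  build <- build_mini(ref, config)
  genome_chr <- as.character(ref$seq)
  mini_chr <- as.character(mini_allele_genome(ref))

  recs <- list(sim_background(ref, genome_chr, depth, read_len, insert_mean,
                              sample_id))
  copy_id <- 0L
  for (form in c("full", "deleted")) {
    n <- if (form == "full") config$n_full else config$n_deleted
    st <- build[[form]]
    for (i in seq_len(n)) {
      copy_id <- copy_id + 1L
      recs[[length(recs) + 1L]] <-
        sim_mini_copy(ref, st, mini_chr, depth / 2, read_len, insert_mean,
                      min_anchor, sample_id, copy_id)
    }
  }
  aln <- rbindlist(recs)
  if (error_rate > 0) aln <- add_seq_errors(aln, error_rate)
  setorder(aln, pos, qname, flag)
  truth <- structure(list(sample_id = sample_id,
                          mini_type = mini_type_of(config$n_full, config$n_deleted),
                          junctions = build$junctions[copies > 0],
                          config = config),
                     class = "TruthRecord")
  list(alignments = aln[], truth = truth)
}

# Plain diploid background: proper pairs, no splits.
sim_background <- function(ref, genome_chr, depth, read_len, insert_mean,
                           sample_id) {
  L <- ref$length
  n <- round(depth * L / (2 * read_len))
  fl <- pmin(pmax(read_len, round(rnorm(n, insert_mean, 0.1 * insert_mean))), L)
  s <- 1L + floor(runif(n) * (L - fl + 1))
  p1 <- as.integer(s)
  p2 <- as.integer(s + fl - read_len)
  qn <- paste0(sample_id, ":bg:", seq_len(n))
  cg <- paste0(read_len, "M")
  data.table(
    qname = rep(qn, 2L),
    flag = rep(c(99L, 147L), each = n),
    rname = ref$chrom,
    pos = c(p1, p2),
    mapq = 60L,
    cigar = cg,
    rnext = "=",
    pnext = c(p2, p1),
    tlen = c(fl, -fl),
    seq = substring(genome_chr, c(p1, p2), c(p1, p2) + read_len - 1L),
    qual = "*",
    sa = NA_character_,
    sample_id = sample_id)
}

# One mini copy: fragments drawn on the circle; junction-crossing reads are
# decomposed into split records.
sim_mini_copy <- function(ref, st, mini_chr, copy_depth, read_len,
                          insert_mean, min_anchor, sample_id, copy_id) {
  L <- st$length
  n <- round(copy_depth * L / (2 * read_len))
  if (n == 0L) return(NULL)
  fl <- pmin(pmax(read_len, round(rnorm(n, insert_mean, 0.1 * insert_mean))), L)
  s <- 1L + floor(runif(n) * L)   # circular: any start is valid
  qn <- paste0(sample_id, ":m", copy_id, ":", seq_len(n))
  # read start positions on the circle (may exceed L; wrap handled per read)
  a1 <- as.integer(s)
  a2 <- as.integer(s + fl - read_len)
  segs <- st$segments
  out <- list(
    map_circle_reads(ref, st, mini_chr, a1, read_dir = 1L, read_len,
                     min_anchor, qn, readbit = 64L, sample_id),
    map_circle_reads(ref, st, mini_chr, a2, read_dir = -1L, read_len,
                     min_anchor, qn, readbit = 128L, sample_id))
  rbindlist(out)
}

# Map reads given by circle start positions to SAM records. read_dir = 1 for
# mates stored in circle-forward orientation, -1 for reverse-complemented
# mates.
map_circle_reads <- function(ref, st, mini_chr, a, read_dir, read_len,
                             min_anchor, qn, readbit, sample_id) {
  L <- st$length
  segs <- st$segments
  a <- ((a - 1L) %% L) + 1L
  b <- a + read_len - 1L                      # unwrapped end (may exceed L)
  seg_i <- findInterval(a, segs$cum_start)
  crossing <- b > segs$cum_end[seg_i]

  # fast path: read contained in one oriented segment
  ii <- which(!crossing)
  fast <- NULL
  if (length(ii)) {
    i <- seg_i[ii]
    off <- a[ii] - segs$cum_start[i]
    plus <- segs$strand[i] == "+"
    rs <- ifelse(plus, segs$start[i] + off,
                 segs$end[i] - off - read_len + 1L)
    re <- rs + read_len - 1L
    minus_bit <- xor(!plus, read_dir == -1L)
    fast <- data.table(
      qname = qn[ii],
      flag = 1L + readbit + ifelse(minus_bit, 16L, 0L),
      rname = ref$chrom,
      pos = as.integer(rs),
      mapq = 60L,
      cigar = paste0(read_len, "M"),
      rnext = "=", pnext = 0L, tlen = 0L,
      seq = substring(mini_chr, rs, re),
      qual = "*",
      sa = NA_character_,
      sample_id = sample_id)
  }

  # crossing reads: decompose into per-segment pieces
  jj <- which(crossing)
  split_recs <- vector("list", length(jj))
  for (k in seq_along(jj)) {
    r <- jj[k]
    split_recs[[k]] <- map_one_crossing_read(ref, st, mini_chr, a[r],
                                             read_dir, read_len, min_anchor,
                                             qn[r], readbit, sample_id)
  }
  rbindlist(c(list(fast), split_recs))
}

map_one_crossing_read <- function(ref, st, mini_chr, a, read_dir, read_len,
                                  min_anchor, qname, readbit, sample_id) {
  L <- st$length
  segs <- st$segments
  b <- a + read_len - 1L
  # stored read sequence along the circle
  circle_pos <- ((seq.int(a, b) - 1L) %% L) + 1L
  stored <- circle_substr(st, circle_pos, read_dir)

  # piece boundaries in unwrapped coordinates
  pieces <- list()
  p <- a
  while (p <= b) {
    pc <- ((p - 1L) %% L) + 1L
    i <- findInterval(pc, segs$cum_start)
    pe_circ <- segs$cum_end[i]
    pe <- min(b, p + (pe_circ - pc))
    pieces[[length(pieces) + 1L]] <- list(i = i, pa = p, pb = pe)
    p <- pe + 1L
  }
  rows <- list()
  for (pc in pieces) {
    m <- pc$pb - pc$pa + 1L
    if (m < min_anchor) next
    i <- pc$i
    ca <- ((pc$pa - 1L) %% L) + 1L
    off <- ca - segs$cum_start[i]
    plus <- segs$strand[i] == "+"
    if (plus) {
      rs <- segs$start[i] + off
      re <- rs + m - 1L
    } else {
      re <- segs$end[i] - off
      rs <- re - m + 1L
    }
    minus_bit <- xor(!plus, read_dir == -1L)
    # read coords in stored orientation
    if (read_dir == 1L) { qa <- pc$pa - a + 1L; qb <- pc$pb - a + 1L
    } else { qa <- b - pc$pb + 1L; qb <- b - pc$pa + 1L }
    if (minus_bit) { lead <- read_len - qb; trail <- qa - 1L
    } else { lead <- qa - 1L; trail <- read_len - qb }
    cigar <- paste0(if (lead > 0) paste0(lead, "S") else "",
                    m, "M",
                    if (trail > 0) paste0(trail, "S") else "")
    seqf <- if (minus_bit) revcomp_chr(stored) else stored
    rows[[length(rows) + 1L]] <- data.table(
      qname = qname, flag = 1L + readbit + if (minus_bit) 16L else 0L,
      rname = ref$chrom, pos = as.integer(rs), mapq = 60L, cigar = cigar,
      rnext = "=", pnext = 0L, tlen = 0L, seq = seqf, qual = "*",
      sa = NA_character_, sample_id = sample_id, m = m,
      strand_chr = if (minus_bit) "-" else "+")
  }
  if (!length(rows)) return(NULL)
  dt <- rbindlist(rows)
  if (nrow(dt) >= 2L) {
    prim <- which.max(dt$m)
    dt[-prim, flag := flag + 2048L]
    sa_str <- paste0(dt$rname, ",", dt$pos, ",", dt$strand_chr, ",",
                     dt$cigar, ",60,0;")
    dt[, sa := vapply(seq_len(.N), function(r)
      paste0("SA:Z:", paste0(sa_str[-r], collapse = "")), character(1))]
  }
  dt[, c("m", "strand_chr") := NULL]
  dt[]
}

# Extract the stored-orientation read sequence for given circle positions.
circle_substr <- function(st, circle_pos, read_dir) {
  s <- as.character(Biostrings::extractAt(
    st$seq, IRanges::IRanges(start = circle_pos, width = 1L)))
  rd <- paste0(s, collapse = "")
  if (read_dir == -1L) revcomp_chr(rd) else rd
}

# i.i.d. substitution errors applied in reference orientation (equivalent to
# read-space errors for an unbiased substitution model).
add_seq_errors <- function(aln, rate) {
  n_bases <- nchar(aln$seq)
  n_err <- stats::rbinom(nrow(aln), n_bases, rate)
  idx <- which(n_err > 0L)
  for (r in idx) {
    sq <- strsplit(aln$seq[r], "")[[1]]
    at <- sample.int(length(sq), n_err[r])
    sq[at] <- vapply(sq[at], function(bse)
      sample(setdiff(c("A", "C", "G", "T"), bse), 1L), character(1))
    aln$seq[r] <- paste0(sq, collapse = "")
  }
  aln
}

#' Simulate a cohort of individuals
#'
#' @param ref a `ReferenceBundle`.
#' @param cohort data.table/data.frame with columns `sample_id`, `n_full`,
#'   `n_deleted` and optionally `extras` (list column; defaults to the
#'   bundle's default extras whenever `n_deleted > 0`).
#' @param depth,read_len,insert_mean,error_rate,min_anchor forwarded to
#'   [simulate_individual()].
#' @param seed master seed; per-sample seeds are derived deterministically.
#' @return list with `alignments` (one data.table, keyed by `sample_id`),
#'   `truth` (named list of truth records) and `ref`.
#' @export
simulate_cohort <- function(ref, cohort, depth = 10, read_len = 150,
                            insert_mean = 400, error_rate = 0,
                            min_anchor = 20, seed = 1L) {
  cohort <- as.data.table(cohort)
  set.seed(seed)
  seeds <- sample.int(1e8L, nrow(cohort))
  alns <- vector("list", nrow(cohort))
  truth <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    ex <- if ("extras" %in% names(cohort)) cohort$extras[[i]] else
      if (cohort$n_deleted[i] > 0) "default" else NULL
    cfg <- mini_config(ref, cohort$n_full[i], cohort$n_deleted[i], extras = ex)
    sim <- simulate_individual(ref, cfg, depth = depth, read_len = read_len,
                               insert_mean = insert_mean,
                               error_rate = error_rate,
                               min_anchor = min_anchor,
                               sample_id = cohort$sample_id[i],
                               seed = seeds[i])
    alns[[i]] <- sim$alignments
    truth[[i]] <- sim$truth
  }
  names(truth) <- cohort$sample_id
  list(alignments = rbindlist(alns), truth = truth, ref = ref)
}

#' Demo cohort design: every mini type, n replicates each
#' @param n_per_type replicates per structural type (default 3).
#' @return data.table with `sample_id`, `n_full`, `n_deleted`, `type`.
#' @export
demo_cohort <- function(n_per_type = 3L) {
  des <- data.table(type = MINI_TYPES,
                    n_full = c(0L, 1L, 2L, 0L, 0L, 1L),
                    n_deleted = c(0L, 0L, 0L, 1L, 2L, 1L))
  out <- des[rep(seq_len(.N), each = n_per_type)]
  out[, sample_id := paste0(type, "_", seq_len(.N)), by = type]
  out[, .(sample_id, n_full, n_deleted, type)]
}
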