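# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of plain character DNA
#' @param x character vector of DNA strings (ACGTN)
#' @return character vector
#' @keywords internal
revcomp_chr <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Parse CIGAR strings into per-record summaries. Only M/I/D/S/H/=/X/N are
# expected; the synthetic generator emits S and M exclusively.
# Returns data.table(ref_span, lead_clip, trail_clip).
cigar_summary <- function(cigar) {
  n <- length(cigar)
  out <- data.table(ref_span = integer(n), lead_clip = integer(n),
                    trail_clip = integer(n))
  if (n == 0L) return(out)
  # fast path: pure-match CIGARs dominate
  simple <- grepl("^\\d+M$", cigar)
  if (any(simple)) {
    out$ref_span[simple] <- as.integer(sub("M$", "", cigar[simple]))
  }
  idx <- which(!simple & cigar != "*")
  if (length(idx)) {
    toks <- regmatches(cigar[idx], gregexpr("\\d+[MIDNSHP=X]", cigar[idx]))
    for (k in seq_along(idx)) {
      tk <- toks[[k]]
      lens <- as.integer(sub(".$", "", tk))
      ops <- substring(tk, nchar(tk), nchar(tk))
      out$ref_span[idx[k]] <- sum(lens[ops %in% c("M", "D", "N", "=", "X")])
      m <- length(ops)
      lead <- 0L; j <- 1L
      while (j <= m && ops[j] %in% c("S", "H")) { lead <- lead + lens[j]; j <- j + 1L }
      trail <- 0L; j <- m
      while (j >= 1L && ops[j] %in% c("S", "H")) { trail <- trail + lens[j]; j <- j - 1L }
      out$lead_clip[idx[k]] <- lead
      out$trail_clip[idx[k]] <- trail
    }
  }
  out
}

# Flag-bit helpers (SAM spec bit names)
flag_has <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L
is_primary <- function(flag) !flag_has(flag, 256L) & !flag_has(flag, 2048L) & !flag_has(flag, 4L)
is_supplementary <- function(flag) flag_has(flag, 2048L)
is_reverse <- function(flag) flag_has(flag, 16L)

# Merge possibly-overlapping 1-based inclusive intervals given as a
# data.table/data.frame with columns start, end. Returns a data.table.
merge_intervals <- function(iv) {
  iv <- as.data.table(iv)
  if (nrow(iv) == 0L) return(data.table(start = integer(0), end = integer(0)))
  ir <- IRanges::reduce(IRanges::IRanges(start = iv$start, end = iv$end))
  data.table(start = IRanges::start(ir), end = IRanges::end(ir))
}

# Total bases covered by (possibly overlapping) intervals, optionally clipped
# to a region c(start, end).
interval_bases <- function(iv, region = NULL) {
  m <- merge_intervals(iv)
  if (!is.null(region)) {
    m <- m[end >= region[1] & start <= region[2]]
    if (nrow(m)) {
      m[, start := pmax(start, region[1])]
      m[, end := pmin(end, region[2])]
    }
  }
  if (nrow(m) == 0L) return(0)
  sum(m$end - m$start + 1)
}

# Orientation of a junction from the retained-flank sides of its two
# breakpoints. "left"+"right" (colinear) folds to head_to_tail; two retained
# left flanks join two fragment tails; two retained right flanks join heads.
orientation_from_sides <- function(side_a, side_b) {
  fifelse(side_a == side_b,
          fifelse(side_a == "left", "tail_to_tail", "head_to_head"),
          "head_to_tail")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
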