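# Format adapters: plain-text SAM, BED-like interval tracks, TSV tables.
# Internally everything is 1-based inclusive; SAM is already 1-based and
# BED files on disk are 0-based half-open (conversion handled by
# rtracklayer).

#' Write alignments as plain-text SAM
#'
#' @param aln alignment data.table as produced by [simulate_individual()] or
#'   [read_sam()].
#' @param path output file.
#' @param chrom_lengths named integer vector for `@SQ` header lines (a
#'   `ReferenceBundle` is also accepted).
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, chrom_lengths) {
  if (inherits(chrom_lengths, "ReferenceBundle"))
    chrom_lengths <- stats::setNames(chrom_lengths$length, chrom_lengths$chrom)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(chrom_lengths), "\tLN:", chrom_lengths))
  body <- paste(aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq, aln$cigar,
                aln$rnext, aln$pnext, aln$tlen, aln$seq, aln$qual, sep = "\t")
  has_sa <- !is.na(aln$sa)
  body[has_sa] <- paste(body[has_sa], aln$sa[has_sa], sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a plain-text SAM file
#'
#' Parses the 11 mandatory columns plus the `SA:Z:` supplementary-alignment
#' tag. Unmapped and malformed records are dropped with a counted warning;
#' more than 10\% malformed records abort the read.
#'
#' @param path SAM file path.
#' @param sample_id sample name attached to every record (default: file name
#'   without extension).
#' @return alignment data.table (see [simulate_individual()] for columns).
#' @export
read_sam <- function(path, sample_id = NULL) {
  sample_id <- sample_id %||% sub("\\.sam$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.table(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      rnext = character(0), pnext = integer(0),
                      tlen = integer(0), seq = character(0),
                      qual = character(0), sa = character(0),
                      sample_id = character(0)))
  dt <- fread(text = lines, sep = "\t", header = FALSE, fill = Inf,
              quote = "", colClasses = list(character = 1))
  n_total <- nrow(dt)
  bad <- is.na(dt$V2) | is.na(dt$V4) | is.na(dt$V11) |
    suppressWarnings(is.na(as.integer(dt$V2)))
  if (any(bad)) {
    if (mean(bad) > 0.10)
      stopf("%d of %d SAM records malformed (>10%%); aborting", sum(bad), n_total)
    warnf("dropped %d malformed SAM record(s)", sum(bad))
    dt <- dt[!bad]
  }
  sa <- rep(NA_character_, nrow(dt))
  tagcols <- names(dt)[-(1:11)]
  for (cl in tagcols) {
    v <- as.character(dt[[cl]])
    hit <- !is.na(v) & startsWith(v, "SA:Z:")
    sa[hit] <- v[hit]
  }
  out <- data.table(qname = as.character(dt$V1), flag = as.integer(dt$V2),
                    rname = as.character(dt$V3), pos = as.integer(dt$V4),
                    mapq = as.integer(dt$V5), cigar = as.character(dt$V6),
                    rnext = as.character(dt$V7), pnext = as.integer(dt$V8),
                    tlen = as.integer(dt$V9), seq = as.character(dt$V10),
                    qual = as.character(dt$V11), sa = sa,
                    sample_id = sample_id)
  out[!flag_has(flag, 4L)]
}

#' Read a BED-like interval track
#'
#' 0-based half-open on disk (standard BED); returned 1-based inclusive.
#' @param path BED file.
#' @return data.table with `start`, `end` (and `chrom` if multi-chromosome).
#' @export
read_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr))
}

#' Write an interval track as BED
#' @param iv data.table with `start`, `end` (1-based inclusive) and
#'   optionally `chrom`.
#' @param path output BED path.
#' @param chrom chromosome name used when `iv` has no `chrom` column.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(iv, path, chrom = "Chr1") {
  iv <- as.data.table(iv)
  ch <- if ("chrom" %in% names(iv)) iv$chrom else chrom
  gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(iv$start, iv$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write / read a pipeline TSV table (lossless round-trip)
#' @param x data.table or data.frame.
#' @param path file path.
#' @return `path` invisibly (write); data.table (read).
#' @export
write_tsv <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) fread(path, sep = "\t", na.strings = "NA")

#' Write a sample sheet
#'
#' Columns: `sample_id`, `sam_path`, `carrier` (logical), `control`
#' (logical).
#' @param sheet data.table with the columns above.
#' @param path output TSV.
#' @export
write_sample_sheet <- function(sheet, path) write_tsv(sheet, path)

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  sh <- read_tsv(path)
  need <- c("sample_id", "sam_path", "carrier", "control")
  if (!all(need %in% names(sh)))
    stopf("sample sheet must have columns: %s", paste(need, collapse = ", "))
  sh
}

#' Persist / reload a reference bundle as plain-text files
#'
#' Writes the chromosome FASTA, gene and repeat BED tracks, the diagnostic
#' SNP TSV and a JSON of the interval constants, so that downstream analysis
#' steps can run from files alone.
#'
#' @param ref a `ReferenceBundle`.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly (write); a `ReferenceBundle` (read).
#' @export
write_reference_bundle <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- Biostrings::DNAStringSet(stats::setNames(list(ref$seq), ref$chrom))
  Biostrings::writeXStringSet(seqs, file.path(dir, "reference.fasta"))
  write_intervals(ref$genes, file.path(dir, "genes.bed"), chrom = ref$chrom)
  write_intervals(ref$repeats, file.path(dir, "repeats.bed"), chrom = ref$chrom)
  write_tsv(ref$snps, file.path(dir, "snps.tsv"))
  meta <- ref[c("chrom", "length", "mini_region", "centromere",
                "deletion_interval", "control_region", "scale", "seed")]
  jsonlite::write_json(meta, file.path(dir, "regions.json"), auto_unbox = FALSE)
  invisible(dir)
}

#' @rdname write_reference_bundle
#' @export
read_reference_bundle <- function(dir) {
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "reference.fasta"))
  meta <- jsonlite::read_json(file.path(dir, "regions.json"), simplifyVector = TRUE)
  structure(list(chrom = meta$chrom, length = as.integer(meta$length),
                 seq = seqs[[1]],
                 mini_region = as.integer(meta$mini_region),
                 centromere = as.integer(meta$centromere),
                 deletion_interval = as.integer(meta$deletion_interval),
                 control_region = as.integer(meta$control_region),
                 genes = read_intervals(file.path(dir, "genes.bed"))[, .(start, end)],
                 repeats = read_intervals(file.path(dir, "repeats.bed"))[, .(start, end)],
                 snps = read_tsv(file.path(dir, "snps.tsv")),
                 scale = meta$scale, seed = meta$seed),
            class = "ReferenceBundle")
}
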