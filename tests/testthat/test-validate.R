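# Contig assembly across junctions, in-silico validation against the
# reference, and diagnostic-SNP haplotype assignment.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

test_that("cross-junction read collection returns the supporting reads", {
  sim <- fx_twodel20()
  cand <- cluster_evidence(extract_split_alignments(sim$alignments))
  for (i in seq_len(nrow(cand))) {
    reads <- collect_cross_junction_reads(cand[i], sim$alignments)
    expect_identical(nrow(reads), cand$n_reads[i])
    expect_true(all(nchar(reads$seq) == 150L))
  }
  none <- cand[1]
  none$read_ids <- list(character(0))
  expect_identical(nrow(collect_cross_junction_reads(none, sim$alignments)), 0L)
})

test_that("greedy assembly merges overlaps and reconstructs chimeras", {
  # single read
  r <- random_dna(150)
  expect_identical(assemble_contig(r)$seq, r)
  # two 150 bp reads overlapping exactly 50 bp -> 250 bp contig
  set.seed(2)
  s <- random_dna(250)
  ctg <- assemble_contig(c(substring(s, 1, 150), substring(s, 101, 250)),
                         min_overlap = 20)
  expect_identical(nchar(ctg$seq), 250L)
  expect_identical(ctg$seq, s)
  # 12 error-free tiled reads reconstruct a 400 bp chimera exactly, with
  # half the reads on the reverse strand
  set.seed(3)
  chim <- random_dna(400)
  starts <- round(seq(1, 251, length.out = 12))
  reads <- substring(chim, starts, starts + 149)
  flip <- seq(2, 12, by = 2)
  reads[flip] <- revcomp(reads[flip])
  ctg2 <- assemble_contig(reads)
  expect_true(ctg2$seq == chim || ctg2$seq == revcomp(chim))
  expect_false(ctg2$fragmentary)
  # no qualifying overlap: longest read returned, flagged fragmentary
  set.seed(5)
  frag <- assemble_contig(c(random_dna(150), random_dna(120)))
  expect_identical(nchar(frag$seq), 150L)
  expect_true(frag$fragmentary)
  expect_error(assemble_contig(character(0)), "no reads")
})

test_that("greedy assembly matches exhaustive merge-order search on small
           inputs", {
  # oracle: explore every merge order (best merge per ordered pair at each
  # step) and return the best achievable single-contig length
  oracle_best <- function(seqs, min_overlap = 20) {
    best <- Inf
    seen <- new.env(parent = emptyenv())
    recurse <- function(pool) {
      sig <- paste(sort(pool), collapse = "#")
      if (!is.null(seen[[sig]])) return()
      seen[[sig]] <- TRUE
      if (length(pool) == 1L) { best <<- min(best, nchar(pool)); return() }
      rc <- revcomp(pool)
      merged_any <- FALSE
      for (i in seq_along(pool)) for (j in seq_along(pool)) {
        if (i == j) next
        bm <- ringmini:::best_merge(pool[i], pool[j], rc[i], rc[j], min_overlap)
        if (bm$k >= min_overlap) {
          merged_any <- TRUE
          recurse(c(pool[-c(i, j)], bm$merged))
        }
      }
      if (!merged_any) best <<- min(best, max(nchar(pool)))
    }
    recurse(unique(seqs))
    best
  }
  for (seed in 1:3) {
    set.seed(seed)
    template <- random_dna(300)
    starts <- sort(sample(1:150, 5))
    reads <- substring(template, starts, starts + 149)
    greedy <- assemble_contig(reads)
    expect_identical(nchar(greedy$seq), as.integer(oracle_best(reads)))
  }
})

test_that("contig validation requires both ends at the expected loci", {
  ref <- fx_ref()
  sim <- fx_twodel20()
  cand <- cluster_evidence(extract_split_alignments(sim$alignments))
  for (i in seq_len(nrow(cand))) {
    reads <- collect_cross_junction_reads(cand[i], sim$alignments)
    ctg <- assemble_contig(reads)
    val <- validate_contig(ctg, ref, cand[i])
    expect_true(val$validated)
    expect_gte(val$identity_left, 0.95)
    expect_gte(val$identity_right, 0.95)
  }
  # a contiguous reference slice is not a junction
  decoy <- as.character(Biostrings::subseq(ref$seq, 700001, 700360))
  expect_false(validate_contig(decoy, ref, cand[1])$validated)
  # one anchored end plus random sequence is not validated either
  em <- ringmini:::expected_chimera(ref, cand[1], flank = 150)
  half <- paste0(substring(em$seq, 1, 150), random_dna(150))
  expect_false(validate_contig(half, ref, cand[1])$validated)
  expect_error(validate_contig(random_dna(40), ref, cand[1]), "anchor")
})

test_that("haplotype assignment follows the allele-consistency rules", {
  ref <- fx_ref()
  # constructed scene: junction at 10000/50000, 3 SNPs near breakpoint A
  snps <- data.table(pos = c(9900L, 9950L, 10020L),
                     background = c("A", "A", "A"), mini = c("C", "C", "C"))
  mkread <- function(id, pos, base) {
    sq <- strrep("G", 150)
    for (p in snps$pos) {
      off <- p - pos + 1L
      if (off >= 1 && off <= 150) substring(sq, off, off) <- base
    }
    mk_aln(id, 0L, pos, "150M", seq = sq)
  }
  jr <- data.table(junction_id = "J1", pos_a = 10000L, pos_b = 50000L,
                   read_ids = list(paste0("S|r", 1:5, "|0")))
  aln_mini <- rbindlist(lapply(1:5, function(i) mkread(paste0("r", i), 9880L + i, "C")))
  expect_identical(assign_haplotype(jr, snps, aln_mini)$call, "mini_haplotype")

  # 50/50 allele conflict: indeterminate
  aln_mix <- rbindlist(lapply(1:4, function(i)
    mkread(paste0("r", i), 9880L + i, if (i %% 2) "C" else "A")))
  jr2 <- copy(jr); jr2$read_ids <- list(paste0("S|r", 1:4, "|0"))
  expect_identical(assign_haplotype(jr2, snps, aln_mix)$call, "indeterminate")

  # all background alleles
  aln_bg <- rbindlist(lapply(1:4, function(i) mkread(paste0("r", i), 9880L + i, "A")))
  expect_identical(assign_haplotype(jr2, snps, aln_bg)$call, "background")

  # no SNP within the window: indeterminate
  far <- data.table(pos = 300000L, background = "A", mini = "C")
  expect_identical(assign_haplotype(jr, far, aln_mini)$call, "indeterminate")
  expect_identical(assign_haplotype(jr, far, aln_mini)$informative_snps, 0L)

  # synthetic junctions live on the mini haplotype: whenever diagnostic
  # SNPs are reachable the call is mini, never background (junctions with
  # no informative SNP in reach stay indeterminate, as in real data)
  n_mini <- 0L
  for (sim in list(fx_twodel20(), fx_onedel())) {
    cand <- cluster_evidence(extract_split_alignments(sim$alignments))
    for (i in seq_len(nrow(cand))) {
      h <- assign_haplotype(cand[i], ref, sim$alignments)
      expect_identical(h$reads_background, 0L)
      expect_true(h$call %in% c("mini_haplotype", "indeterminate"))
      if (h$reads_mini >= 2L) expect_identical(h$call, "mini_haplotype")
      n_mini <- n_mini + (h$call == "mini_haplotype")
    }
  }
  expect_gte(n_mini, 1L)
})
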