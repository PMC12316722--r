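# Synthetic cohort generator: determinism, composition arithmetic of the
# mini structures, and the statistical properties of emitted alignments.

test_that("reference generation is deterministic and validates bounds", {
  args <- list(length = 2e5, mini_region = c(130001L, 190000L),
               centromere = c(150001L, 170000L),
               deletion_interval = c(160001L, 173000L),
               control_region = c(130001L, 200000L), seed = 5)
  r1 <- do.call(generate_reference, args)
  r2 <- do.call(generate_reference, args)
  expect_identical(as.character(r1$seq), as.character(r2$seq))
  expect_identical(r1$genes, r2$genes)
  expect_identical(r1$snps, r2$snps)

  expect_error(generate_reference(length = 1e5, mini_region = c(90001, 120000)),
               "mini_region")
  expect_error(do.call(generate_reference,
                       modifyList(args, list(centromere = c(100, 200)))),
               "centromere")
  expect_true(all(r1$snps$background != r1$snps$mini))
})

test_that("feature fractions hit their targets with centromeric contrast", {
  ref <- fx_ref()
  cen <- ref$centromere
  frac <- function(iv, region)
    ringmini:::interval_bases(iv, region) / (region[2] - region[1] + 1)
  rep_in <- frac(ref$repeats, cen)
  rep_out <- frac(ref$repeats, c(1, cen[1] - 1))
  gene_in <- frac(ref$genes, cen)
  gene_out <- frac(ref$genes, c(1, cen[1] - 1))
  expect_lt(abs(rep_in - 0.6), 0.05)
  expect_lt(abs(rep_out - 0.1), 0.05)
  expect_gt(gene_out, gene_in)          # genes depleted in the centromere
  expect_lt(abs(gene_out - 0.3), 0.05)
})

test_that("mini composition yields one adjacency per event", {
  ref <- fx_ref()
  # full ring only: the circularization site
  b1 <- build_mini(ref, mini_config(ref, 1, 0))
  expect_identical(nrow(b1$junctions[copies > 0]), 1L)
  expect_identical(b1$junctions$name[1], "circularization")
  expect_identical(b1$junctions$orientation[1], "head_to_tail")

  # no mini at all
  b0 <- build_mini(ref, mini_config(ref, 0, 0))
  expect_identical(nrow(b0$junctions[copies > 0]), 0L)

  # deleted ring with three extra junctions: 1 + 1 + 3 adjacencies
  extras <- data.table(
    pos_a = c(1350001L, 1400001L, 1400002L),
    pos_b = c(1360001L, 1430001L, 1430002L),
    orientation = c("head_to_tail", "tail_to_tail", "head_to_head"))
  b3 <- build_mini(ref, mini_config(ref, 0, 1, extras = extras))
  expect_identical(nrow(b3$junctions[copies > 0]), 5L)
  # truth breakpoints all inside the mini region
  jn <- b3$junctions
  expect_true(all(jn$pos_a >= ref$mini_region[1] & jn$pos_b <= ref$mini_region[2]))
  # segment walk conserves sequence: full length = span; deleted = span -
  # deletion (the inversion extra rearranges without loss)
  span <- ref$mini_region[2] - ref$mini_region[1] + 1L
  expect_identical(build_mini(ref, mini_config(ref, 1, 0))$full$length, span)
  del <- ref$deletion_interval
  expect_identical(b3$deleted$length, span - (1360001L - 1350001L - 1L) -
                     (del[2] - del[1] + 1L))
})

test_that("uncomposable rearrangement walks raise configuration errors", {
  ref <- fx_ref()
  expect_error(mini_config(ref, 2, 1), "n_full")
  expect_error(mini_config(ref, 0, 1, deletion_interval = c(1, 5000)),
               "within the mini region")
  # overlapping deletions cannot be composed linearly
  bad1 <- data.table(pos_a = c(1400000L, 1450000L),
                     pos_b = c(1500000L, 1550000L),
                     orientation = c("head_to_tail", "head_to_tail"))
  expect_error(build_mini(ref, mini_config(ref, 0, 1, extras = bad1)),
               "not composable")
  # a lone strand flip cannot close the ring
  bad2 <- data.table(pos_a = 1800000L, pos_b = 1850000L,
                     orientation = "tail_to_tail")
  expect_error(build_mini(ref, mini_config(ref, 0, 1, extras = bad2)),
               "cannot close")
  expect_error(simulate_individual(ref, mini_config(ref, 0, 0), depth = -1),
               "depth")
})

test_that("simulated alignments are deterministic and scale with depth", {
  ref <- fx_small_ref()
  cfg <- mini_config(ref, 0, 1, extras = "default")
  s1 <- simulate_individual(ref, cfg, depth = 6, sample_id = "X", seed = 9)
  s2 <- simulate_individual(ref, cfg, depth = 6, sample_id = "X", seed = 9)
  expect_identical(s1$alignments, s2$alignments)
  # byte-identical SAM stream
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  write_sam(s1$alignments, f1, ref); write_sam(s2$alignments, f2, ref)
  expect_identical(readLines(f1), readLines(f2))

  # dosage conservation: primary read count linear in depth within 2%
  n6 <- sum(ringmini:::is_primary(s1$alignments$flag))
  s12 <- simulate_individual(ref, cfg, depth = 12, sample_id = "X", seed = 10)
  n12 <- sum(ringmini:::is_primary(s12$alignments$flag))
  expect_lt(abs(n12 / n6 - 2), 0.02 * 2)
})

test_that("a cohort without mini emits no split alignments anywhere", {
  ev <- extract_split_alignments(fx_ctrl()$alignments, min_separation = 2000)
  expect_identical(nrow(ev), 0L)
  expect_false(any(ringmini:::is_supplementary(fx_ctrl()$alignments$flag)))
})

test_that("junction-crossing reads appear at the Poisson-expected rate", {
  sim <- fx_twodel20()
  ev <- extract_split_alignments(sim$alignments)
  cand <- cluster_evidence(ev)
  truth <- sim$truth$junctions
  lambda <- expected_junction_support(depth = 20, copies = 2)
  ci <- qpois(c(0.005, 0.995), lambda)
  for (i in seq_len(nrow(truth))) {
    hit <- cand[pos_a == truth$pos_a[i] & pos_b == truth$pos_b[i]]
    expect_identical(nrow(hit), 1L)
    expect_gte(hit$n_reads, ci[1])
    expect_lte(hit$n_reads, ci[2])
  }
})

test_that("mini-origin reads carry the mini-haplotype allele", {
  ref <- fx_ref()
  sim <- fx_onefull()
  aln <- sim$alignments[ringmini:::is_primary(flag) & cigar == "150M"]
  snps <- ref$snps[pos >= ref$mini_region[1] & pos <= ref$mini_region[2]]
  base_at <- function(rec, p) substring(rec$seq, p - rec$pos + 1L, p - rec$pos + 1L)
  checked_mini <- 0L; checked_bg <- 0L
  for (i in seq_len(min(200, nrow(snps)))) {
    p <- snps$pos[i]
    cover <- aln[pos <= p & pos + 149L >= p]
    if (nrow(cover) == 0L) next
    mini_reads <- cover[grepl(":m", qname, fixed = TRUE)]
    bg_reads <- cover[grepl(":bg:", qname, fixed = TRUE)]
    if (nrow(mini_reads)) {
      expect_true(all(base_at(mini_reads, p) == snps$mini[i]))
      checked_mini <- checked_mini + nrow(mini_reads)
    }
    if (nrow(bg_reads)) {
      expect_true(all(base_at(bg_reads, p) == snps$background[i]))
      checked_bg <- checked_bg + nrow(bg_reads)
    }
    if (checked_mini > 50 && checked_bg > 50) break
  }
  expect_gt(checked_mini, 0L)
  expect_gt(checked_bg, 0L)
})
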