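# Split-read junction discovery, clustering, thresholds and filters.

test_that("split extraction honors the 2 kb separation boundary", {
  mk_split <- function(p2) {
    rbind(mk_aln("r1", 0L, 100000L, "100M50S"),     # breakpoint 100099, left
          mk_aln("r1", 2048L, p2, "100S50M"))       # breakpoint p2, right
  }
  # separation 1999: excluded
  expect_identical(nrow(extract_split_alignments(mk_split(102098L))), 0L)
  # separation exactly 2000: included ("at least 2000 bp apart")
  ev <- extract_split_alignments(mk_split(102099L))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$pos_a, 100099L)
  expect_identical(ev$side_a, "left")
  expect_identical(ev$pos_b, 102099L)
  expect_identical(ev$side_b, "right")
  expect_identical(ev$orientation, "head_to_tail")
})

test_that("synthetic junctions are recovered at exact positions with correct
           orientation", {
  sim <- fx_twodel20()
  cand <- cluster_evidence(extract_split_alignments(sim$alignments))
  truth <- sim$truth$junctions
  expect_identical(nrow(cand), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    hit <- cand[abs(pos_a - truth$pos_a[i]) <= 10 &
                  abs(pos_b - truth$pos_b[i]) <= 10 &
                  orientation == truth$orientation[i]]
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$side_a, truth$side_a[i])
    expect_identical(hit$side_b, truth$side_b[i])
  }
  # every breakpoint inside the mini region
  mr <- fx_ref()$mini_region
  expect_true(all(cand$pos_a >= mr[1] & cand$pos_b <= mr[2]))
})

test_that("evidence clustering merges within tolerance and takes medians", {
  ev1 <- data.table(read_id = c("a", "b"), sample_id = "S",
                    chrom_a = "Chr1", pos_a = c(10000L, 10000L),
                    side_a = "left", chrom_b = "Chr1",
                    pos_b = c(50000L, 50000L), side_b = "right",
                    orientation = "head_to_tail", separation = 40000)
  c1 <- cluster_evidence(ev1)
  expect_identical(nrow(c1), 1L)
  expect_identical(c1$n_reads, 2L)
  expect_identical(c1$support[[1]][["S"]], 2L)

  ev2 <- copy(ev1)[2, pos_a := 10050L]
  expect_identical(nrow(cluster_evidence(ev2)), 2L)

  set.seed(4)
  jit <- sample(-3:3, 8, replace = TRUE)
  ev3 <- data.table(read_id = paste0("r", 1:8), sample_id = "S",
                    chrom_a = "Chr1", pos_a = 20000L + jit, side_a = "left",
                    chrom_b = "Chr1", pos_b = 60000L + rev(jit),
                    side_b = "right", orientation = "head_to_tail",
                    separation = 40000)
  c3 <- cluster_evidence(ev3)
  expect_identical(nrow(c3), 1L)
  expect_lte(abs(c3$pos_a - 20000L), 5L)
  expect_lte(abs(c3$pos_b - 60000L), 5L)
})

test_that("pseudo-junction threshold equals half the boundary coverage", {
  ref <- fx_ref()
  expect_identical(pseudo_junction_threshold(fx_ctrl()$alignments[0],
                                             5000, 50000), 0)
  # 30 reads across every internal boundary of a 50 kb genome: 15.0 exactly
  bounds <- seq(5000, 45000, by = 5000)
  aln <- rbindlist(lapply(bounds, function(b)
    mk_aln(paste0("b", b, "_", 1:30), 0L, b - 75L, "150M")))
  expect_identical(pseudo_junction_threshold(aln, 5000, 50000), 15)
  # synthetic depth-10 control: within 20% of depth/2
  th <- pseudo_junction_threshold(fx_ctrl()$alignments, 5000, ref)
  expect_lt(abs(th - 5) / 5, 0.2)
  expect_error(pseudo_junction_threshold(aln, 5000, 0), "genome")
})

test_that("threshold scales linearly with depth", {
  ref <- fx_small_ref()
  s10 <- simulate_individual(ref, mini_config(ref, 0, 0), depth = 10,
                             sample_id = "a", seed = 21)
  s20 <- simulate_individual(ref, mini_config(ref, 0, 0), depth = 20,
                             sample_id = "b", seed = 22)
  t10 <- pseudo_junction_threshold(s10$alignments, 5000, ref)
  t20 <- pseudo_junction_threshold(s20$alignments, 5000, ref)
  expect_lt(abs(t20 / t10 - 2), 0.2)
})

test_that("carrier-exclusivity and coverage filters gate acceptance", {
  cand <- data.table(
    junction_id = c("J1", "J2", "J3"),
    chrom_a = "Chr1", pos_a = c(1e4L, 2e4L, 3e4L), side_a = "left",
    chrom_b = "Chr1", pos_b = c(5e4L, 6e4L, 7e4L), side_b = "right",
    orientation = "head_to_tail", n_reads = c(13L, 1L, 12L),
    read_ids = list(character(12), character(1), character(12)),
    support = list(c(CAR = 12L, CTL = 1L), c(CAR = 1L), c(CAR = 12L)))
  out <- filter_junctions(cand, "CAR", "CTL", c(CAR = 5))
  # one read in a control is disqualifying regardless of carrier support
  expect_false(out$accepted[1])
  expect_false(out$carrier_exclusive[1])
  # support below threshold
  expect_false(out$accepted[2])
  # clean injected junction
  expect_true(out$accepted[3])
  # empty control set: warning, exclusivity vacuously true
  expect_warning(out2 <- filter_junctions(cand, "CAR", character(0),
                                          c(CAR = 5)), "control")
  expect_true(out2$accepted[3])
})

test_that("orientation chi-square matches the closed form", {
  r0 <- orientation_chisq(rep(c("head_to_tail", "tail_to_tail",
                                "head_to_head"), each = 3))
  expect_identical(r0$statistic, 0)
  expect_identical(r0$p_value, 1)

  r1 <- orientation_chisq(c(rep("head_to_tail", 7), rep("tail_to_tail", 2),
                            "head_to_head"))
  expect_equal(r1$statistic, 6.2, tolerance = 1e-12)
  expect_equal(r1$p_value, pchisq(6.2, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(r1$p_value - 0.045), 0.001)

  r2 <- orientation_chisq(c(rep("head_to_tail", 4), rep("tail_to_tail", 3),
                            rep("head_to_head", 3)))
  expect_gt(r2$p_value, 0.9)
  expect_error(orientation_chisq(character(0)), "zero junctions")
})
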