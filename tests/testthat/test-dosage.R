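# Dosage profiles: binning, control normalization, deletion-dip estimation,
# six-type classification and PCA clustering.

test_that("bin_coverage assigns each primary alignment to one bin", {
  ref <- fx_ref()
  empty <- fx_ctrl()$alignments[0]
  cv <- bin_coverage(empty, 2500, ref)
  expect_true(all(cv$count == 0L))
  expect_identical(nrow(cv), 800L)

  # 100 reads starting in bin 3, plus supplementary/secondary noise that
  # must not be counted
  aln <- rbind(mk_aln(paste0("r", 1:100), 0L, 7501 + (1:100), "150M"),
               mk_aln("s1", 2048L, 7600, "75S75M"),
               mk_aln("s2", 256L, 7600, "150M"))
  cv <- bin_coverage(aln, 2500, ref)
  expect_identical(cv$count[cv$bin == 3L], 100L)
  expect_identical(sum(cv$count), 100L)
  expect_error(bin_coverage(aln, 0, ref), "bin_size")
})

test_that("per-bin counts follow the Poisson coverage oracle", {
  cv <- fx_cov(fx_ctrl())
  # read starts per bin: depth * bin / read_len (reads, not pairs)
  lambda <- 10 * 2500 / 150
  z <- (cv$count - lambda) / sqrt(lambda)
  expect_lt(abs(mean(cv$count) / lambda - 1), 0.02)
  expect_gte(mean(abs(z) <= 4), 0.995)
})

test_that("normalization identity and scale invariance hold exactly", {
  cv <- fx_cov(fx_ctrl())
  prof_self <- normalize_dosage(cv, cv)
  expect_true(all(abs(prof_self$dosage - 2) < 1e-12, na.rm = TRUE))

  cv2 <- copy(cv)
  cv2[, count := count * 5L]
  setattr(cv2, "bin_size", attr(cv, "bin_size"))
  setattr(cv2, "total", sum(cv2$count))
  prof_a <- normalize_dosage(cv, fx_cov(fx_onefull()))
  prof_b <- normalize_dosage(cv2, fx_cov(fx_onefull()))
  expect_equal(prof_a$dosage, prof_b$dosage, tolerance = 1e-12)
})

test_that("carrier dosage levels follow the 2 + copies arithmetic", {
  ref <- fx_ref()
  mr <- ref$mini_region; del <- ref$deletion_interval
  # one full ring: mini region at 3
  p1 <- fx_profile(fx_onefull())
  expect_lt(abs(mean(p1[start >= mr[1] & end <= mr[2], dosage]) - 3), 0.15)
  # euploid background of the same sample stays at 2
  expect_lt(abs(mean(p1[end < mr[1], dosage]) - 2), 0.15)
  # two deleted rings: retained at 4, deletion interval back to 2
  cov20 <- bin_coverage(fx_twodel20()$alignments, 2500, ref)
  p2 <- normalize_dosage(cov20, fx_cov(fx_ctrl()), exclude = mr)
  retained <- p2[start >= mr[1] & end <= mr[2] & (end < del[1] | start > del[2])]
  expect_lt(abs(mean(retained$dosage) - 4), 0.2)
  expect_lt(abs(mean(p2[start >= del[1] & end <= del[2], dosage]) - 2), 0.2)
})

test_that("deleted-interval estimator finds the dip and only the dip", {
  ref <- fx_ref()
  mr <- ref$mini_region
  expect_null(estimate_deleted_interval(mk_profile(rep(3, 100)), mr))
  # constructed 10-bin dip recovered exactly
  prof <- mk_profile(c(rep(3, 40), rep(2, 10), rep(3, 50)))
  est <- estimate_deleted_interval(prof, mr)
  expect_identical(est, c(prof$start[41], prof$end[50]))
  # synthetic deleted mini: interval matches truth with Jaccard >= 0.8
  est2 <- estimate_deleted_interval(fx_profile(fx_onedel()), mr)
  expect_gte(jaccard(est2, ref$deletion_interval), 0.8)
})

test_that("template classification recovers all six structural types", {
  ref <- fx_ref()
  mr <- ref$mini_region; del <- ref$deletion_interval
  flat <- function(level) mk_profile(rep(level, 240))
  expect_identical(classify_mini_type(flat(2), mr, del)$type, "NO_MINI")
  expect_identical(classify_mini_type(flat(3), mr, del)$type, "ONE_FULL")
  expect_identical(classify_mini_type(flat(4), mr, del)$type, "TWO_FULL")
  # constructed 4 retained / 3 in the deletion interval
  v <- rep(4, 240)
  dsel <- which(1300001 + (0:239) * 2500 >= del[1] &
                  1300000 + (1:240) * 2500 <= del[2])
  v[dsel] <- 3
  expect_identical(classify_mini_type(mk_profile(v), mr, del)$type,
                   "FULL_PLUS_DELETED")
  # missing-bin guard
  v[seq_len(60)] <- NA
  expect_identical(classify_mini_type(mk_profile(v), mr, del)$type,
                   "UNCLASSIFIABLE")

  # synthetic fixtures match their truth
  for (sim in list(fx_ctrl(), fx_onefull(), fx_onedel())) {
    cl <- classify_mini_type(fx_profile(sim), mr, del)
    expect_identical(cl$type, sim$truth$mini_type)
    # fitted retained level is never intermediate
    expect_lt(abs(cl$retained_level - round(cl$retained_level)), 0.25)
  }
})

test_that("PCA clustering separates structural patterns", {
  ref <- fx_ref()
  same <- list(a = mk_profile(rep(2, 60), 10000L),
               b = mk_profile(rep(2, 60), 10000L),
               c = mk_profile(rep(2, 60), 10000L))
  cl <- pca_cluster(same, ref$mini_region)
  expect_identical(cl$k, 1L)

  # NO_MINI vs ONE_FULL, two samples each, with mild noise
  set.seed(1)
  two <- list(n1 = mk_profile(rnorm(60, 2, 0.05), 10000L),
              n2 = mk_profile(rnorm(60, 2, 0.05), 10000L),
              f1 = mk_profile(rnorm(60, 3, 0.05), 10000L),
              f2 = mk_profile(rnorm(60, 3, 0.05), 10000L))
  cl2 <- pca_cluster(two, ref$mini_region)
  expect_identical(cl2$k, 2L)
  expect_identical(cl2$labels[["n1"]], cl2$labels[["n2"]])
  expect_identical(cl2$labels[["f1"]], cl2$labels[["f2"]])
  expect_false(cl2$labels[["n1"]] == cl2$labels[["f1"]])
  expect_error(pca_cluster(same[1], ref$mini_region), "at least 2")
})
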