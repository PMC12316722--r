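#!/usr/bin/env Rscript
# Step 3 -- novel DNA junction discovery.
#
# Collects reads whose alignment splits into segments mapping at least
# 2 kb apart, clusters the split evidence into candidate junctions, and
# applies the two false-positive filters: per-sample pseudo-junction
# coverage thresholds (mean boundary-spanning reads of 5 kb bins, halved)
# and carrier exclusivity (zero supporting reads in every control). Also
# tests the joining-orientation mix of accepted junctions against
# uniformity.

suppressMessages({library(ringmini); library(data.table)})
ref <- read_reference_bundle("scratch/cohort/reference")
sheet <- read_sample_sheet("results/sample_sheet.tsv")
aln <- rbindlist(lapply(seq_len(nrow(sheet)), function(i)
  read_sam(sheet$sam_path[i], sheet$sample_id[i])))

thresholds <- vapply(split(aln, by = "sample_id"), pseudo_junction_threshold,
                     numeric(1), bin_size = 5000, chrom_length = ref)
evidence <- extract_split_alignments(aln, min_separation = 2000)
cand <- cluster_evidence(evidence, tolerance = 10)
cand <- filter_junctions(cand, sheet[carrier == TRUE, sample_id],
                         sheet[control == TRUE, sample_id], thresholds)
write_tsv(flatten_junctions(cand), "results/junctions.tsv")
write_bedpe(cand[accepted == TRUE], "results/junctions.bedpe")

truth <- unique(read_tsv("results/cohort_truth_junctions.tsv")[, .(pos_a, pos_b, orientation)])
sc <- score_junctions(cand[accepted == TRUE], truth, tol = 10)
ori <- orientation_chisq(cand[accepted == TRUE])
message(sprintf(paste0("%d split reads -> %d candidates -> %d accepted; ",
                       "recall of truth junctions %d/%d; orientation chi-square ",
                       "%.2f (p = %.2f)"),
                nrow(evidence), nrow(cand), sum(cand$accepted),
                sum(sc$matched), sc$n_true, ori$statistic, ori$p_value))
message(sprintf("per-sample thresholds: %.1f-%.1f reads",
                min(thresholds), max(thresholds)))
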