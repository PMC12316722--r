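#!/usr/bin/env Rscript
# Step 2 -- dosage profiles and mini-type calls.
#
# Reads the cohort SAMs, bins primary alignments (2.5 kb bins, the scaled
# analog of 25 kb), normalizes each sample to the first non-carrier control
# with the euploid level fixed at 2, classifies every sample into one of
# the six mini structural types by nearest expected-dosage template, and
# clusters the coarse-bin (10 kb analog of 100 kb) profiles by PCA +
# hierarchical clustering. Writes type calls and PCA coordinates.

suppressMessages({library(ringmini); library(data.table)})
ref <- read_reference_bundle("scratch/cohort/reference")
sheet <- read_sample_sheet("results/sample_sheet.tsv")
aln <- rbindlist(lapply(seq_len(nrow(sheet)), function(i)
  read_sam(sheet$sam_path[i], sheet$sample_id[i])))

control_id <- sheet[control == TRUE, sample_id][1]
by_sample <- split(aln, by = "sample_id")
profiles <- lapply(by_sample, function(a)
  normalize_dosage(bin_coverage(a, 2500, ref),
                   bin_coverage(by_sample[[control_id]], 2500, ref),
                   exclude = ref$mini_region))
calls <- rbindlist(lapply(names(profiles), function(sid) {
  cl <- classify_mini_type(profiles[[sid]], ref$mini_region, ref$deletion_interval)
  dip <- estimate_deleted_interval(profiles[[sid]], ref$mini_region)
  data.table(sample_id = sid, type = cl$type,
             retained_level = round(cl$retained_level, 3),
             deletion_level = round(cl$deletion_level, 3),
             dip_start = if (is.null(dip)) NA_integer_ else dip[1],
             dip_end = if (is.null(dip)) NA_integer_ else dip[2])
}))
truth <- read_tsv("results/cohort_truth_types.tsv")
calls[truth, true_type := i.true_type, on = "sample_id"]

coarse <- lapply(by_sample, function(a)
  normalize_dosage(bin_coverage(a, 10000, ref),
                   bin_coverage(by_sample[[control_id]], 10000, ref),
                   exclude = ref$mini_region))
cl <- pca_cluster(coarse, ref$mini_region)
calls[, cluster := cl$labels[sample_id]]
write_tsv(calls, "results/type_calls.tsv")
write_tsv(data.table(sample_id = rownames(cl$coords), cl$coords,
                     cluster = cl$labels),
          "results/pca_coordinates.tsv")

message(sprintf("typed %d samples; %d/%d match truth; PCA clustering chose k = %d",
                nrow(calls), sum(calls$type == calls$true_type), nrow(calls), cl$k))
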