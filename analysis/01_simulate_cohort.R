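#!/usr/bin/env Rscript
# Step 1 -- simulate the study cohort.
#
# Builds the toy reference (2 Mb chromosome; mini region 1.3-1.9 Mb with a
# centromere analog at 1.5-1.7 Mb) and a cohort of 18 individuals, three of
# each mini structural type, sequenced at 10x paired-end 150 bp. Deleted
# mini forms lack the 1.6-1.73 Mb analog interval and carry an inverted
# 30 kb block, so the cohort harbours four distinct novel junctions in all
# three orientation classes. Alignments go to scratch/ as plain-text SAM;
# the sample sheet and the junction/type truth go to results/.

suppressMessages({library(ringmini); library(data.table)})
dir.create("scratch/cohort", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

SEED <- 20
ref <- generate_reference(seed = SEED)
write_reference_bundle(ref, "scratch/cohort/reference")

cohort <- demo_cohort(3L)
sim <- simulate_cohort(ref, cohort, depth = 10, seed = SEED)

sheet <- data.table(sample_id = cohort$sample_id,
                    sam_path = file.path("scratch/cohort",
                                         paste0(cohort$sample_id, ".sam")),
                    carrier = cohort$n_full + cohort$n_deleted > 0,
                    control = cohort$n_full + cohort$n_deleted == 0)
for (sid in cohort$sample_id)
  write_sam(sim$alignments[sample_id == sid], sheet[sample_id == sid, sam_path], ref)
write_sample_sheet(sheet, "results/sample_sheet.tsv")

truth_jn <- rbindlist(lapply(sim$truth, function(tr)
  if (nrow(tr$junctions)) cbind(sample_id = tr$sample_id, tr$junctions)))
write_tsv(truth_jn, "results/cohort_truth_junctions.tsv")
write_tsv(data.table(sample_id = cohort$sample_id, true_type = cohort$type),
          "results/cohort_truth_types.tsv")

message(sprintf("simulated %d individuals (%d alignment records); %d distinct true junctions",
                nrow(cohort), nrow(sim$alignments),
                nrow(unique(truth_jn[, .(pos_a, pos_b)]))))
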