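# End-to-end orchestration: simulate (or load) a cohort, compute dosage
# profiles and mini-type calls, discover/filter/validate junctions, assign
# haplotypes, and run breakpoint enrichment.

#' Pipeline configuration
#'
#' Numeric constants of the workflow. Defaults are the study's values mapped
#' by the linear scale factor where they are genomic lengths: profile bins
#' are the scaled analog of 25 kb, clustering bins of 100 kb; the
#' pseudo-junction bin (5 kb), the split-segment separation floor (2000 bp)
#' and the enrichment windows (1 kb, 10 kb) are used unscaled, as they
#' control read-level resolution rather than genome extent. `paper_values`
#' records each paper-scale constant next to the value used.
#'
#' @param scale linear scale factor of the toy genome (default 0.1).
#' @param profile_bin,cluster_bin,pseudo_bin bin sizes in bp.
#' @param min_separation minimum split-segment separation (bp).
#' @param cluster_tolerance breakpoint clustering tolerance (bp).
#' @param windows enrichment window sizes (bp).
#' @param n_pseudo,reps null-resampling sizes.
#' @param alpha significance level.
#' @param depth,read_len,insert_mean,min_anchor simulation parameters.
#' @param seed master seed.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(scale = 0.1,
                            profile_bin = 2500L, cluster_bin = 10000L,
                            pseudo_bin = 5000L, min_separation = 2000L,
                            cluster_tolerance = 10L,
                            windows = c(1000L, 10000L),
                            n_pseudo = 10000L, reps = 1000L, alpha = 0.05,
                            depth = 10, read_len = 150L, insert_mean = 400L,
                            min_anchor = 20L, seed = 1L) {
  stopifnot(profile_bin > 0, cluster_bin > 0, pseudo_bin > 0,
            min_separation > 0, all(windows > 0), alpha > 0, alpha < 1)
  structure(list(
    scale = scale, profile_bin = as.integer(profile_bin),
    cluster_bin = as.integer(cluster_bin),
    pseudo_bin = as.integer(pseudo_bin),
    min_separation = as.integer(min_separation),
    cluster_tolerance = as.integer(cluster_tolerance),
    windows = as.integer(windows), n_pseudo = as.integer(n_pseudo),
    reps = as.integer(reps), alpha = alpha, depth = depth,
    read_len = as.integer(read_len), insert_mean = as.integer(insert_mean),
    min_anchor = as.integer(min_anchor), seed = as.integer(seed),
    paper_values = list(profile_bin = 25000, cluster_bin = 1e5,
                        pseudo_bin = 5000, min_separation = 2000,
                        windows = c(1000, 10000), n_pseudo = 10000,
                        reps = 1000, euploid_dosage = 2,
                        mini_region_mb = c(13, 19), centromere_mb = c(15, 17),
                        deletion_mb = c(16, 17.3), control_region_mb = c(13, 20))),
    class = "PipelineConfig")
}

#' Run the full workflow on a (simulated or provided) cohort
#'
#' Stages: dosage profiles normalized to the first non-carrier control and
#' six-type classification; PCA clustering of coarse-bin profiles; split
#' read junction discovery with per-sample pseudo-junction thresholds and
#' carrier-exclusivity filtering; contig assembly, in-silico validation and
#' haplotype assignment of accepted junctions; feature enrichment around
#' validated breakpoints. Deterministic given the config seed.
#'
#' @param config a `PipelineConfig`.
#' @param ref a `ReferenceBundle`; generated from the config seed when
#'   `NULL`.
#' @param cohort cohort design for simulation (see [simulate_cohort()]);
#'   default [demo_cohort()]. Ignored when `samples` is given.
#' @param samples optional pre-built list: `alignments` (pooled data.table
#'   with `sample_id`), `carriers`, `controls` (character vectors), and
#'   optionally `truth`. Supply this to run on externally read SAM files.
#' @param out_dir optional directory for TSV outputs.
#' @param run_enrichment compute the enrichment stage (default TRUE).
#' @return list of class `RunReport`: `type_calls`, `clusters`, `junctions`
#'   (all candidates with filter flags plus validation/haplotype columns),
#'   `presence` (samples x junctions support matrix), `enrichment`,
#'   `thresholds`, `config`, `truth`.
#' @export
run_pipeline <- function(config = pipeline_config(), ref = NULL,
                         cohort = NULL, samples = NULL, out_dir = NULL,
                         run_enrichment = TRUE) {
  t0 <- Sys.time()
  if (is.null(ref)) ref <- generate_reference(seed = config$seed)
  truth <- NULL
  if (is.null(samples)) {
    cohort <- as.data.table(cohort %||% demo_cohort())
    stage_log("simulating %d individuals at %gx", nrow(cohort), config$depth)
    sim <- simulate_cohort(ref, cohort, depth = config$depth,
                           read_len = config$read_len,
                           insert_mean = config$insert_mean,
                           min_anchor = config$min_anchor,
                           seed = config$seed)
    aln <- sim$alignments
    truth <- sim$truth
    carriers <- cohort[n_full + n_deleted > 0, sample_id]
    controls <- cohort[n_full + n_deleted == 0, sample_id]
  } else {
    aln <- samples$alignments
    carriers <- samples$carriers
    controls <- samples$controls
    truth <- samples$truth
  }
  if (length(controls) == 0L)
    stopf("no non-carrier control sample: dosage normalization requires one")
  control_id <- controls[1]
  ids <- unique(aln$sample_id)

  stage_log("dosage profiles (%d bp bins), typing, clustering", config$profile_bin)
  by_sample <- split(aln, by = "sample_id")
  cov_p <- lapply(by_sample, bin_coverage, bin_size = config$profile_bin,
                  chrom_length = ref)
  cov_c <- lapply(by_sample, bin_coverage, bin_size = config$cluster_bin,
                  chrom_length = ref)
  prof_p <- lapply(cov_p, normalize_dosage, control = cov_p[[control_id]],
                   exclude = ref$mini_region)
  prof_c <- lapply(cov_c, normalize_dosage, control = cov_c[[control_id]],
                   exclude = ref$mini_region)
  calls <- lapply(prof_p, classify_mini_type, mini_region = ref$mini_region,
                  deletion_interval = ref$deletion_interval)
  type_calls <- data.table(
    sample_id = names(calls),
    type = vapply(calls, `[[`, character(1), "type"),
    distance = vapply(calls, `[[`, numeric(1), "distance"),
    retained_level = vapply(calls, `[[`, numeric(1), "retained_level"),
    deletion_level = vapply(calls, `[[`, numeric(1), "deletion_level"))
  if (!is.null(truth))
    type_calls[, truth_type := vapply(truth[sample_id], `[[`, character(1),
                                      "mini_type")]
  clusters <- if (length(prof_c) >= 2L)
    pca_cluster(prof_c, ref$mini_region) else NULL

  stage_log("junction discovery (min separation %d bp)", config$min_separation)
  thresholds <- vapply(by_sample, pseudo_junction_threshold,
                       numeric(1), bin_size = config$pseudo_bin,
                       chrom_length = ref)
  evidence <- extract_split_alignments(aln, config$min_separation)
  cand <- cluster_evidence(evidence, config$cluster_tolerance)
  cand <- filter_junctions(cand, carriers, controls, thresholds)

  stage_log("validating %d accepted junction(s)", sum(cand$accepted))
  cand[, `:=`(validated = FALSE, haplotype = NA_character_,
              contig_len = NA_integer_)]
  for (i in which(cand$accepted)) {
    jr <- cand[i]
    reads <- collect_cross_junction_reads(jr, aln)
    # assemble from the best-supporting carrier (cross-junction reads are
    # extracted per line), capped for determinism and speed
    top <- names(sort(table(reads$sample_id), decreasing = TRUE))[1]
    rsub <- reads[sample_id == top][order(read_id)]
    ctg <- assemble_contig(head(rsub, 40L))
    val <- validate_contig(ctg, ref, jr)
    hap <- assign_haplotype(jr, ref, aln)
    cand[i, `:=`(validated = val$validated, haplotype = hap$call,
                 contig_len = nchar(ctg$seq))]
  }

  presence <- presence_matrix(cand[accepted == TRUE], ids)

  enr <- NULL
  if (run_enrichment) {
    bps <- breakpoints_of(cand[validated == TRUE], ref$control_region)
    if (length(bps) >= 2L) {
      stage_log("enrichment over %d breakpoints", length(bps))
      enr <- rbindlist(lapply(config$windows, function(w) {
        rbind(
          enrichment_test(bps, ref$genes, w, ref,
                          resample_null(ref$genes, ref$control_region, w, ref,
                                        config$n_pseudo, config$reps),
                          feature = "gene"),
          enrichment_test(bps, ref$repeats, w, ref,
                          resample_null(ref$repeats, ref$control_region, w, ref,
                                        config$n_pseudo, config$reps),
                          feature = "repeat"))
      }))
      enr[, significant := p_value < config$alpha]
    } else stage_log("enrichment skipped: %d validated breakpoint(s)", length(bps))
  }

  report <- structure(list(type_calls = type_calls, clusters = clusters,
                           junctions = cand, presence = presence,
                           enrichment = enr, thresholds = thresholds,
                           profiles = prof_p, config = config, truth = truth,
                           elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
                      class = "RunReport")
  if (!is.null(out_dir)) write_report(report, out_dir, ref)
  report
}

# Both breakpoints of each junction enter the set independently, restricted
# to the control region.
breakpoints_of <- function(junctions, control_region = NULL) {
  bps <- c(junctions$pos_a, junctions$pos_b)
  if (!is.null(control_region))
    bps <- bps[bps >= control_region[1] & bps <= control_region[2]]
  bps
}

presence_matrix <- function(junctions, sample_ids) {
  m <- matrix(0L, nrow = length(sample_ids), ncol = nrow(junctions),
              dimnames = list(sample_ids, junctions$junction_id))
  for (j in seq_len(nrow(junctions))) {
    sup <- junctions$support[[j]]
    keep <- names(sup) %in% sample_ids
    m[names(sup)[keep], j] <- as.integer(sup[keep])
  }
  m
}

#' Write the tables of a run report
#' @param report a `RunReport`.
#' @param out_dir output directory (created if needed).
#' @param ref the `ReferenceBundle` of the run (for dosage bed context).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, ref = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$type_calls, file.path(out_dir, "type_calls.tsv"))
  write_tsv(flatten_junctions(report$junctions),
            file.path(out_dir, "junctions.tsv"))
  if (!is.null(report$enrichment))
    write_tsv(report$enrichment, file.path(out_dir, "enrichment.tsv"))
  pres <- as.data.table(report$presence, keep.rownames = "sample_id")
  write_tsv(pres, file.path(out_dir, "junction_presence.tsv"))
  for (sid in names(report$profiles)) {
    p <- report$profiles[[sid]]
    out <- p[, .(chrom, bin_start = start - 1L, bin_end = end, dosage)]
    write_tsv(out, file.path(out_dir, paste0("dosage_", sid, ".tsv")))
  }
  invisible(out_dir)
}

#' Flatten a junction table for TSV export
#'
#' List columns are collapsed: per-sample support becomes
#' `"sample:count;..."`; read ids are dropped.
#' @param junctions candidate junction table.
#' @return plain data.table.
#' @export
flatten_junctions <- function(junctions) {
  out <- as.data.table(junctions)
  if ("support" %in% names(out))
    out[, support := vapply(support, function(s)
      paste(paste0(names(s), ":", s), collapse = ";"), character(1))]
  if ("read_ids" %in% names(out)) out[, read_ids := NULL]
  out[]
}

#' Export junctions as BEDPE
#'
#' 0-based half-open single-base intervals per breakpoint; strand encodes
#' the retained flank (`+` = left flank retained, `-` = right).
#' @param junctions junction table.
#' @param path output file.
#' @export
write_bedpe <- function(junctions, path) {
  j <- as.data.table(junctions)
  bed <- data.table(chrom1 = j$chrom_a, start1 = j$pos_a - 1L, end1 = j$pos_a,
                    chrom2 = j$chrom_b, start2 = j$pos_b - 1L, end2 = j$pos_b,
                    name = j$junction_id, score = j$n_reads,
                    strand1 = fifelse(j$side_a == "left", "+", "-"),
                    strand2 = fifelse(j$side_b == "left", "+", "-"))
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

stage_log <- function(fmt, ...) {
  message(sprintf(paste0("[ringmini %s] ", fmt),
                  format(Sys.time(), "%H:%M:%S"), ...))
}
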