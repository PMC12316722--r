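# Shared fixtures, built lazily and cached for the whole test run.
suppressMessages(library(data.table))

fx_env <- new.env(parent = emptyenv())
fx_get <- function(name, builder) {
  if (is.null(fx_env[[name]])) fx_env[[name]] <- builder()
  fx_env[[name]]
}

# default toy reference (2 Mb, mini 1.3-1.9 Mb)
fx_ref <- function() fx_get("ref", function() generate_reference(seed = 101))

# small reference (600 kb) with proportionally scaled mini system; mini is
# 15% of the chromosome so junction thresholds sit closer to depth/2
fx_small_ref <- function() fx_get("small_ref", function()
  generate_reference(length = 6e5,
                     mini_region = c(420001L, 510000L),
                     centromere = c(450001L, 480000L),
                     deletion_interval = c(465001L, 484500L),
                     control_region = c(420001L, 600000L),
                     seed = 111))

fx_ctrl <- function() fx_get("ctrl", function()
  simulate_individual(fx_ref(), mini_config(fx_ref(), 0, 0),
                      depth = 10, sample_id = "CTRL", seed = 102))

fx_onefull <- function() fx_get("onefull", function()
  simulate_individual(fx_ref(), mini_config(fx_ref(), 1, 0),
                      depth = 10, sample_id = "ONEFULL", seed = 103))

fx_onedel <- function() fx_get("onedel", function()
  simulate_individual(fx_ref(), mini_config(fx_ref(), 0, 1, extras = "default"),
                      depth = 10, sample_id = "ONEDEL", seed = 106))

fx_twodel20 <- function() fx_get("twodel20", function()
  simulate_individual(fx_ref(), mini_config(fx_ref(), 0, 2, extras = "default"),
                      depth = 20, sample_id = "TWODEL", seed = 105))

fx_cov <- function(sim, bin = 2500) bin_coverage(sim$alignments, bin, fx_ref())

fx_profile <- function(sim) {
  fx_get(paste0("prof_", sim$truth$sample_id), function()
    normalize_dosage(fx_cov(sim), fx_cov(fx_ctrl()),
                     exclude = fx_ref()$mini_region))
}

# hand-built alignment records (defaults give an unpaired primary alignment)
mk_aln <- function(qname, flag, pos, cigar, seq = "*", sa = NA_character_,
                   sample_id = "S", rname = "Chr1") {
  data.table(qname = qname, flag = as.integer(flag), rname = rname,
             pos = as.integer(pos), mapq = 60L, cigar = cigar,
             rnext = "*", pnext = 0L, tlen = 0L, seq = seq, qual = "*",
             sa = sa, sample_id = sample_id)
}

# hand-built dosage profile tiling bins from `origin`
mk_profile <- function(dosage, bin_size = 2500L, origin = 1300001L) {
  n <- length(dosage)
  p <- data.table(chrom = "Chr1", bin = seq_len(n) - 1L,
                  start = origin + (seq_len(n) - 1L) * bin_size,
                  end = origin + seq_len(n) * bin_size - 1L,
                  dosage = dosage)
  setattr(p, "bin_size", as.integer(bin_size))
  setattr(p, "class", c("DosageProfile", class(p)))
  p
}

jaccard <- function(a, b) {
  i <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  i / ((a[2] - a[1] + 1) + (b[2] - b[1] + 1) - i)
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
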