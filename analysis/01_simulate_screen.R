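#!/usr/bin/env Rscript
# Simulate a sensitised transposon screen with known ground truth.
#
# The synthetic cohort mirrors the shape of a prostate piggyBac screen:
# tens of lesions, a handful of insertions per lesion, three planted CIS
# loci of different compactness, local hopping around the donor locus on
# chr10, PCR-duplicate jitter and a low-depth read-count contaminant.

suppressPackageStartupMessages(library(pbscreen))
out_dir <- "results/analysis"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

layout <- genome_layout(c(chr1 = 60e6, chr2 = 50e6, chr3 = 40e6,
                          chr4 = 30e6, chr10 = 40e6),
                        donor_chromosome = "chr10")
config <- screen_sim_config(
  n_lesions = 40,
  background_rate = 0.04,          # ~ 7 background sites per lesion
  planted_cis = data.frame(
    chrom = c("chr1", "chr2", "chr3"),
    center = c(20e6, 35e6, 10e6),
    width = c(2e4, 1.2e5, 3.4e5),  # compact, medium, diffuse loci
    n_insertions = c(9, 8, 10),
    n_lesions = c(6, 5, 6)),
  duplicate_rate = 0.15, duplicate_jitter_max = 5,
  read_count_mean = 60, read_count_dispersion = 2,
  low_depth_fraction = 0.15,
  local_hopping = list(enabled = TRUE, half_width = 2e6, per_lesion = 4),
  seed = 20240101)

sim <- simulate_insertions(layout, config)
cat("simulated", nrow(sim$sites), "raw integration calls across",
    length(unique(sim$sites$lesion_id)), "lesions\n")
print(sim$truth$origin_counts)

write_sites_tsv(sim$sites, file.path(out_dir, "sim_sites_raw.tsv"))
jsonlite::write_json(
  list(planted_windows = sim$truth$planted_windows,
       layout = layout$chromosomes,
       donor_chromosome = layout$donor_chromosome),
  file.path(out_dir, "sim_truth.json"), auto_unbox = TRUE, digits = NA)

# a read-level library for the trimming stage (subset of lesions keeps the
# FASTQ small)
genome <- simulate_genome(layout, seed = 20240102)
lesions <- sprintf("L%03d", 1:8)
sub <- sim$sites[sim$sites$lesion_id %in% lesions, ]
barcodes <- stats::setNames(
  c("ACGTAC", "TGCATG", "GATCGA", "CCTTAA", "AGGTCC", "TTACGG",
    "CAATGC", "GTTCAG"), lesions)
ac <- adaptor_config(barcodes,
                     transposon_tag = "TTAACCCTAGAAAGATA",
                     adaptor_tail = "GTCGACGATC",
                     transposon_ref = paste0(
                       "TTAACCCTAGAAAGATAATCATATTGTGACGTACGTTAAAGATAAT",
                       "CATGCGTAAAATTGACGCATG"))
rs <- simulate_reads(sub, genome, ac,
                     list(reads_per_site = 1, base_error_rate = 0.005,
                          seed = 20240103))
cat("emitted", nrow(rs$reads), "splinkerette reads for",
    nrow(sub), "sites\n")
write_fastq(rs$reads, file.path(out_dir, "sim_reads.fastq"))
utils::write.table(rs$truth, file.path(out_dir, "sim_reads_truth.bed"),
                   sep = "\t", quote = FALSE, row.names = FALSE,
                   col.names = FALSE)
utils::write.table(data.frame(sample_id = names(barcodes),
                              barcode = unname(barcodes)),
                   file.path(out_dir, "barcodes.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote raw sites, truth, FASTQ and barcode table under", out_dir, "\n")
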