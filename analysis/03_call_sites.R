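#!/usr/bin/env Rscript
# Turn junction alignments into merged, filtered integration sites.
#
# Alignment itself is external (bwa in a real screen); here the
# simulation's truth BED stands in for the aligner's output, which lets
# the site-calling conventions be exercised end to end.

suppressPackageStartupMessages(library(pbscreen))
out_dir <- "results/analysis"

raw <- read_sites_tsv(file.path(out_dir, "sim_sites_raw.tsv"))
truth <- jsonlite::read_json(file.path(out_dir, "sim_truth.json"),
                             simplifyVector = TRUE)

# expand each site's supporting reads into alignment records: the aligner
# reports the fragment interval; the junction is the 5' end
set.seed(20240301)
idx <- rep(seq_len(nrow(raw)), raw$read_count)
len <- sample(30:120, length(idx), replace = TRUE)
aln <- data.frame(
  read_id = sprintf("aln%06d", seq_along(idx)),
  lesion_id = raw$lesion_id[idx],
  chrom = raw$chrom[idx],
  start = ifelse(raw$orientation[idx] == "+", raw$pos[idx],
                 pmax(1, raw$pos[idx] - len + 1)),
  end = ifelse(raw$orientation[idx] == "+", raw$pos[idx] + len - 1,
               raw$pos[idx]),
  strand = raw$orientation[idx],
  mapq = sample(c(0, 30, 60), length(idx), replace = TRUE,
                prob = c(0.02, 0.18, 0.8)),
  stringsAsFactors = FALSE)

fc <- site_filter_config(min_reads = 10, merge_window = 5, mapq_min = 10,
                         exclude_chromosomes = truth$donor_chromosome)
calls <- sites_from_alignments(aln, fc)
cat("converted", nrow(aln), "alignments:", nrow(calls$calls), "calls,",
    nrow(calls$rejected), "rejected (low mapq)\n")

sites <- collapse_duplicates(calls$calls)
merged <- merge_nearby(sites, fc$merge_window)
cat("collapsed to", nrow(sites), "sites; merged within",
    fc$merge_window, "bp to", nrow(merged), "\n")

for_cis <- apply_site_filters(merged, fc, apply_min_reads = FALSE)
for_genes <- apply_site_filters(merged, fc, apply_min_reads = TRUE)
cat("donor-chromosome filter removed", for_cis$removed[["chromosome"]],
    "sites; candidate list additionally drops",
    for_genes$removed[["read_depth"]], "shallow sites\n")
cat("median sites per lesion (depth-filtered):",
    stats::median(table(for_genes$sites$lesion_id)), "\n")

write_sites_tsv(for_cis$sites, file.path(out_dir, "sites_for_cis.tsv"))
write_sites_tsv(for_genes$sites,
                file.path(out_dir, "sites_candidates.tsv"))
write_sites_bed(for_cis$sites, file.path(out_dir, "sites_for_cis.bed"))
cat("wrote merged site tables under", out_dir, "\n")
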