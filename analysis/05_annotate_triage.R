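#!/usr/bin/env Rscript
# Annotate CIS windows with genes and triage candidates by the screen's
# strength rules (depth, span, multi-gene ambiguity, blacklist).

suppressPackageStartupMessages(library(pbscreen))
out_dir <- "results/analysis"

final <- utils::read.delim(file.path(out_dir, "cis_merged.tsv"),
                           stringsAsFactors = FALSE)
sites <- read_sites_tsv(file.path(out_dir, "sites_for_cis.tsv"))
truth <- jsonlite::read_json(file.path(out_dir, "sim_truth.json"),
                             simplifyVector = TRUE)

# synthetic gene model: one gene spanning each planted window (named) plus
# a regular backbone of background genes on every chromosome
tw <- truth$planted_windows
backbone <- do.call(rbind, lapply(seq_len(nrow(truth$layout)), function(i)
  data.frame(chrom = truth$layout$name[i],
             start = seq(1e6, truth$layout$length[i] - 1e6, by = 4e6),
             stringsAsFactors = FALSE)))
backbone$end <- backbone$start + 5e4
backbone$name <- sprintf("Bg%03d", seq_len(nrow(backbone)))
planted <- data.frame(chrom = tw$chrom, start = tw$start - 5e3,
                      end = tw$end + 5e3,
                      name = c("CandA", "CandB", "Nav2"),
                      stringsAsFactors = FALSE)
genes_bed <- file.path(out_dir, "genes_synthetic.bed")
all_genes <- rbind(planted, backbone[, c("chrom", "start", "end", "name")])
utils::write.table(
  data.frame(all_genes$chrom, all_genes$start - 1L, all_genes$end,
             all_genes$name, 0L,
             rep_len(c("+", "-"), nrow(all_genes))),
  genes_bed, sep = "\t", quote = FALSE, row.names = FALSE,
  col.names = FALSE)
genes <- load_gene_model(genes_bed)
cat("gene model:", nrow(genes), "genes (synthetic)\n")

assign <- assign_sites_to_genes(sites, genes)
cat(nrow(assign$assignments), "site-gene assignments;",
    length(assign$unassigned), "sites outside gene bodies\n")
utils::write.table(assign$assignments,
                   file.path(out_dir, "site_gene_assignments.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

ann <- annotate_cis(final, genes)
rules <- triage_rules(min_supporting_reads = 10, max_span = 1e5,
                      blacklist = "Nav2")
report <- triage(ann, sites, rules)
cat("\ntriage report:\n")
print(report[, c("chrom", "start", "end", "span", "genes", "flags",
                 "verdict")])
utils::write.table(report, file.path(out_dir, "triage_report.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("strong candidates:",
    paste(report$genes[report$verdict == "strong"], collapse = ", "), "\n")
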