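#' Load a gene model from GFF3 or BED6
#'
#' One record per gene with its full transcriptional span ("gene body",
#' introns included), 1-based inclusive. GFF3 files are reduced to their
#' `gene` features (all features are used when none are typed `gene`);
#' BED coordinates are converted from 0-based half-open. Overlapping genes
#' are all retained.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file.
#' @return data.frame `gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `strand`. Errors when no genes can be parsed.
#' @export
load_gene_model <- function(path) {
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "GFF3" else "BED"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "GFF3" && "type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  if (!length(gr)) stop("no gene records parsed from ", path)
  mc <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(mc) && !all(is.na(mc$ID))) as.character(mc$ID)
        else if ("Name" %in% names(mc)) as.character(mc$Name)
        else if ("name" %in% names(mc)) as.character(mc$name)
        else sprintf("gene%05d", seq_along(gr))
  sym <- if ("Name" %in% names(mc) && !all(is.na(mc$Name)))
           as.character(mc$Name)
         else if ("name" %in% names(mc)) as.character(mc$name)
         else id
  data.frame(gene_id = id, symbol = sym,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

.genes_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start, genes$end),
                         strand = ifelse(genes$strand %in% c("+", "-"),
                                         genes$strand, "*"))
}

#' Assign integration sites to gene bodies
#'
#' A site is assigned to every gene whose body contains its position
#' (`start <= pos <= end`); the relative orientation is `same` when the
#' transposon orientation equals the gene strand, `opposite` otherwise,
#' and `NA` when either strand is unknown. Sites contained in no gene are
#' returned unassigned.
#'
#' @param sites site data.frame (`chrom`, `pos`, `orientation`; a
#'   `site_id` column is used as the site key when present, else a
#'   `lesion_id:chrom:pos` key is built).
#' @param genes gene data.frame from [load_gene_model()].
#' @return list with `assignments` (data.frame `site_key`, `gene_id`,
#'   `symbol`, `relative_orientation`) and `unassigned` (character vector
#'   of site keys).
#' @export
assign_sites_to_genes <- function(sites, genes) {
  key <- if ("site_id" %in% names(sites)) sites$site_id else
    paste(sites$lesion_id, sites$chrom, sites$pos, sep = ":")
  if (!nrow(sites))
    return(list(assignments = data.frame(site_key = character(),
                                         gene_id = character(),
                                         symbol = character(),
                                         relative_orientation = character(),
                                         stringsAsFactors = FALSE),
                unassigned = character()))
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::findOverlaps(sgr, .genes_granges(genes),
                                      ignore.strand = TRUE)
  si <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  rel <- ifelse(sites$orientation[si] %in% c("+", "-") &
                  genes$strand[gi] %in% c("+", "-"),
                ifelse(sites$orientation[si] == genes$strand[gi],
                       "same", "opposite"),
                NA_character_)
  list(assignments = data.frame(site_key = key[si],
                                gene_id = genes$gene_id[gi],
                                symbol = genes$symbol[gi],
                                relative_orientation = rel,
                                stringsAsFactors = FALSE),
       unassigned = key[setdiff(seq_len(nrow(sites)), unique(si))])
}

#' Annotate CIS windows with genes
#'
#' Each CIS lists every gene whose body overlaps its window. Windows
#' overlapping no gene are annotated with the gene nearest to the peak
#' position, labelled `nearest` with its distance; windows with more than
#' one overlapping gene get a `multi_gene` flag.
#'
#' @param calls CIS data.frame from [call_cis()] or
#'   [merge_cis_across_scales()].
#' @param genes gene data.frame from [load_gene_model()].
#' @return `calls` with added columns `genes` (comma-separated symbols),
#'   `n_genes`, `multi_gene`, `nearest` (TRUE when the listed gene only
#'   neighbours the window) and `gene_distance` (bp from the peak to the
#'   nearest gene body; 0 for overlapping genes).
#' @export
annotate_cis <- function(calls, genes) {
  calls$genes <- character(nrow(calls))
  calls$n_genes <- 0L
  calls$multi_gene <- FALSE
  calls$nearest <- FALSE
  calls$gene_distance <- NA_real_
  if (!nrow(calls)) return(calls)
  ggr <- .genes_granges(genes)
  wgr <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$start, calls$end))
  hits <- GenomicRanges::findOverlaps(wgr, ggr, ignore.strand = TRUE)
  for (i in seq_len(nrow(calls))) {
    gi <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    if (length(gi)) {
      calls$genes[i] <- paste(genes$symbol[gi], collapse = ",")
      calls$n_genes[i] <- length(gi)
      calls$multi_gene[i] <- length(gi) > 1
      calls$gene_distance[i] <- 0
    } else {
      same_chr <- which(genes$chrom == calls$chrom[i])
      if (!length(same_chr)) next
      d <- pmax(genes$start[same_chr] - calls$peak[i],
                calls$peak[i] - genes$end[same_chr], 0)
      j <- same_chr[which.min(d)]
      calls$genes[i] <- genes$symbol[j]
      calls$n_genes[i] <- 0L
      calls$nearest[i] <- TRUE
      calls$gene_distance[i] <- min(d)
    }
  }
  calls
}
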