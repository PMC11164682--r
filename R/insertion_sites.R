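#' Site-level filter configuration
#'
#' Controls how alignments become integration sites and which sites the
#' screen keeps: a mapping-quality floor, per-lesion merging of positions
#' within a few bp (PCR-duplicate collapse), exclusion of the donor
#' chromosome (local hopping inflates its density), and an optional
#' strictly-greater read-depth cut used for candidate gene lists.
#'
#' @param min_reads read-depth threshold; when the depth filter is applied,
#'   sites are kept only if `read_count > min_reads`.
#' @param exclude_chromosomes chromosome names to drop (typically the donor
#'   chromosome).
#' @param merge_window bp; sites within this distance (inclusive) are
#'   transitively merged within a lesion and chromosome.
#' @param mapq_min minimum mapping quality for an alignment to count.
#' @return An object of class `site_filter_config`.
#' @export
site_filter_config <- function(min_reads = 10L,
                               exclude_chromosomes = character(),
                               merge_window = 5L, mapq_min = 10L) {
  stopifnot(min_reads >= 0, merge_window >= 0, mapq_min >= 0)
  structure(list(min_reads = as.integer(min_reads),
                 exclude_chromosomes = as.character(exclude_chromosomes),
                 merge_window = as.integer(merge_window),
                 mapq_min = as.integer(mapq_min)),
            class = "site_filter_config")
}

#' Convert junction-fragment alignments to raw integration calls
#'
#' The integration position is the 5' junction coordinate of the aligned
#' fragment: the leftmost aligned base for a + strand alignment, the
#' rightmost for a - strand alignment (the fragment runs away from the
#' transposon). Orientation is the alignment strand. Alignments below the
#' mapping-quality floor and malformed records are dropped per record, with
#' reasons logged, never by aborting.
#'
#' @param alignments data.frame with columns `read_id`, `lesion_id`,
#'   `chrom`, `start`, `end` (1-based inclusive), `strand`, `mapq`.
#' @param config a [site_filter_config()].
#' @return list with `calls` (data.frame `read_id`, `lesion_id`, `chrom`,
#'   `pos`, `orientation`) and `rejected` (data.frame `read_id`, `reason`).
#' @export
sites_from_alignments <- function(alignments, config = site_filter_config()) {
  req <- c("read_id", "lesion_id", "chrom", "start", "end", "strand",
           "mapq")
  stopifnot(all(req %in% names(alignments)))
  a <- alignments
  bad <- is.na(a$chrom) | is.na(a$start) | is.na(a$end) |
    !(a$strand %in% c("+", "-")) | a$start < 1 | a$end < a$start
  lowq <- !bad & (is.na(a$mapq) | a$mapq < config$mapq_min)
  keep <- !bad & !lowq
  calls <- data.frame(read_id = a$read_id[keep],
                      lesion_id = a$lesion_id[keep],
                      chrom = a$chrom[keep],
                      pos = ifelse(a$strand[keep] == "+",
                                   a$start[keep], a$end[keep]),
                      orientation = a$strand[keep],
                      stringsAsFactors = FALSE)
  rejected <- data.frame(
    read_id = a$read_id[!keep],
    reason = ifelse(bad[!keep], "malformed", "low_mapq"),
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(calls = calls, rejected = rejected)
}

#' Collapse identical raw calls into integration sites
#'
#' Groups calls by (lesion, chromosome, position, orientation); the group
#' size becomes the site's supporting read count.
#'
#' @param calls data.frame from [sites_from_alignments()]`$calls`.
#' @return data.frame `lesion_id`, `chrom`, `pos`, `orientation`,
#'   `read_count`, sorted by lesion, chromosome, position.
#' @export
collapse_duplicates <- function(calls) {
  if (!nrow(calls))
    return(data.frame(lesion_id = character(), chrom = character(),
                      pos = integer(), orientation = character(),
                      read_count = integer(), stringsAsFactors = FALSE))
  key <- paste(calls$lesion_id, calls$chrom, calls$pos, calls$orientation,
               sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
  out <- data.frame(lesion_id = parts[, 1], chrom = parts[, 2],
                    pos = as.integer(parts[, 3]), orientation = parts[, 4],
                    read_count = as.integer(agg$Freq),
                    stringsAsFactors = FALSE)
  out <- out[order(out$lesion_id, out$chrom, out$pos, out$orientation), ]
  rownames(out) <- NULL
  out
}

#' Merge nearby integration sites within a lesion
#'
#' Within each (lesion, chromosome), sites whose positions are within
#' `merge_window` bp of each other are transitively chained (single
#' linkage) into one merged site, negating residual PCR-duplicate
#' positions. The merged site takes the position and orientation of the
#' member with the highest read count (leftmost on ties) and the sum of
#' member read counts. Output positions within a lesion and chromosome are
#' pairwise more than `merge_window` bp apart; the operation is idempotent
#' and independent of input order.
#'
#' @param sites data.frame with `lesion_id`, `chrom`, `pos`, `orientation`,
#'   `read_count`.
#' @param merge_window bp, inclusive distance for chaining.
#' @return data.frame of merged sites with an extra `n_merged` column
#'   (number of member sites).
#' @export
merge_nearby <- function(sites, merge_window = 5L) {
  cols <- c("lesion_id", "chrom", "pos", "orientation", "read_count")
  stopifnot(all(cols %in% names(sites)))
  if (!nrow(sites)) {
    out <- sites[, cols, drop = FALSE]
    out$n_merged <- integer()
    return(out)
  }
  s <- sites[order(sites$lesion_id, sites$chrom, sites$pos,
                   -sites$read_count, sites$orientation),
             cols, drop = FALSE]
  grp <- paste(s$lesion_id, s$chrom, sep = "\r")
  new_grp <- c(TRUE, grp[-1] != grp[-nrow(s)])
  gap_break <- c(TRUE, diff(s$pos) > merge_window) | new_grp
  cluster <- cumsum(gap_break)
  pieces <- lapply(split(seq_len(nrow(s)), cluster), function(ix) {
    m <- s[ix, , drop = FALSE]
    best <- which(m$read_count == max(m$read_count))
    best <- best[m$pos[best] == min(m$pos[best])]
    best <- best[order(m$orientation[best])][1]  # "+" before "-" on full tie
    data.frame(lesion_id = m$lesion_id[1], chrom = m$chrom[1],
               pos = m$pos[best], orientation = m$orientation[best],
               read_count = sum(m$read_count), n_merged = nrow(m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$lesion_id, out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Apply the screen's site-level filters
#'
#' Removes sites on excluded chromosomes first, then (optionally) sites
#' whose read count is not strictly greater than `min_reads`. Removal
#' counts are reported per filter in application order. The depth filter is
#' off by default here because CIS calling uses the full merged site set;
#' candidate gene lists re-apply it.
#'
#' @param sites merged site data.frame.
#' @param config a [site_filter_config()].
#' @param apply_min_reads apply the strictly-greater read-depth cut.
#' @return list with `sites` (filtered data.frame) and `removed` (named
#'   integer vector: `chromosome`, `read_depth`).
#' @export
apply_site_filters <- function(sites, config, apply_min_reads = FALSE) {
  stopifnot(inherits(config, "site_filter_config"))
  drop_chr <- sites$chrom %in% config$exclude_chromosomes
  kept <- sites[!drop_chr, , drop = FALSE]
  removed <- c(chromosome = sum(drop_chr), read_depth = 0L)
  if (isTRUE(apply_min_reads)) {
    drop_rd <- kept$read_count <= config$min_reads
    removed["read_depth"] <- sum(drop_rd)
    kept <- kept[!drop_rd, , drop = FALSE]
  }
  rownames(kept) <- NULL
  list(sites = kept, removed = removed)
}

#' Read junction alignments from a SAM/BAM file
#'
#' The lesion id is taken from the read-group `ID`, or, when the file has
#' no read groups, from `lesion_id` (typically the file name stem).
#'
#' @param path SAM or BAM file (SAM is converted in a temporary directory).
#' @param lesion_id fallback lesion id.
#' @return alignment data.frame as expected by [sites_from_alignments()].
#' @export
read_alignments_sam <- function(path, lesion_id = NULL) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  ga <- GenomicAlignments::readGAlignments(
    bam, use.names = TRUE,
    param = Rsamtools::ScanBamParam(what = c("mapq"), tag = "RG"))
  rg <- S4Vectors::mcols(ga)$RG
  les <- if (!is.null(rg) && !all(is.na(rg))) as.character(rg) else {
    if (is.null(lesion_id))
      lesion_id <- sub("\\.(sam|bam)$", "", basename(path),
                       ignore.case = TRUE)
    rep(lesion_id, length(ga))
  }
  data.frame(read_id = names(ga), lesion_id = les,
             chrom = as.character(GenomicAlignments::seqnames(ga)),
             start = GenomicAlignments::start(ga),
             end = GenomicAlignments::end(ga),
             strand = as.character(GenomicAlignments::strand(ga)),
             mapq = S4Vectors::mcols(ga)$mapq,
             stringsAsFactors = FALSE)
}

#' Read junction alignments from a BED6 file
#'
#' BED is 0-based half-open; coordinates are converted to 1-based
#' inclusive. The BED score column is taken as mapping quality and the name
#' column as read id.
#'
#' @param path BED6 file.
#' @param lesion_id lesion id for every record (defaults to file stem).
#' @return alignment data.frame as expected by [sites_from_alignments()].
#' @export
read_alignments_bed <- function(path, lesion_id = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(lesion_id))
    lesion_id <- sub("\\.bed$", "", basename(path), ignore.case = TRUE)
  data.frame(read_id = if (!is.null(gr$name)) gr$name else
               sprintf("rec%06d", seq_along(gr)),
             lesion_id = lesion_id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             mapq = if (!is.null(gr$score)) as.numeric(gr$score) else NA,
             stringsAsFactors = FALSE)
}

#' Write integration sites as TSV
#'
#' @param sites site data.frame.
#' @param path output path.
#' @export
write_sites_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an integration-site TSV
#'
#' @param path TSV with columns `lesion_id`, `chrom`, `pos`, `orientation`,
#'   `read_count` (extra columns preserved).
#' @return site data.frame.
#' @export
read_sites_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("lesion_id", "chrom", "pos", "orientation",
                  "read_count") %in% names(df)))
  df
}

#' Write integration sites as BED6 (0-based half-open)
#'
#' @param sites site data.frame.
#' @param path output path.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(sites$chrom, sites$pos - 1L, sites$pos,
                    paste(sites$lesion_id, sites$pos, sep = "_"),
                    sites$read_count, sites$orientation)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
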