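#' Adaptor and barcode configuration for splinkerette libraries
#'
#' Describes the fixed read structure of a splinkerette junction library:
#' a per-sample barcode at the read start, the transposon-end tag
#' immediately after it, and the splinkerette adaptor sequence that appears
#' at the 3' end when a short fragment is read through. Barcode and tag
#' sequences are library-specific inputs and are never hard-coded.
#'
#' @param barcodes named character vector, sample id -> barcode sequence;
#'   all barcodes must be unique, non-empty and the same length.
#' @param transposon_tag transposon-end sequence expected immediately after
#'   the barcode (the junction-proximal ITR end).
#' @param adaptor_tail splinkerette adaptor sequence trimmed, together with
#'   everything 3' of it, from the read.
#' @param restriction_site recognition sequence of the fragmenting enzyme
#'   (informational metadata; fragments are not required to end in it).
#' @param max_mismatches mismatches tolerated when matching the barcode and
#'   the transposon tag (Hamming, prefix-anchored; no indels).
#' @param transposon_ref full transposon/ITR reference sequence used by
#'   [filter_transposon_only()]; may be `NULL` if that filter is not used.
#' @return An object of class `adaptor_config`.
#' @export
adaptor_config <- function(barcodes, transposon_tag, adaptor_tail,
                           restriction_site = "GATC", max_mismatches = 1L,
                           transposon_ref = NULL) {
  stopifnot(length(barcodes) >= 1, !is.null(names(barcodes)),
            all(nzchar(barcodes)), max_mismatches >= 0,
            nzchar(transposon_tag))
  if (any(duplicated(barcodes)))
    stop("two samples share an identical barcode")
  if (length(unique(nchar(barcodes))) != 1)
    stop("barcodes must all have the same length")
  structure(list(barcodes = barcodes,
                 transposon_tag = toupper(transposon_tag),
                 adaptor_tail = toupper(adaptor_tail),
                 restriction_site = toupper(restriction_site),
                 max_mismatches = as.integer(max_mismatches),
                 transposon_ref = if (is.null(transposon_ref)) NULL else
                   toupper(transposon_ref)),
            class = "adaptor_config")
}

# Hamming distance between `pattern` and the same-length prefix of each
# sequence; Inf where the sequence is shorter than the pattern.
.prefix_mismatches <- function(seqs, pattern) {
  k <- nchar(pattern)
  pref <- substr(seqs, 1L, k)
  out <- rep(Inf, length(seqs))
  ok <- nchar(pref) == k
  if (any(ok)) {
    pm <- utf8ToInt(pattern)
    out[ok] <- vapply(pref[ok],
                      function(s) sum(utf8ToInt(s) != pm), 0,
                      USE.NAMES = FALSE)
  }
  out
}

#' Demultiplex reads by prefix barcode
#'
#' Assigns each read to the unique sample whose barcode matches the read's
#' prefix within `max_mismatches` (Hamming distance, no indels). Reads
#' matching zero barcodes, or more than one (ambiguous), go to the
#' unassigned set — conservative against sample bleed-through. The barcode
#' is stripped from assigned reads.
#'
#' @param reads data.frame with columns `id`, `sequence` and optionally
#'   `quality` (carried through, trimmed in step with the sequence).
#' @param config an [adaptor_config()].
#' @return list with `samples` (named list of per-sample data.frames, one
#'   entry per configured sample), `unassigned` (data.frame) and
#'   `assignments` (data.frame `id`, `sample`; `sample` is NA when
#'   unassigned).
#' @export
demultiplex <- function(reads, config) {
  stopifnot(inherits(config, "adaptor_config"),
            all(c("id", "sequence") %in% names(reads)))
  has_q <- "quality" %in% names(reads)
  k <- nchar(config$barcodes[[1]])
  mm <- vapply(unname(config$barcodes),
               function(b) .prefix_mismatches(reads$sequence, b),
               numeric(nrow(reads)))
  mm <- matrix(mm, nrow = nrow(reads))
  hits <- mm <= config$max_mismatches
  n_hits <- rowSums(hits)
  sample_of <- rep(NA_character_, nrow(reads))
  uniq <- n_hits == 1
  sample_of[uniq] <- names(config$barcodes)[max.col(hits[uniq, ,
                                                         drop = FALSE])]
  strip <- function(df) {
    df$sequence <- substr(df$sequence, k + 1L, nchar(df$sequence))
    if (has_q) df$quality <- substr(df$quality, k + 1L, nchar(df$quality))
    rownames(df) <- NULL
    df
  }
  samples <- lapply(names(config$barcodes), function(s)
    strip(reads[!is.na(sample_of) & sample_of == s, , drop = FALSE]))
  names(samples) <- names(config$barcodes)
  unassigned <- reads[is.na(sample_of), , drop = FALSE]
  rownames(unassigned) <- NULL
  list(samples = samples, unassigned = unassigned,
       assignments = data.frame(id = reads$id, sample = sample_of,
                                stringsAsFactors = FALSE))
}

#' Trim demultiplexed reads to their genomic junction fragments
#'
#' Locates the transposon-end tag at the read start (within
#' `max_mismatches`, Hamming), removes it, then removes the splinkerette
#' adaptor tail (first exact occurrence) and everything 3' of it. The
#' intervening sequence is the genomic fragment. Reads without the tag, or
#' with nothing between tag and adaptor, are rejected with a reason rather
#' than an error.
#'
#' @param reads data.frame with columns `id`, `sequence` (barcode already
#'   removed by [demultiplex()]); an optional `lesion_id`/`sample` column is
#'   carried through.
#' @param config an [adaptor_config()].
#' @param transposon_end label recorded for the transposon side of the
#'   junction (a single library reads one end).
#' @return list with `trimmed` (data.frame `id`, `fragment`,
#'   `transposon_end`, plus any carried sample column) and `rejected`
#'   (data.frame `id`, `reason`; reason in `no_transposon_tag`,
#'   `empty_fragment`).
#' @export
trim_reads <- function(reads, config, transposon_end = "PB3") {
  stopifnot(inherits(config, "adaptor_config"),
            all(c("id", "sequence") %in% names(reads)))
  tag <- config$transposon_tag
  mm <- .prefix_mismatches(reads$sequence, tag)
  has_tag <- mm <= config$max_mismatches
  frag <- substr(reads$sequence, nchar(tag) + 1L, nchar(reads$sequence))
  ad_at <- if (nzchar(config$adaptor_tail))
    regexpr(config$adaptor_tail, frag, fixed = TRUE) else -1L
  cut <- ifelse(ad_at > 0, ad_at - 1L, nchar(frag))
  frag <- substr(frag, 1L, cut)
  empty <- has_tag & !nzchar(frag)
  keep <- has_tag & nzchar(frag)
  carried <- intersect(c("lesion_id", "sample"), names(reads))
  trimmed <- data.frame(id = reads$id[keep], fragment = frag[keep],
                        transposon_end = transposon_end,
                        stringsAsFactors = FALSE)
  for (col in carried) trimmed[[col]] <- reads[[col]][keep]
  rejected <- data.frame(
    id = reads$id[!keep],
    reason = ifelse(!has_tag[!keep], "no_transposon_tag", "empty_fragment"),
    stringsAsFactors = FALSE)
  list(trimmed = trimmed, rejected = rejected)
}

#' Discard fragments that are still transposon sequence
#'
#' A trimmed fragment that matches the transposon reference (near-exact
#' substring, either strand, within `max_mismatches`) carries no genomic
#' information and is discarded; such reads arise from internal transposon
#' priming or incomplete junctions.
#'
#' @param trimmed data.frame from [trim_reads()] (needs `id`, `fragment`).
#' @param config an [adaptor_config()] with a non-NULL `transposon_ref`.
#' @return list with `kept` (data.frame) and `discarded` (data.frame `id`,
#'   `reason` = "transposon_only").
#' @export
filter_transposon_only <- function(trimmed, config) {
  stopifnot(inherits(config, "adaptor_config"))
  if (is.null(config$transposon_ref))
    stop("transposon_ref missing from adaptor_config but filter requested")
  ref <- Biostrings::DNAString(config$transposon_ref)
  rc_ref <- Biostrings::reverseComplement(ref)
  is_tp <- vapply(trimmed$fragment, function(fr) {
    p <- Biostrings::DNAString(fr)
    Biostrings::countPattern(p, ref,
                             max.mismatch = config$max_mismatches) > 0 ||
      Biostrings::countPattern(p, rc_ref,
                               max.mismatch = config$max_mismatches) > 0
  }, logical(1), USE.NAMES = FALSE)
  discarded <- data.frame(id = trimmed$id[is_tp],
                          reason = rep("transposon_only", sum(is_tp)),
                          stringsAsFactors = FALSE)
  kept <- trimmed[!is_tp, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, discarded = discarded)
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ file (gzip-transparent).
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), sequence = unname(as.character(x)),
             quality = unname(as.character(S4Vectors::mcols(x)$qualities)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with `id`, `sequence` and optionally `quality`
#'   (constant maximum quality written when absent).
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$id
  qual <- if ("quality" %in% names(reads)) reads$quality else
    vapply(nchar(reads$sequence), function(k) strrep("I", k), "")
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read a sample_id/barcode table
#'
#' @param path TSV with columns `sample_id` and `barcode` (header required).
#' @return named character vector, sample id -> barcode.
#' @export
read_barcode_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "barcode") %in% names(df)))
  stats::setNames(toupper(df$barcode), df$sample_id)
}
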