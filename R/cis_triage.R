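#' Candidate-strength rules for annotated CIS calls
#'
#' Encodes the criteria a screen applies when ranking CIS loci for
#' validation: supporting read depth, genomic span of the window,
#' single-gene interpretability, a blacklist of genes recurrently flagged
#' as probable false positives in transposon screens, and (optionally)
#' support from more than one lesion.
#'
#' @param min_supporting_reads read-depth threshold; a CIS is flagged
#'   `low_read_depth` when no supporting site has
#'   `read_count > min_supporting_reads`.
#' @param max_span bp; windows longer than this are flagged `large_span`.
#' @param blacklist gene symbols known as likely screen artifacts. `Nav2`
#'   ships as the default, having been recovered above random expectation
#'   across independent transposon screens.
#' @param require_multiple_lesions flag CIS supported by a single lesion.
#' @param lenient_multi_gene when TRUE, a `multi_gene` flag alone does not
#'   demote a CIS to weak.
#' @return An object of class `triage_rules`.
#' @export
triage_rules <- function(min_supporting_reads = 10L, max_span = 1e5,
                         blacklist = "Nav2",
                         require_multiple_lesions = FALSE,
                         lenient_multi_gene = FALSE) {
  stopifnot(max_span > 0, min_supporting_reads >= 0)
  structure(list(min_supporting_reads = as.integer(min_supporting_reads),
                 max_span = max_span,
                 blacklist = as.character(blacklist),
                 require_multiple_lesions = isTRUE(require_multiple_lesions),
                 lenient_multi_gene = isTRUE(lenient_multi_gene)),
            class = "triage_rules")
}

#' Triage annotated CIS calls into strong and weak candidates
#'
#' Applies [triage_rules()] to each annotated CIS: `low_read_depth` when
#' every supporting site is at or below the read threshold (one strong
#' site clears the flag), `large_span` when the window exceeds `max_span`,
#' `multi_gene` from the annotation, `blacklisted` when any associated
#' gene is on the blacklist, `single_lesion` when enabled and only one
#' lesion supports the CIS. The verdict is `strong` iff no flag is set
#' (`multi_gene` alone tolerated under the lenient rule).
#'
#' @param annotated CIS data.frame from [annotate_cis()] (needs `chrom`,
#'   `start`, `end`, `genes`, `multi_gene`, `n_lesions`).
#' @param sites merged site data.frame from which supporting sites are
#'   looked up by containment in the window extended by the call's kernel
#'   scale (so flanking sites whose kernels build the peak count as
#'   support).
#' @param rules a [triage_rules()].
#' @return data.frame: one row per CIS with `chrom`, `peak`, `start`,
#'   `end`, `span`, `genes`, `flags` (comma-separated), `verdict`.
#' @export
triage <- function(annotated, sites, rules = triage_rules()) {
  stopifnot(inherits(rules, "triage_rules"))
  if (!nrow(annotated))
    return(data.frame(chrom = character(), peak = numeric(),
                      start = numeric(), end = numeric(), span = numeric(),
                      genes = character(), flags = character(),
                      verdict = character(), stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(annotated)), function(i) {
    cis <- annotated[i, ]
    # supporting sites within one kernel width of the window: a peak can
    # sit between flanking sites whose kernels overlap, leaving the
    # super-threshold window itself empty
    ext <- if ("scale" %in% names(cis) && is.finite(cis$scale))
      cis$scale else 0
    supp <- sites[sites$chrom == cis$chrom &
                    sites$pos >= cis$start - ext &
                    sites$pos <= cis$end + ext, , drop = FALSE]
    if (!nrow(supp))
      stop("CIS ", cis$chrom, ":", cis$start, "-", cis$end,
           " has no supporting sites in the site table")
    flags <- character()
    if (!any(supp$read_count > rules$min_supporting_reads))
      flags <- c(flags, "low_read_depth")
    span <- cis$end - cis$start + 1
    if (span > rules$max_span) flags <- c(flags, "large_span")
    if (isTRUE(cis$multi_gene)) flags <- c(flags, "multi_gene")
    genes <- strsplit(cis$genes, ",", fixed = TRUE)[[1]]
    if (any(genes %in% rules$blacklist))
      flags <- c(flags, "blacklisted")
    if (rules$require_multiple_lesions &&
        length(unique(supp$lesion_id)) <= 1)
      flags <- c(flags, "single_lesion")
    effective <- if (rules$lenient_multi_gene)
      setdiff(flags, "multi_gene") else flags
    data.frame(chrom = cis$chrom,
               peak = if ("peak" %in% names(cis)) cis$peak else NA_real_,
               start = cis$start, end = cis$end, span = span,
               genes = cis$genes,
               flags = paste(flags, collapse = ","),
               verdict = if (length(effective)) "weak" else "strong",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
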