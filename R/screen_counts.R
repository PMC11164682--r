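#' Read a screen-summary counts table
#'
#' The headline bookkeeping of a screen — animals dissected, animals in
#' which lesions were found, lesions isolated and sequenced, final
#' integration-site count — as a two-column `metric`/`value` TSV. The
#' package ships the counts of the prostate piggyBac screen it models as
#' `extdata/screen_counts.tsv`.
#'
#' @param path TSV with columns `metric` and `value`; defaults to the
#'   bundled screen summary.
#' @return named numeric vector of counts.
#' @export
read_screen_counts <- function(path = system.file("extdata",
                                                  "screen_counts.tsv",
                                                  package = "pbscreen")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("metric", "value") %in% names(df)))
  stats::setNames(as.numeric(df$value), df$metric)
}

#' Percentage of dissected animals in which lesions were found
#'
#' @param counts named vector from [read_screen_counts()] with entries
#'   `animals_dissected` and `animals_with_lesions`.
#' @return the lesion rate in percent.
#' @export
lesion_rate <- function(counts = read_screen_counts()) {
  stopifnot(all(c("animals_dissected", "animals_with_lesions") %in%
                  names(counts)),
            counts["animals_dissected"] > 0)
  unname(100 * counts["animals_with_lesions"] /
           counts["animals_dissected"])
}
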