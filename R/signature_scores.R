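#' Per-sample gene-signature score as a sum of z-scores
#'
#' For each signature gene present in the matrix, expression is z-scored
#' across all samples (population standard deviation, divisor n); a
#' sample's signature score is the sum of its z-scores over the signature
#' genes. By construction the scores sum to zero over the full sample set.
#' Signature genes absent from the matrix or with zero variance are
#' dropped and reported.
#'
#' @param mat numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames); values assumed already normalized/log-scale.
#' @param signature character vector of signature gene labels.
#' @return list with `scores` (named numeric vector per sample) and
#'   `coverage` (list: `used`, `missing`, `zero_variance`).
#' @export
signature_score <- function(mat, signature) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)),
            !is.null(colnames(mat)))
  if (ncol(mat) < 2) stop("at least two samples required to z-score")
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat)))
    stop("duplicate gene or sample labels")
  present <- intersect(signature, rownames(mat))
  if (!length(present)) stop("no signature genes present in the matrix")
  sub <- mat[present, , drop = FALSE]
  mu <- rowMeans(sub)
  n <- ncol(sub)
  sdev <- sqrt(rowMeans((sub - mu)^2))  # population sd, divisor n
  zerovar <- sdev == 0
  used <- present[!zerovar]
  if (!length(used)) stop("all present signature genes have zero variance")
  z <- (sub[used, , drop = FALSE] - mu[used]) / sdev[used]
  scores <- colSums(z)
  list(scores = scores,
       coverage = list(used = used,
                       missing = setdiff(signature, rownames(mat)),
                       zero_variance = present[zerovar]))
}

#' Split samples into high/low groups by a gene's median expression
#'
#' Samples strictly above the median go to `high`; the rest (including
#' ties at the median) to `low` — a deterministic, documented tie rule.
#'
#' @param mat expression matrix (genes x samples).
#' @param gene gene label to split on.
#' @return list with `high`, `low` (character sample vectors), `median`,
#'   and `sizes`.
#' @export
median_split <- function(mat, gene) {
  if (!gene %in% rownames(mat)) stop("gene '", gene, "' not in matrix")
  v <- mat[gene, ]
  med <- stats::median(v)
  high <- colnames(mat)[v > med]
  low <- colnames(mat)[v <= med]
  if (!length(high))
    warning("no samples above the median of '", gene,
            "' (constant expression?)")
  list(high = high, low = low, median = med,
       sizes = c(high = length(high), low = length(low)))
}

#' Spearman rank correlation between two paired vectors
#'
#' Rho is computed on mid-ranks (average ranks for ties). The two-sided
#' p-value uses the exact permutation distribution for n <= 10 without
#' ties and the t-approximation otherwise.
#'
#' @param x,y paired numeric vectors (>= 3 observations).
#' @return list `rho`, `p_value`, `n`. A constant input yields `rho = NA`
#'   with a message in `error`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                error = "constant input vector"))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = n <= 10 && !ties))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Welch's unpaired t-test between signature scores of two groups
#'
#' @param scores named numeric vector (e.g. from [signature_score()]).
#' @param high,low sample labels of the two groups (e.g. from
#'   [median_split()]).
#' @return list with `mean_high`, `mean_low`, `t`, `p_value`, `n_high`,
#'   `n_low` and, for degenerate zero-variance inputs, a `note`.
#' @export
compare_groups <- function(scores, high, low) {
  a <- scores[high]
  b <- scores[low]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least two samples")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(mean_high = mean(a), mean_low = mean(b),
                t = if (same) 0 else sign(mean(a) - mean(b)) * Inf,
                p_value = if (same) 1 else 0,
                n_high = length(a), n_low = length(b),
                note = "both groups have zero variance"))
  }
  tt <- stats::t.test(a, b)  # Welch by default
  list(mean_high = unname(mean(a)), mean_low = unname(mean(b)),
       t = unname(tt$statistic), p_value = tt$p.value,
       n_high = length(a), n_low = length(b))
}

#' Read an expression matrix TSV (first column gene, header = samples)
#'
#' @param path TSV path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}

#' Read a signature gene list (one symbol per line)
#'
#' @param path text file path.
#' @return character vector of gene symbols.
#' @export
read_signature <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
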