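# shared fixtures, built in code

fix_layout <- function() {
  genome_layout(c(chr1 = 10e6, chr2 = 8e6, chr10 = 5e6),
                donor_chromosome = "chr10")
}

fix_adaptor <- function(n_samples = 4, transposon_ref = TRUE) {
  bcs <- c("ACGTAC", "TGCATG", "GATCGA", "CCTTAA", "AGGTCC", "TTACGG")
  adaptor_config(
    stats::setNames(bcs[seq_len(n_samples)],
                    sprintf("L%03d", seq_len(n_samples))),
    transposon_tag = "TTAACCCTAGAAAGATA",
    adaptor_tail = "GTCGACGATC",
    transposon_ref = if (transposon_ref)
      paste0("TTAACCCTAGAAAGATAATCATATTGTGACGTACGTTAAAGATAATCAT",
             "GCGTAAAATTGACGCATG") else NULL)
}

fix_sites <- function(lesion, chrom, pos, orientation = "+",
                      read_count = 1L) {
  data.frame(lesion_id = rep_len(lesion, length(pos)),
             chrom = rep_len(chrom, length(pos)),
             pos = as.integer(pos),
             orientation = rep_len(orientation, length(pos)),
             read_count = rep_len(as.integer(read_count), length(pos)),
             stringsAsFactors = FALSE)
}

# brute-force single-linkage merge oracle: union-find over |pi - pj| <= w,
# representative = highest read count (leftmost tie), counts summed
oracle_merge <- function(sites, w) {
  n <- nrow(sites)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sites$lesion_id[i] == sites$lesion_id[j] &&
        sites$chrom[i] == sites$chrom[j] &&
        abs(sites$pos[i] - sites$pos[j]) <= w) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  pieces <- lapply(split(seq_len(n), root), function(ix) {
    m <- sites[ix, , drop = FALSE]
    best <- which(m$read_count == max(m$read_count))
    best <- best[m$pos[best] == min(m$pos[best])]
    best <- best[order(m$orientation[best])][1]
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

# direct per-point kernel summation (no truncation)
oracle_density <- function(positions, h, grid) {
  vapply(grid, function(g) sum(exp(-(g - positions)^2 / (2 * h^2))), 0)
}

# mid-rank Spearman rho from first principles
oracle_spearman_rho <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
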