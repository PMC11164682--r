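#' Type-I error of CIS calling on null screens
#'
#' Simulates screens with uniform background insertions only (no planted
#' clusters), runs the full merge-and-call pipeline on each, and reports
#' the fraction of chromosome-by-scale tests that yield at least one CIS
#' call. Under a calibrated caller this fraction stays at or below the
#' nominal alpha.
#'
#' @param n_screens number of null screens.
#' @param layout a [genome_layout()] (donor chromosome, if any, is excluded
#'   from the accounting like it is from calling).
#' @param n_lesions,background_rate generator settings per screen.
#' @param config a [cis_config()]; its `seed` is offset per screen.
#' @param seed base seed.
#' @return list: `rate` (false-positive fraction), `n_tests`, `n_calls`.
#' @export
cis_type1_simulation <- function(n_screens, layout, n_lesions = 10,
                                 background_rate = 0.3,
                                 config = cis_config(scales = 1e4,
                                                     n_permutations = 199),
                                 seed = 1L) {
  excl <- union(config$exclude_chromosomes,
                if (is.null(layout$donor_chromosome)) character() else
                  layout$donor_chromosome)
  test_chroms <- setdiff(layout$chromosomes$name, excl)
  n_tests <- 0L
  n_hit <- 0L
  n_calls <- 0L
  for (r in seq_len(n_screens)) {
    sim <- simulate_insertions(layout, screen_sim_config(
      n_lesions = n_lesions, background_rate = background_rate,
      duplicate_rate = 0, seed = seed + r))
    merged <- merge_nearby(sim$sites[, c("lesion_id", "chrom", "pos",
                                         "orientation", "read_count")])
    cfg <- config
    cfg$seed <- (config$seed + 131L * r) %% .Machine$integer.max
    calls <- call_cis(merged, layout, cfg)
    for (chrom in intersect(test_chroms, unique(merged$chrom))) {
      for (h in config$scales) {
        n_tests <- n_tests + 1L
        k <- sum(calls$chrom == chrom & calls$scale == h)
        n_calls <- n_calls + k
        if (k > 0) n_hit <- n_hit + 1L
      }
    }
  }
  list(rate = n_hit / n_tests, n_tests = n_tests, n_calls = n_calls)
}

#' Power of CIS calling to recover a planted cluster
#'
#' Replicates a screen with one planted cluster over uniform background
#' sites and reports how often a CIS window overlapping the true planted
#' window is called.
#'
#' @param n_reps replicates.
#' @param chrom_length chromosome length in bp.
#' @param cluster_sites,cluster_width planted cluster: number of sites and
#'   window width (bp), centred mid-chromosome.
#' @param cluster_lesions distinct lesions carrying the cluster.
#' @param background_sites expected background sites on the chromosome
#'   (across all lesions).
#' @param n_lesions lesions per screen.
#' @param config a [cis_config()]; seed offset per replicate.
#' @param seed base seed.
#' @return list: `power` (recovery fraction), `n_reps`, `recovered`.
#' @export
cis_power_simulation <- function(n_reps, chrom_length = 1e7,
                                 cluster_sites = 20, cluster_width = 1e4,
                                 cluster_lesions = 5,
                                 background_sites = 50, n_lesions = 5,
                                 config = cis_config(scales = 1e4,
                                                     n_permutations = 199),
                                 seed = 1L) {
  layout <- genome_layout(stats::setNames(chrom_length, "chrS"))
  rate <- background_sites / n_lesions / (chrom_length / 1e6)
  recovered <- 0L
  for (r in seq_len(n_reps)) {
    sim <- simulate_insertions(layout, screen_sim_config(
      n_lesions = n_lesions, background_rate = rate,
      duplicate_rate = 0,
      planted_cis = data.frame(chrom = "chrS", center = chrom_length / 2,
                               width = cluster_width,
                               n_insertions = cluster_sites,
                               n_lesions = cluster_lesions),
      seed = seed + r))
    merged <- merge_nearby(sim$sites[, c("lesion_id", "chrom", "pos",
                                         "orientation", "read_count")])
    cfg <- config
    cfg$seed <- (config$seed + 257L * r) %% .Machine$integer.max
    calls <- call_cis(merged, layout, cfg)
    w <- sim$truth$planted_windows
    if (nrow(calls) &&
        any(calls$start <= w$end[1] & calls$end >= w$start[1]))
      recovered <- recovered + 1L
  }
  list(power = recovered / n_reps, n_reps = n_reps, recovered = recovered)
}
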