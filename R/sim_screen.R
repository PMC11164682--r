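#' Describe a genome as a set of named chromosomes
#'
#' A minimal genome layout used throughout the pipeline: chromosome names,
#' lengths, and (optionally) which chromosome carries the transposon donor
#' concatemer. Integration statistics on the donor chromosome are skewed by
#' local hopping, so downstream CIS calling excludes it by default.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp, or a
#'   data.frame with columns `name` and `length`.
#' @param donor_chromosome name of the donor chromosome, or `NULL` if the
#'   screen has none (or it is not to be tracked).
#' @return An object of class `genome_layout` with elements `chromosomes`
#'   (data.frame `name`, `length`) and `donor_chromosome`.
#' @examples
#' genome_layout(c(chr1 = 10e6, chr10 = 8e6), donor_chromosome = "chr10")
#' @export
genome_layout <- function(chromosomes, donor_chromosome = NULL) {
  if (is.data.frame(chromosomes)) {
    stopifnot(all(c("name", "length") %in% names(chromosomes)))
    chroms <- data.frame(name = as.character(chromosomes$name),
                         length = as.numeric(chromosomes$length),
                         stringsAsFactors = FALSE)
  } else {
    if (is.null(names(chromosomes)) || any(names(chromosomes) == ""))
      stop("chromosomes must be named")
    chroms <- data.frame(name = names(chromosomes),
                         length = as.numeric(chromosomes),
                         stringsAsFactors = FALSE)
  }
  if (any(duplicated(chroms$name))) stop("chromosome names must be unique")
  if (any(!is.finite(chroms$length)) || any(chroms$length <= 0))
    stop("chromosome lengths must be positive")
  if (!is.null(donor_chromosome) && !donor_chromosome %in% chroms$name)
    stop("donor_chromosome '", donor_chromosome, "' is not in the layout")
  structure(list(chromosomes = chroms, donor_chromosome = donor_chromosome),
            class = "genome_layout")
}

#' Configuration for a synthetic insertional-mutagenesis screen
#'
#' Defines the generative model used by [simulate_insertions()]: uniform
#' background insertions per lesion, planted CIS clusters shared across a
#' stated number of lesions, a local-hopping hotspot on the donor
#' chromosome, PCR-duplicate records jittered by a few bp, and a
#' negative-binomial read-count model with a low-depth contaminant so the
#' read-depth filters of the real pipeline are exercisable.
#'
#' @param n_lesions number of lesions (sequencing libraries) to simulate.
#' @param background_rate background insertions per megabase per lesion.
#' @param planted_cis `NULL`, or a data.frame with columns `chrom`, `center`
#'   (bp), `width` (bp, full window width), `n_insertions` (total across the
#'   cluster) and `n_lesions` (distinct lesions carrying them).
#' @param duplicate_rate probability that a site spawns one jittered
#'   PCR-duplicate record.
#' @param duplicate_jitter_max maximum positional jitter of a duplicate in
#'   bp; the offset is uniform on `{-max..-1, 1..max}` (never 0, so merging
#'   is exercised).
#' @param read_count_mean,read_count_dispersion mean and dispersion (`size`)
#'   of the negative-binomial supporting-read count per site (floored at 1).
#' @param low_depth_fraction probability that a site instead draws its count
#'   uniformly from 1..9, emulating poorly amplified junctions.
#' @param local_hopping list with elements `enabled` (flag), `half_width`
#'   (bp, hotspot half-width), `per_lesion` (hopping insertions per lesion)
#'   and optionally `center` (bp on the donor chromosome; defaults to its
#'   midpoint).
#' @param seed integer seed; identical seed and config give byte-identical
#'   output.
#' @return An object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_lesions,
                              background_rate = 0.5,
                              planted_cis = NULL,
                              duplicate_rate = 0.1,
                              duplicate_jitter_max = 5,
                              read_count_mean = 50,
                              read_count_dispersion = 2,
                              low_depth_fraction = 0.1,
                              local_hopping = list(enabled = FALSE,
                                                   half_width = 1e6,
                                                   per_lesion = 0,
                                                   center = NULL),
                              seed = 1L) {
  stopifnot(n_lesions >= 1, background_rate >= 0,
            duplicate_rate >= 0, duplicate_rate <= 1,
            duplicate_jitter_max >= 0,
            read_count_mean > 0, read_count_dispersion > 0,
            low_depth_fraction >= 0, low_depth_fraction <= 1)
  if (!is.null(planted_cis)) {
    stopifnot(is.data.frame(planted_cis),
              all(c("chrom", "center", "width", "n_insertions",
                    "n_lesions") %in% names(planted_cis)),
              all(planted_cis$width > 0),
              all(planted_cis$n_insertions >= 0),
              all(planted_cis$n_lesions >= 1))
  }
  hop <- utils::modifyList(list(enabled = FALSE, half_width = 1e6,
                                per_lesion = 0, center = NULL),
                           local_hopping)
  structure(list(n_lesions = as.integer(n_lesions),
                 background_rate = background_rate,
                 planted_cis = planted_cis,
                 duplicate_rate = duplicate_rate,
                 duplicate_jitter_max = as.integer(duplicate_jitter_max),
                 read_count_mean = read_count_mean,
                 read_count_dispersion = read_count_dispersion,
                 low_depth_fraction = low_depth_fraction,
                 local_hopping = hop,
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

.validate_sim_config <- function(layout, config) {
  if (!is.null(config$planted_cis)) {
    bad <- setdiff(config$planted_cis$chrom, layout$chromosomes$name)
    if (length(bad))
      stop("planted CIS chromosome(s) absent from layout: ",
           paste(bad, collapse = ", "))
  }
  if (isTRUE(config$local_hopping$enabled) &&
      is.null(layout$donor_chromosome))
    stop("local hopping enabled but the layout has no donor chromosome")
  invisible(TRUE)
}

.empty_sites <- function() {
  data.frame(site_id = character(), lesion_id = character(),
             chrom = character(), pos = integer(),
             orientation = character(), read_count = integer(),
             origin = character(), parent_id = character(),
             stringsAsFactors = FALSE)
}

#' Simulate raw integration-site calls for a synthetic screen
#'
#' Draws background insertions uniformly along each chromosome per lesion
#' (Poisson counts at `background_rate` per Mb), places each planted cluster
#' within its window across the stated number of lesions, adds
#' local-hopping insertions on the donor chromosome, spawns jittered
#' PCR-duplicate records, and assigns negative-binomial supporting-read
#' counts with a low-depth contaminant. Every emitted record carries an
#' origin label, and the returned truth record allows recovery tests
#' against the planted windows.
#'
#' @param layout a [genome_layout()].
#' @param config a [screen_sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{sites}{data.frame of raw integration calls: `site_id`,
#'       `lesion_id`, `chrom`, `pos` (1-based bp), `orientation` (+/-),
#'       `read_count`, `origin` (background | planted | hopping |
#'       duplicate), `parent_id` (parent site for duplicates, else NA).}
#'     \item{truth}{list with `planted_windows` (data.frame `chrom`,
#'       `start`, `end`, 1-based inclusive) and `origin_counts`.}
#'   }
#' @export
simulate_insertions <- function(layout, config) {
  stopifnot(inherits(layout, "genome_layout"),
            inherits(config, "screen_sim_config"))
  .validate_sim_config(layout, config)
  withr::with_seed(config$seed, {
    lesions <- sprintf("L%03d", seq_len(config$n_lesions))
    recs <- list()
    # background: Poisson per lesion x chromosome, uniform positions
    for (les in lesions) {
      for (ci in seq_len(nrow(layout$chromosomes))) {
        L <- layout$chromosomes$length[ci]
        n <- stats::rpois(1, config$background_rate * L / 1e6)
        if (n > 0)
          recs[[length(recs) + 1L]] <- data.frame(
            lesion_id = les, chrom = layout$chromosomes$name[ci],
            pos = sample.int(L, n, replace = TRUE),
            orientation = sample(c("+", "-"), n, replace = TRUE),
            origin = "background", stringsAsFactors = FALSE)
      }
    }
    # planted clusters: uniform within window, spread over chosen lesions
    planted_windows <- data.frame(chrom = character(), start = numeric(),
                                  end = numeric(), stringsAsFactors = FALSE)
    if (!is.null(config$planted_cis) && nrow(config$planted_cis)) {
      for (k in seq_len(nrow(config$planted_cis))) {
        pc <- config$planted_cis[k, ]
        L <- layout$chromosomes$length[match(pc$chrom,
                                             layout$chromosomes$name)]
        lo <- max(1, round(pc$center - pc$width / 2))
        hi <- min(L, round(pc$center + pc$width / 2))
        planted_windows <- rbind(planted_windows,
                                 data.frame(chrom = pc$chrom, start = lo,
                                            end = hi,
                                            stringsAsFactors = FALSE))
        if (pc$n_insertions == 0) next
        carriers <- sample(lesions, min(pc$n_lesions, length(lesions)))
        owner <- sample(carriers, pc$n_insertions, replace = TRUE)
        # guarantee every carrier gets at least one insertion when possible
        if (pc$n_insertions >= length(carriers))
          owner[seq_along(carriers)] <- carriers
        recs[[length(recs) + 1L]] <- data.frame(
          lesion_id = owner, chrom = pc$chrom,
          pos = lo + sample.int(hi - lo + 1L, pc$n_insertions,
                                replace = TRUE) - 1L,
          orientation = sample(c("+", "-"), pc$n_insertions,
                               replace = TRUE),
          origin = "planted", stringsAsFactors = FALSE)
      }
    }
    # local hopping: hotspot around the donor locus
    hop <- config$local_hopping
    if (isTRUE(hop$enabled) && hop$per_lesion > 0) {
      donor <- layout$donor_chromosome
      L <- layout$chromosomes$length[match(donor, layout$chromosomes$name)]
      center <- if (is.null(hop$center)) round(L / 2) else hop$center
      lo <- max(1, center - hop$half_width)
      hi <- min(L, center + hop$half_width)
      for (les in lesions) {
        n <- stats::rpois(1, hop$per_lesion)
        if (n > 0)
          recs[[length(recs) + 1L]] <- data.frame(
            lesion_id = les, chrom = donor,
            pos = lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L,
            orientation = sample(c("+", "-"), n, replace = TRUE),
            origin = "hopping", stringsAsFactors = FALSE)
      }
    }
    sites <- if (length(recs)) do.call(rbind, recs) else
      .empty_sites()[c("lesion_id", "chrom", "pos", "orientation", "origin")]
    if (nrow(sites)) {
      sites$site_id <- sprintf("S%05d", seq_len(nrow(sites)))
      sites$parent_id <- NA_character_
      # PCR duplicates: jitter uniform on +/-1..jitter_max, never 0
      if (config$duplicate_rate > 0 && config$duplicate_jitter_max > 0) {
        is_dup <- stats::runif(nrow(sites)) < config$duplicate_rate
        if (any(is_dup)) {
          par <- sites[is_dup, ]
          off <- sample.int(config$duplicate_jitter_max, nrow(par),
                            replace = TRUE) *
            sample(c(-1L, 1L), nrow(par), replace = TRUE)
          dup <- par
          dup$pos <- pmax(1L, par$pos + off)
          dup$origin <- "duplicate"
          dup$parent_id <- par$site_id
          dup$site_id <- sprintf("S%05d", nrow(sites) + seq_len(nrow(dup)))
          sites <- rbind(sites, dup)
        }
      }
      # supporting-read counts
      n <- nrow(sites)
      rc <- pmax(1L, stats::rnbinom(n, mu = config$read_count_mean,
                                    size = config$read_count_dispersion))
      low <- stats::runif(n) < config$low_depth_fraction
      rc[low] <- sample.int(9L, sum(low), replace = TRUE)
      sites$read_count <- as.integer(rc)
      sites <- sites[, c("site_id", "lesion_id", "chrom", "pos",
                         "orientation", "read_count", "origin",
                         "parent_id")]
      rownames(sites) <- NULL
    } else {
      sites <- .empty_sites()
    }
    truth <- list(planted_windows = planted_windows,
                  origin_counts = table(factor(sites$origin,
                                               levels = c("background",
                                                          "planted",
                                                          "hopping",
                                                          "duplicate"))))
    list(sites = sites, truth = truth)
  })
}

#' Generate a random reference genome for a layout
#'
#' Uniform random nucleotide sequence per chromosome. The pipeline's
#' statistics never read bases, so sequence is only needed when simulating
#' reads; base composition is uniform by design.
#'
#' @param layout a [genome_layout()].
#' @param seed integer seed.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
simulate_genome <- function(layout, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    seqs <- vapply(layout$chromosomes$length, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), "")
    names(seqs) <- layout$chromosomes$name
    Biostrings::DNAStringSet(seqs)
  })
}

#' Simulate splinkerette junction reads from integration sites
#'
#' Emits one read per supporting read of each site (or a fixed number),
#' structured as barcode + transposon-end tag + genomic fragment
#' (+ splinkerette adaptor tail when the fragment is short enough to read
#' through). The genomic fragment starts at the integration junction and
#' extends away from the transposon; its true origin is recorded in a
#' BED-like truth table (0-based half-open).
#'
#' @param sites data.frame of integration calls (needs `site_id`,
#'   `lesion_id`, `chrom`, `pos`, `orientation`, `read_count`).
#' @param genome a [Biostrings::DNAStringSet] (see [simulate_genome()]).
#' @param adaptor_config an [adaptor_config()] whose `barcodes` cover every
#'   lesion in `sites`.
#' @param read_config list: `fragment_len_min`, `fragment_len_max` (uniform
#'   fragment length in bp), `reads_per_site` (`NULL` to use each site's
#'   `read_count`, or a fixed integer), `base_error_rate` (per-base
#'   substitution probability on the genomic fragment), `with_adaptor`
#'   (append the adaptor tail), `seed`.
#' @return list with `reads` (data.frame `id`, `lesion_id`, `sequence`,
#'   `quality`) and `truth` (data.frame `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `fragment` — BED6 columns plus the error-free
#'   fragment sequence; one row per read).
#' @export
simulate_reads <- function(sites, genome, adaptor_config,
                           read_config = list()) {
  rc <- utils::modifyList(list(fragment_len_min = 30L,
                               fragment_len_max = 120L,
                               reads_per_site = NULL,
                               base_error_rate = 0,
                               with_adaptor = TRUE,
                               seed = 1L), read_config)
  stopifnot(inherits(adaptor_config, "adaptor_config"))
  missing_bc <- setdiff(unique(sites$lesion_id),
                        names(adaptor_config$barcodes))
  if (length(missing_bc))
    stop("no barcode configured for lesion(s): ",
         paste(missing_bc, collapse = ", "))
  if (!nrow(sites))
    return(list(reads = data.frame(id = character(),
                                   lesion_id = character(),
                                   sequence = character(),
                                   quality = character(),
                                   stringsAsFactors = FALSE),
                truth = data.frame()))
  withr::with_seed(as.integer(rc$seed), {
    nread <- if (is.null(rc$reads_per_site)) sites$read_count else
      rep(as.integer(rc$reads_per_site), nrow(sites))
    idx <- rep(seq_len(nrow(sites)), nread)
    n <- length(idx)
    len <- sample(seq(rc$fragment_len_min, rc$fragment_len_max), n,
                  replace = TRUE)
    chrom <- sites$chrom[idx]
    pos <- sites$pos[idx]
    ori <- sites$orientation[idx]
    L <- Biostrings::width(genome)[match(chrom, names(genome))]
    # fragment runs away from the junction; clip at chromosome ends
    start1 <- ifelse(ori == "+", pos, pmax(1, pos - len + 1L))
    end1 <- ifelse(ori == "+", pmin(L, pos + len - 1L), pos)
    frag <- as.character(Biostrings::subseq(genome[chrom], start1, end1))
    frag[ori == "-"] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(frag[ori == "-"])))
    read_frag <- if (rc$base_error_rate > 0)
      .mutate_bases(frag, rc$base_error_rate) else frag
    bc <- unname(adaptor_config$barcodes[sites$lesion_id[idx]])
    seqs <- paste0(bc, adaptor_config$transposon_tag, read_frag,
                   if (isTRUE(rc$with_adaptor)) adaptor_config$adaptor_tail
                   else "")
    ids <- sprintf("read%06d", seq_len(n))
    reads <- data.frame(id = ids, lesion_id = sites$lesion_id[idx],
                        sequence = seqs,
                        quality = vapply(nchar(seqs), function(k)
                          strrep("I", k), ""),
                        stringsAsFactors = FALSE)
    truth <- data.frame(chrom = chrom, start = start1 - 1L, end = end1,
                        name = ids, score = 0L, strand = ori,
                        fragment = frag, stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

.mutate_bases <- function(seqs, rate) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit)
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Configuration for a synthetic expression cohort
#'
#' The cohort emulates the structure assumed by signature scoring on
#' patient data: one latent pathway-activity factor shared by a target gene
#' and a set of signature genes, plus independent noise genes. The implied
#' population Spearman correlation between the target gene and the
#' signature score is reported as truth.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param signature_size number of signature genes (< n_genes).
#' @param target_gene_label row label of the target gene.
#' @param latent_loading loading of the shared factor on the target and each
#'   signature gene (per-gene expression = loading * factor + N(0, noise_sd^2)).
#' @param noise_sd standard deviation of the per-gene noise.
#' @param seed integer seed.
#' @return An object of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes = 1000, n_samples = 100,
                            signature_size = 50,
                            target_gene_label = "TARGET",
                            latent_loading = 1, noise_sd = 1, seed = 1L) {
  stopifnot(signature_size < n_genes, noise_sd >= 0, n_samples >= 2)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 signature_size = as.integer(signature_size),
                 target_gene_label = target_gene_label,
                 latent_loading = latent_loading,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "expr_sim_config")
}

#' Population Spearman correlation implied by the latent-factor model
#'
#' For target and signature genes all loading `a` on one standard-normal
#' factor with independent Gaussian noise (sd `s`), the target and the sum
#' of signature-gene z-scores are bivariate normal with Pearson correlation
#' `m a^2 / sqrt((a^2 + s^2)(m^2 a^2 + m s^2))` for `m` signature genes; the
#' Spearman correlation is then `(6/pi) asin(rho_P / 2)`.
#'
#' @param loading factor loading `a`.
#' @param noise_sd noise sd `s`.
#' @param signature_size number of signature genes `m`.
#' @return The population Spearman correlation.
#' @export
population_spearman <- function(loading, noise_sd, signature_size) {
  m <- signature_size
  a2 <- loading^2
  s2 <- noise_sd^2
  if (a2 == 0) return(0)
  denom <- sqrt((a2 + s2) * (m^2 * a2 + m * s2))
  rho_p <- m * a2 / denom
  (6 / pi) * asin(rho_p / 2)
}

#' Factor loading achieving a target population Spearman correlation
#'
#' Inverts [population_spearman()] in closed form (quadratic in the squared
#' loading).
#'
#' @param rho target population Spearman correlation in (0, 1).
#' @param noise_sd noise sd.
#' @param signature_size number of signature genes.
#' @return The loading `a > 0`.
#' @export
loading_for_spearman <- function(rho, noise_sd, signature_size) {
  stopifnot(rho > 0, rho < 1)
  m <- signature_size
  s2 <- noise_sd^2
  r2 <- (2 * sin(pi * rho / 6))^2  # implied Pearson rho, squared
  # m u^2 (1 - r2) - r2 s2 (1 + m) u - r2 s2^2 = 0, u = a^2
  A <- m * (1 - r2)
  B <- -r2 * s2 * (1 + m)
  C <- -r2 * s2^2
  u <- (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
  sqrt(u)
}

#' Simulate an expression cohort with a planted pathway factor
#'
#' @param config an [expr_sim_config()].
#' @return list with `matrix` (genes x samples, dimnames set), `truth`
#'   (list: `target_gene`, `signature_genes`, `latent_loading`,
#'   `population_rho` — the implied population Spearman correlation between
#'   target expression and the signature score — and `factor`, the latent
#'   per-sample factor values).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  withr::with_seed(config$seed, {
    g <- config$n_genes
    s <- config$n_samples
    m <- config$signature_size
    f <- stats::rnorm(s)
    mat <- matrix(stats::rnorm(g * s, sd = max(config$noise_sd, 0)),
                  nrow = g, ncol = s)
    sig_rows <- seq_len(m) + 1L
    loaded <- c(1L, sig_rows)  # target + signature genes share the factor
    mat[loaded, ] <- mat[loaded, ] +
      config$latent_loading * matrix(f, nrow = length(loaded), ncol = s,
                                     byrow = TRUE)
    sig_genes <- sprintf("SIG%03d", seq_len(m))
    rownames(mat) <- c(config$target_gene_label, sig_genes,
                       sprintf("G%05d", seq_len(g - m - 1L)))
    colnames(mat) <- sprintf("sample%03d", seq_len(s))
    rho <- population_spearman(config$latent_loading, config$noise_sd, m)
    list(matrix = mat,
         truth = list(target_gene = config$target_gene_label,
                      signature_genes = sig_genes,
                      latent_loading = config$latent_loading,
                      population_rho = rho, factor = f))
  })
}
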