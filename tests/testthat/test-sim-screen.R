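test_that("zero-rate config yields an empty site table", {
  lay <- fix_layout()
  cfg <- screen_sim_config(n_lesions = 5, background_rate = 0,
                           duplicate_rate = 0, seed = 1)
  sim <- simulate_insertions(lay, cfg)
  expect_equal(nrow(sim$sites), 0)
})

test_that("a lone planted cluster emits exactly its insertions, inside the window", {
  lay <- fix_layout()
  cfg <- screen_sim_config(
    n_lesions = 8, background_rate = 0, duplicate_rate = 0,
    planted_cis = data.frame(chrom = "chr1", center = 5e6, width = 1e4,
                             n_insertions = 20, n_lesions = 5),
    seed = 2)
  sim <- simulate_insertions(lay, cfg)
  expect_equal(nrow(sim$sites), 20)
  expect_true(all(sim$sites$origin == "planted"))
  w <- sim$truth$planted_windows
  expect_true(all(sim$sites$pos >= w$start & sim$sites$pos <= w$end))
  expect_equal(length(unique(sim$sites$lesion_id)), 5)
})

test_that("background totals match the Poisson expectation over 200 seeds", {
  lay <- genome_layout(c(chrA = 100e6))
  totals <- vapply(1:200, function(s) {
    cfg <- screen_sim_config(n_lesions = 10, background_rate = 1,
                             duplicate_rate = 0, seed = s)
    nrow(simulate_insertions(lay, cfg)$sites)
  }, 0)
  mu <- 1000  # 1/Mb * 100 Mb * 10 lesions
  se <- sqrt(mu / 200)
  expect_lt(abs(mean(totals) - mu), 3 * se)
})

test_that("simulation is deterministic and conserves origin labels", {
  lay <- fix_layout()
  cfg <- screen_sim_config(
    n_lesions = 6, background_rate = 0.5,
    planted_cis = data.frame(chrom = "chr2", center = 4e6, width = 2e4,
                             n_insertions = 15, n_lesions = 4),
    local_hopping = list(enabled = TRUE, half_width = 5e5, per_lesion = 2),
    seed = 7)
  a <- simulate_insertions(lay, cfg)
  b <- simulate_insertions(lay, cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$sites), sum(a$truth$origin_counts))
  expect_true(all(a$sites$origin %in%
                    c("background", "planted", "hopping", "duplicate")))
  hop <- a$sites[a$sites$origin == "hopping", ]
  expect_true(all(hop$chrom == "chr10"))
  dup <- a$sites[a$sites$origin == "duplicate", ]
  par <- a$sites[match(dup$parent_id, a$sites$site_id), ]
  off <- abs(dup$pos - par$pos)
  expect_true(all(off >= 1 & off <= cfg$duplicate_jitter_max))
})

test_that("a planted chromosome absent from the layout is a configuration error", {
  lay <- fix_layout()
  cfg <- screen_sim_config(
    n_lesions = 3,
    planted_cis = data.frame(chrom = "chrZ", center = 1e6, width = 1e4,
                             n_insertions = 5, n_lesions = 2))
  expect_error(simulate_insertions(lay, cfg), "chrZ")
})

test_that("simulated reads carry barcode and tag prefixes, one truth line per read", {
  lay <- genome_layout(c(chrA = 1e5))
  sites <- fix_sites("L001", "chrA", c(5000, 70000),
                     orientation = c("+", "-"), read_count = c(3, 2))
  sites$site_id <- c("S1", "S2")
  genome <- simulate_genome(lay, seed = 4)
  ac <- fix_adaptor(1)
  rs <- simulate_reads(sites, genome, ac, list(seed = 5))
  expect_equal(nrow(rs$reads), 5)
  expect_equal(nrow(rs$truth), nrow(rs$reads))
  expect_true(all(startsWith(rs$reads$sequence,
                             paste0(ac$barcodes[["L001"]],
                                    ac$transposon_tag))))
  # truth fragments equal the reference at the recorded coordinates
  for (i in seq_len(nrow(rs$truth))) {
    tr <- rs$truth[i, ]
    ref <- as.character(Biostrings::subseq(genome[[tr$chrom]],
                                           tr$start + 1L, tr$end))
    if (tr$strand == "-")
      ref <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(ref)))
    expect_identical(tr$fragment, ref)
  }
  # junction-proximal fragment end sits at the site position
  j <- ifelse(rs$truth$strand == "+", rs$truth$start + 1L, rs$truth$end)
  expect_true(all(j %in% sites$pos))
})

test_that("expression truth reports zero correlation at zero loading", {
  ex <- simulate_expression(expr_sim_config(n_genes = 50, n_samples = 30,
                                            signature_size = 10,
                                            latent_loading = 0, seed = 1))
  expect_equal(ex$truth$population_rho, 0)
})

test_that("noise-free expression couples target and score monotonically", {
  ex <- simulate_expression(expr_sim_config(n_genes = 40, n_samples = 25,
                                            signature_size = 8,
                                            latent_loading = 1.5,
                                            noise_sd = 0, seed = 2))
  ss <- signature_score(ex$matrix, ex$truth$signature_genes)
  rho <- correlate(ex$matrix[ex$truth$target_gene, ], ss$scores)$rho
  expect_equal(rho, 1)
})

test_that("the loading calibrated for Spearman 0.6 recovers it empirically", {
  a <- loading_for_spearman(0.6, noise_sd = 1, signature_size = 40)
  cfg <- expr_sim_config(n_genes = 200, n_samples = 500,
                         signature_size = 40, latent_loading = a,
                         noise_sd = 1, seed = 3)
  ex <- simulate_expression(cfg)
  expect_equal(ex$truth$population_rho, 0.6, tolerance = 1e-10)
  ss <- signature_score(ex$matrix, ex$truth$signature_genes)
  rho <- correlate(ex$matrix[ex$truth$target_gene, ], ss$scores)$rho
  expect_lt(abs(rho - 0.6), 0.1)
})
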