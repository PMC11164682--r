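test_that("the unnormalized kernel has unit height and the closed-form falloff", {
  h <- 1e4
  tr <- kernel_density(5e5, h, grid = c(5e5, 5e5 + h))
  expect_equal(tr$values[1], 1)
  expect_equal(tr$values[2], exp(-1 / 2))
  expect_equal(length(kernel_density(numeric(), h)$values), 0)
})

test_that("grid densities equal direct per-point summation within 1e-9", {
  set.seed(5)
  pos <- runif(50, 1, 1e7)
  h <- 1e4
  tr <- kernel_density(pos, h)
  direct <- oracle_density(pos, h, tr$grid)
  expect_lt(max(abs(tr$values - direct)), 1e-9)
})

test_that("density superposes additively over site subsets", {
  set.seed(6)
  a <- runif(20, 1, 1e6)
  b <- runif(30, 1, 1e6)
  grid <- seq(0, 1e6, by = 1000)
  fa <- kernel_density(a, 1e4, grid = grid)$values
  fb <- kernel_density(b, 1e4, grid = grid)$values
  fab <- kernel_density(c(a, b), 1e4, grid = grid)$values
  expect_equal(fab, fa + fb, tolerance = 1e-12)
})

test_that("single-site permutation maxima are 1 up to grid resolution", {
  h <- 1e4
  null <- permutation_null(1, 1e7, h, 50, grid_step = h / 10, seed = 3)
  # nearest grid point is within step/2, bounding the height from below
  expect_true(all(null <= 1 & null >= exp(-(h / 10)^2 / (8 * h^2))))
  expect_true(all(abs(null - 1) < 2e-3))
})

test_that("null maxima increase stochastically with site count", {
  h <- 1e4
  m5 <- permutation_null(5, 1e7, h, 200, seed = 4)
  m20 <- permutation_null(20, 1e7, h, 200, seed = 4)
  qs <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(stats::quantile(m20, qs) >= stats::quantile(m5, qs)))
  expect_gt(mean(m20), mean(m5))
  # determinism
  expect_identical(m5, permutation_null(5, 1e7, h, 200, seed = 4))
})

test_that("the alpha threshold follows the order-statistic convention", {
  null <- sort(runif(19, 0, 5))
  expect_equal(null_threshold(null, 0.05), max(null))
  null199 <- sort(runif(199, 0, 5))
  expect_equal(null_threshold(null199, 0.05), null199[190])
})

test_that("an empty site set yields an empty call list", {
  lay <- fix_layout()
  calls <- call_cis(fix_sites(character(), character(), integer()),
                    lay, cis_config(scales = 1e4, n_permutations = 19))
  expect_equal(nrow(calls), 0)
})

test_that("a planted cluster is called and donor-chromosome sites are ignored", {
  lay <- fix_layout()
  set.seed(8)
  sites <- rbind(
    fix_sites("L001", "chr1", round(runif(30, 1, 1e7))),
    fix_sites(sprintf("L%03d", 1:3), "chr1",
              round(rnorm(15, 5e6, 3e3)), read_count = 20),
    fix_sites("L001", "chr10", round(rnorm(40, 2.5e6, 1e4))))
  cc <- call_cis(sites, lay,
                 cis_config(scales = 1e4, n_permutations = 199, seed = 2))
  expect_true(all(cc$chrom != "chr10"))
  hit <- cc[cc$chrom == "chr1" & cc$start <= 5e6 & cc$end >= 5e6, ]
  expect_gte(nrow(hit), 1)
  expect_lt(hit$p_adjusted[1], 0.05)
  expect_equal(hit$n_lesions[1], 3)
  expect_true(hit$start[1] <= hit$peak[1] & hit$peak[1] <= hit$end[1])
})

test_that("calls are equivariant under translation of all sites", {
  lay <- genome_layout(c(chrA = 1e7))
  set.seed(9)
  base <- c(round(runif(30, 2e6, 8e6)), round(rnorm(12, 4e6, 2e3)))
  delta <- 123456
  cfg <- cis_config(scales = 1e4, n_permutations = 99, seed = 5)
  c1 <- call_cis(fix_sites("L001", "chrA", base), lay, cfg)
  c2 <- call_cis(fix_sites("L001", "chrA", base + delta), lay, cfg)
  expect_equal(nrow(c1), nrow(c2))
  expect_equal(c2$peak, c1$peak + delta)
  expect_equal(c2$start, c1$start + delta)
  expect_equal(c2$end, c1$end + delta)
  expect_equal(c2$height, c1$height)
  expect_equal(c2$p_adjusted, c1$p_adjusted)
})

test_that("raising alpha never removes a called locus", {
  lay <- genome_layout(c(chrA = 1e7))
  set.seed(10)
  sites <- fix_sites("L001", "chrA",
                     c(round(runif(40, 1, 1e7)),
                       round(rnorm(10, 3e6, 2e3)),
                       round(rnorm(6, 7e6, 2e3))))
  strict <- call_cis(sites, lay, cis_config(scales = 1e4, alpha = 0.01,
                                            n_permutations = 199, seed = 6))
  loose <- call_cis(sites, lay, cis_config(scales = 1e4, alpha = 0.05,
                                           n_permutations = 199, seed = 6))
  for (i in seq_len(nrow(strict)))
    expect_true(any(loose$chrom == strict$chrom[i] &
                      loose$start <= strict$end[i] &
                      loose$end >= strict$start[i]))
})

test_that("cross-scale merging keeps the most significant representative", {
  calls <- data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    peak = c(5e6, 5.01e6, 1e6),
    start = c(4.99e6, 4.9e6, 0.99e6), end = c(5.02e6, 5.1e6, 1.01e6),
    scale = c(1e4, 1e5, 1e4), height = c(8, 6, 4),
    n_sites = c(8L, 10L, 4L), n_lesions = c(3L, 4L, 2L),
    p_adjusted = c(0.01, 0.03, 0.02), stringsAsFactors = FALSE)
  merged <- merge_cis_across_scales(calls)
  expect_equal(nrow(merged), 2)
  m1 <- merged[merged$chrom == "chr1", ]
  expect_equal(m1$p_adjusted, 0.01)
  expect_equal(m1$scale, 1e4)
  expect_equal(m1$n_members, 2)
  expect_equal(m1$merged_start, 4.9e6)
  expect_equal(m1$merged_end, 5.1e6)
  # disjoint windows pass through
  expect_equal(merged[merged$chrom == "chr2", ]$n_members, 1)
  # identical call at two scales collapses with both in provenance
  dup <- calls[c(1, 1), ]
  dup$scale <- c(1e4, 3e4)
  dup$p_adjusted <- c(0.02, 0.02)
  md <- merge_cis_across_scales(dup)
  expect_equal(nrow(md), 1)
  expect_equal(md$scale, 1e4)  # smallest h on p tie
  expect_equal(md$n_members, 2)
})
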