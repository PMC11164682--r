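test_that("junction coordinates follow the strand convention and mapq floor", {
  aln <- data.frame(read_id = c("r1", "r2", "r3", "r4"),
                    lesion_id = "L001", chrom = "chr1",
                    start = c(1000, 1000, 1000, NA),
                    end = c(1050, 1050, 1050, 1050),
                    strand = c("+", "-", "+", "+"),
                    mapq = c(60, 60, 5, 60),
                    stringsAsFactors = FALSE)
  res <- sites_from_alignments(aln, site_filter_config(mapq_min = 10))
  expect_equal(res$calls$pos[res$calls$read_id == "r1"], 1000)
  expect_equal(res$calls$pos[res$calls$read_id == "r2"], 1050)
  expect_equal(res$rejected$reason[res$rejected$read_id == "r3"],
               "low_mapq")
  expect_equal(res$rejected$reason[res$rejected$read_id == "r4"],
               "malformed")
  expect_equal(nrow(res$calls) + nrow(res$rejected), nrow(aln))
})

test_that("duplicate collapsing counts reads and keys on orientation", {
  calls <- data.frame(
    read_id = sprintf("r%02d", 1:15), lesion_id = "L001", chrom = "chr1",
    pos = c(rep(1000, 12), rep(1000, 2), 2000),
    orientation = c(rep("+", 12), rep("-", 2), "+"),
    stringsAsFactors = FALSE)
  sites <- collapse_duplicates(calls)
  expect_equal(nrow(sites), 3)
  expect_equal(sites$read_count[sites$pos == 1000 &
                                  sites$orientation == "+"], 12)
  expect_equal(sites$read_count[sites$pos == 1000 &
                                  sites$orientation == "-"], 2)
  expect_equal(sum(sites$read_count), nrow(calls))
})

test_that("nearby sites merge to the best-supported coordinate", {
  s <- fix_sites("L001", "chr1", c(1000, 1003), read_count = c(12, 3))
  m <- merge_nearby(s, 5)
  expect_equal(nrow(m), 1)
  expect_equal(m$pos, 1000)
  expect_equal(m$read_count, 15)
  # strict boundary: distance 6 > 5 stays unmerged
  s2 <- fix_sites("L001", "chr1", c(1000, 1006))
  expect_equal(nrow(merge_nearby(s2, 5)), 2)
  # inclusive boundary: distance 5 merges
  s3 <- fix_sites("L001", "chr1", c(1000, 1005))
  expect_equal(nrow(merge_nearby(s3, 5)), 1)
  # transitive chain
  s4 <- fix_sites("L001", "chr1", c(1000, 1004, 1008))
  expect_equal(nrow(merge_nearby(s4, 5)), 1)
  # different lesions never merge
  s5 <- fix_sites(c("L001", "L002"), "chr1", c(1000, 1002))
  expect_equal(nrow(merge_nearby(s5, 5)), 2)
})

test_that("merging matches the brute-force single-linkage oracle exhaustively", {
  for (w in c(2L, 5L)) {
    for (k in 1:4) {
      combos <- utils::combn(10L, k)
      for (ci in seq_len(ncol(combos))) {
        pos <- combos[, ci]
        rc <- ((pos * 7L) %% 5L) + 1L  # deterministic counts incl. ties
        s <- fix_sites("L001", "chr1", pos,
                       orientation = rep(c("+", "-"),
                                         length.out = length(pos)),
                       read_count = rc)
        got <- merge_nearby(s, w)
        want <- oracle_merge(s, w)
        expect_equal(got, want,
                     info = sprintf("w=%d pos=%s", w,
                                    paste(pos, collapse = ",")))
      }
    }
  }
})

test_that("merging is idempotent and input-order invariant on random inputs", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(1:8, 1)
    s <- fix_sites(sample(c("L001", "L002"), n, replace = TRUE),
                   sample(c("chr1", "chr2"), n, replace = TRUE),
                   sample(1:30, n, replace = TRUE),
                   orientation = sample(c("+", "-"), n, replace = TRUE),
                   read_count = sample(1:20, n, replace = TRUE))
    s <- collapse_duplicates(
      data.frame(read_id = seq_len(sum(s$read_count)),
                 lesion_id = rep(s$lesion_id, s$read_count),
                 chrom = rep(s$chrom, s$read_count),
                 pos = rep(s$pos, s$read_count),
                 orientation = rep(s$orientation, s$read_count),
                 stringsAsFactors = FALSE))
    m1 <- merge_nearby(s, 5)
    expect_equal(merge_nearby(m1, 5)[names(s)], m1[names(s)])
    perm <- sample(nrow(s))
    expect_equal(merge_nearby(s[perm, ], 5), m1)
    expect_equal(sum(m1$read_count), sum(s$read_count))
    d <- unlist(lapply(split(m1$pos, paste(m1$lesion_id, m1$chrom)),
                       function(p) diff(sort(p))))
    expect_true(all(d > 5))
  }
})

test_that("site filters remove donor-chromosome and shallow sites in order", {
  cfg <- site_filter_config(min_reads = 10,
                            exclude_chromosomes = "chr10")
  s <- fix_sites("L001", c("chr1", "chr1", "chr1", "chr10"),
                 c(100, 200, 300, 400),
                 read_count = c(10, 11, 50, 99))
  res <- apply_site_filters(s, cfg, apply_min_reads = TRUE)
  expect_equal(res$removed[["chromosome"]], 1)
  expect_equal(res$removed[["read_depth"]], 1)  # exactly 10 is removed
  expect_setequal(res$sites$pos, c(200, 300))   # 11 is kept
  # depth filter off by default
  res2 <- apply_site_filters(s, cfg)
  expect_equal(nrow(res2$sites), 3)
})

test_that("SAM alignments round-trip into calls with read groups as lesions", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:100000",
    "@RG\tID:L001\tSM:L001",
    paste("r1", 0, "chr1", 1000, 60, "51M", "*", 0, 0,
          strrep("A", 51), strrep("I", 51), "RG:Z:L001", sep = "\t"),
    paste("r2", 16, "chr1", 1000, 60, "51M", "*", 0, 0,
          strrep("A", 51), strrep("I", 51), "RG:Z:L001", sep = "\t"),
    paste("r3", 0, "chr1", 5000, 3, "51M", "*", 0, 0,
          strrep("A", 51), strrep("I", 51), "RG:Z:L001", sep = "\t")),
    sam)
  aln <- read_alignments_sam(sam)
  expect_equal(nrow(aln), 3)
  expect_true(all(aln$lesion_id == "L001"))
  res <- sites_from_alignments(aln, site_filter_config())
  expect_equal(res$calls$pos[res$calls$read_id == "r1"], 1000)
  expect_equal(res$calls$pos[res$calls$read_id == "r2"], 1050)
  expect_equal(res$rejected$read_id, "r3")
})

test_that("site tables round-trip through TSV and BED export is 0-based", {
  s <- fix_sites("L001", "chr1", c(1000, 2000), read_count = c(5, 7))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_sites_tsv(s, tsv)
  expect_equal(read_sites_tsv(tsv), s)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(s, bed)
  b <- utils::read.delim(bed, header = FALSE)
  expect_equal(b$V2, s$pos - 1)
  expect_equal(b$V3, s$pos)
})
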