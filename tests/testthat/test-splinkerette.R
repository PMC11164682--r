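test_that("exact barcode prefixes are assigned to their sample", {
  ac <- fix_adaptor(2)
  reads <- data.frame(id = c("r1", "r2"),
                      sequence = c(paste0("ACGTAC", "TTTT"),
                                   paste0("TGCATG", "GGGG")),
                      stringsAsFactors = FALSE)
  dm <- demultiplex(reads, ac)
  expect_equal(dm$samples$L001$id, "r1")
  expect_equal(dm$samples$L002$id, "r2")
  expect_equal(nrow(dm$unassigned), 0)
  # barcode stripped
  expect_equal(dm$samples$L001$sequence, "TTTT")
})

test_that("prefixes beyond the mismatch budget stay unassigned", {
  ac <- fix_adaptor(2)  # barcodes ACGTAC, TGCATG; max_mismatches 1
  reads <- data.frame(id = "r1", sequence = "ACAAACTTTT",
                      stringsAsFactors = FALSE)  # 2 mismatches to ACGTAC
  dm <- demultiplex(reads, ac)
  expect_equal(nrow(dm$unassigned), 1)
  expect_true(is.na(dm$assignments$sample))
})

test_that("a prefix within range of two barcodes is ambiguous, hence unassigned", {
  ac <- adaptor_config(c(A = "ACGT", B = "ACGA"),
                       transposon_tag = "TTAA", adaptor_tail = "GTCGAC",
                       max_mismatches = 1)
  # Hamming oracle: ACGT is 0 from A and 1 from B -> matches both within 1
  hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_equal(hd("ACGT", "ACGT"), 0)
  expect_equal(hd("ACGT", "ACGA"), 1)
  dm <- demultiplex(data.frame(id = "r1", sequence = "ACGTTTTT",
                               stringsAsFactors = FALSE), ac)
  expect_equal(nrow(dm$unassigned), 1)
})

test_that("identical barcodes for different samples are rejected at config time", {
  expect_error(adaptor_config(c(A = "ACGT", B = "ACGT"),
                              transposon_tag = "TTAA",
                              adaptor_tail = "GTCGAC"),
               "identical barcode")
})

test_that("demultiplexing is exhaustive, disjoint and order-invariant", {
  ac <- fix_adaptor(3)
  set.seed(11)
  seqs <- vapply(1:60, function(i) {
    bc <- sample(c(unname(ac$barcodes), "NNNNNN"), 1)
    paste0(bc, paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                     collapse = ""))
  }, "")
  reads <- data.frame(id = sprintf("r%02d", 1:60), sequence = seqs,
                      stringsAsFactors = FALSE)
  dm <- demultiplex(reads, ac)
  ids <- c(unlist(lapply(dm$samples, `[[`, "id")), dm$unassigned$id)
  expect_setequal(ids, reads$id)
  expect_equal(length(ids), nrow(reads))  # disjoint
  perm <- sample(nrow(reads))
  dm2 <- demultiplex(reads[perm, ], ac)
  expect_equal(dm2$assignments$sample[order(dm2$assignments$id)],
               dm$assignments$sample[order(dm$assignments$id)])
})

test_that("trimming recovers the fragment between tag and adaptor", {
  ac <- fix_adaptor(1)
  frag <- "ACGTACGTACGT"
  reads <- data.frame(
    id = c("ok", "empty", "notag"),
    sequence = c(paste0(ac$transposon_tag, frag, ac$adaptor_tail),
                 paste0(ac$transposon_tag, ac$adaptor_tail),
                 paste0("GGGGGGGGGGGGGGGGG", frag)),
    stringsAsFactors = FALSE)
  tr <- trim_reads(reads, ac)
  expect_equal(tr$trimmed$id, "ok")
  expect_equal(tr$trimmed$fragment, frag)
  expect_setequal(tr$rejected$reason[tr$rejected$id == "empty"],
                  "empty_fragment")
  expect_setequal(tr$rejected$reason[tr$rejected$id == "notag"],
                  "no_transposon_tag")
  expect_equal(nrow(tr$trimmed) + nrow(tr$rejected), nrow(reads))
})

test_that("a tag with one mismatch is still trimmed; without adaptor the tail is kept", {
  ac <- fix_adaptor(1)
  tag1 <- ac$transposon_tag
  substr(tag1, 3, 3) <- ifelse(substr(tag1, 3, 3) == "A", "C", "A")
  tr <- trim_reads(data.frame(id = "r", sequence = paste0(tag1, "ACGTT"),
                              stringsAsFactors = FALSE), ac)
  expect_equal(tr$trimmed$fragment, "ACGTT")
})

test_that("transposon-only fragments are discarded with a conserving log", {
  ac <- fix_adaptor(1)
  trimmed <- data.frame(
    id = c("tp", "gen"),
    fragment = c(substr(ac$transposon_ref, 5, 30),
                 "ACGTGTCAGTTACGGATCAAGGTCAG"),
    stringsAsFactors = FALSE)
  fl <- filter_transposon_only(trimmed, ac)
  expect_equal(fl$discarded$id, "tp")
  expect_equal(fl$discarded$reason, "transposon_only")
  expect_equal(fl$kept$id, "gen")
  expect_equal(nrow(fl$kept) + nrow(fl$discarded), nrow(trimmed))
  ac2 <- fix_adaptor(1, transposon_ref = FALSE)
  expect_error(filter_transposon_only(trimmed, ac2), "transposon_ref")
})

test_that("trimming a noisy simulated library recovers fragment boundaries", {
  # 0.5% per-base substitutions on the genomic fragment: boundaries must
  # still be recovered; content differs only by the planted substitutions
  lay <- genome_layout(c(chrA = 5e5))
  cfg <- screen_sim_config(n_lesions = 2, background_rate = 550,
                           duplicate_rate = 0, seed = 21)
  sim <- simulate_insertions(lay, cfg)
  genome <- simulate_genome(lay, seed = 22)
  ac <- fix_adaptor(2)
  rs <- simulate_reads(sim$sites, genome, ac,
                       list(reads_per_site = 2, base_error_rate = 0.005,
                            seed = 23))
  expect_gte(nrow(rs$reads), 1000)
  dm <- demultiplex(rs$reads, ac)
  tr <- trim_reads(do.call(rbind, c(dm$samples, make.row.names = FALSE)),
                   ac)
  truth <- rs$truth[match(tr$trimmed$id, rs$truth$name), ]
  len_ok <- nchar(tr$trimmed$fragment) == truth$end - truth$start
  expect_gte(mean(len_ok), 0.99)
  mm_rate <- mapply(function(a, b) {
    if (nchar(a) != nchar(b)) return(1)
    mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, tr$trimmed$fragment, truth$fragment)
  expect_gte(mean(mm_rate <= 0.05), 0.99)
})

test_that("FASTQ round-trips through write and read", {
  reads <- data.frame(id = c("a", "b"), sequence = c("ACGT", "GGTTAA"),
                      quality = c("IIII", "IIIIII"),
                      stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_equal(back, reads)
})
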