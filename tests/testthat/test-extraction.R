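test_that("key tables must be distinct and prefix-free", {
  expect_error(keyTable(c("ACGT", "ACGT"), c("S1", "S2")), "distinct")
  expect_error(keyTable(c("AC", "ACGT"), c("S1", "S2")), "prefix")
  expect_error(keyTable("ACXT", "S1"), "A/C/G/T")
  kt <- keyTable(c("acgt", "TTAA"), c("S1", "S2"))
  expect_identical(kt$key, c("ACGT", "TTAA"))
})

test_that("demultiplexing matches exact key prefixes only", {
  kt <- keyTable(c("ACGT", "TGCA"), c("S1", "S2"))
  expect_identical(demultiplex("ACGTCATGAAA", kt), "S1")
  expect_identical(demultiplex("TTTTCATGAAA", kt), NA_character_)
  expect_identical(demultiplex("", kt), NA_character_)
  expect_identical(demultiplex(c("TGCANNN", "ACGT"), kt), c("S2", "S1"))
})

test_that("tag extraction returns CATG+17 or a reasoned rejection", {
  tag17 <- strrep("A", 17)
  ok <- extractTag(paste0("ACGT", "CATG", tag17, "GGGG"), 4)
  expect_identical(ok$status, "ok")
  expect_identical(ok$tag, paste0("CATG", tag17))
  # spurious dilinker: 73 nt, no anchor after the key
  dilinker <- paste0("ACGT", strrep("T", 69))
  expect_identical(extractTag(dilinker, 4)$status, "no_anchor")
  # anchor but only 16 nt of tail
  expect_identical(extractTag(paste0("ACGT", "CATG", strrep("A", 16)), 4)$status,
                   "too_short")
  # read ends before the anchor can be checked
  expect_identical(extractTag("ACGTCA", 4)$status, "too_short")
  # non-ACGT base inside the tag
  expect_identical(extractTag(paste0("ACGT", "CATG", "AAAAAAAANAAAAAAAA"), 4)$status,
                   "ambiguous_base")
  # case-insensitive input, uppercase canonical tag
  low <- extractTag(paste0("acgt", "catg", tolower(tag17)), 4)
  expect_identical(low$tag, paste0("CATG", tag17))
})

test_that("tag counting equals the generator truth when no decoys exist", {
  design <- sampleDesign(cultivars = c("Desiree", "Kuras"), weeks = 9,
                         replicates = 1:2)
  cfg <- generatorConfig(12, 4, design, mean_depth = 300, seed = 2,
                         dilinker_fraction = 0, no_anchor_fraction = 0)
  tx <- simulateTranscriptome(cfg)
  rd <- simulateReads(cfg, tx)
  tct <- countTags(rd$reads, design)
  tag_of <- tx$tagTruth$tag[match(rownames(rd$truth)[rd$truth[, 1] >= 0],
                                  tx$tagTruth$gene_id)]
  truth_by_tag <- rd$truth
  rownames(truth_by_tag) <- tag_of
  truth_by_tag <- truth_by_tag[rowSums(truth_by_tag) > 0, , drop = FALSE]
  truth_by_tag <- truth_by_tag[order(rownames(truth_by_tag)), , drop = FALSE]
  expect_identical(unname(counts(tct)[, colnames(truth_by_tag)]),
                   unname(truth_by_tag) + 0)
})

test_that("empty input gives an empty table with zero totals", {
  kt <- keyTable("ACGT", "S1")
  tct <- countTags(character(0), kt)
  expect_equal(dim(counts(tct)), c(0L, 1L))
  expect_equal(sum(dispositions(tct)[, -1]), 0)
})

test_that("counting is additive over concatenated read streams", {
  design <- sampleDesign(cultivars = "Desiree", weeks = 9, replicates = 1:3)
  cfg1 <- generatorConfig(10, 4, design, mean_depth = 200, seed = 5)
  cfg2 <- generatorConfig(10, 4, design, mean_depth = 150, seed = 6)
  tx <- simulateTranscriptome(cfg1)
  r1 <- as.character(simulateReads(cfg1, tx)$reads)
  r2 <- as.character(simulateReads(cfg2, tx)$reads)
  t1 <- counts(countTags(r1, design))
  t2 <- counts(countTags(r2, design))
  tc <- counts(countTags(c(r1, r2), design))
  tags <- sort(union(rownames(t1), rownames(t2)))
  add <- matrix(0, length(tags), ncol(t1), dimnames = list(tags, colnames(t1)))
  add[rownames(t1), ] <- add[rownames(t1), ] + t1
  add[rownames(t2), ] <- add[rownames(t2), ] + t2
  expect_equal(tc, add)
})

test_that("streaming counts equal a naive dictionary recount", {
  design <- sampleDesign(cultivars = c("Desiree", "Kuras"), weeks = 9,
                         replicates = 1:2)
  cfg <- generatorConfig(15, 5, design, mean_depth = 100, seed = 8,
                         dilinker_fraction = 0.1, no_anchor_fraction = 0.05)
  rd <- simulateReads(cfg, simulateTranscriptome(cfg))
  reads <- as.character(rd$reads)
  expect_lte(length(reads), 1000)
  oracle <- naiveRecount(reads, design)
  tct <- countTags(reads, design, chunk_size = 97L)  # force several chunks
  expect_equal(unname(counts(tct)[, colnames(oracle$counts)]),
               unname(oracle$counts) + 0)
  d <- dispositions(tct)
  expect_identical(sum(d$productive), as.integer(oracle$disp["productive"]))
  expect_identical(sum(d$no_anchor + d$too_short + d$ambiguous_base),
                   as.integer(oracle$disp["rejected"]))
  expect_identical(sum(d$unmatched), as.integer(oracle$disp["unmatched"]))
  # conservation: every read is accounted for exactly once
  expect_identical(sum(d[, c("productive", "no_anchor", "too_short",
                             "ambiguous_base", "unmatched")]),
                   length(reads))
  # unmatched reads are exactly the generator's decoys
  expect_identical(sum(d$unmatched), as.integer(rd$decoys))
})

test_that("FASTQ files round-trip and malformed records are named", {
  design <- sampleDesign(cultivars = "Desiree", weeks = 9, replicates = 1)
  cfg <- generatorConfig(6, 2, design, mean_depth = 50, seed = 4)
  rd <- simulateReads(cfg, simulateTranscriptome(cfg))
  fq <- tempfile(fileext = ".fastq")
  writeFastq(rd$reads, fq)
  tct_file <- countTags(fastq = fq, keys = design)
  tct_mem <- countTags(rd$reads, design)
  expect_equal(counts(tct_file), counts(tct_mem))

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "oops", "IIII"), bad)
  expect_error(countTags(fastq = bad, keys = design), "record 2")
  writeLines(c("@r1", "ACGT", "+"), bad)
  expect_error(countTags(fastq = bad, keys = design), "truncated")
})
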