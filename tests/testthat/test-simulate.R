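test_that("generator config enforces its invariants", {
  d <- tinyDesign()
  expect_error(generatorConfig(10, 20, d, 100), "n_starch_genes")
  expect_error(generatorConfig(10, 5, d, 100, dilinker_fraction = 0.7,
                               no_anchor_fraction = 0.4), "must lie in")
  expect_error(generatorConfig(10, 5, d, 100,
                               transcript_length_range = c(10, 20)),
               "too short to host CATG")
  expect_error(generatorConfig(10, 5, d, 100,
                               expression_effects = data.frame(
                                 gene_id = "gene0001", cultivar = "Kuras",
                                 week = 12, fold = -1)),
               "fold multipliers")
  dupd <- d; dupd$key[2] <- dupd$key[1]
  expect_error(generatorConfig(10, 5, dupd, 100), "unique")
})

test_that("transcriptome generation is seed-deterministic and CATG-anchored", {
  cfg <- tinyConfig(seed = 1, n_genes = 50)
  tx1 <- simulateTranscriptome(cfg)
  tx2 <- simulateTranscriptome(cfg)
  expect_identical(as.character(tx1$transcripts), as.character(tx2$transcripts))
  expect_true(all(grepl("CATG", as.character(tx1$transcripts), fixed = TRUE)))
  # every gene has at least one transcript
  expect_setequal(unique(tx1$geneMap$gene_id), sprintf("gene%04d", 1:50))
})

test_that("pathway map assigns each starch gene to exactly one step", {
  cfg <- tinyConfig(n_genes = 30, n_starch_genes = 12)
  pm <- simulateTranscriptome(cfg)$pathwayMap
  expect_equal(nrow(pm), 12)
  expect_equal(length(unique(pm$step_name)), 6)
  expect_equal(anyDuplicated(pm$gene_id), 0)
})

test_that("read generation matches its truth table and configured layout", {
  design <- sampleDesign(cultivars = "Desiree", weeks = 9, replicates = 1:2)
  cfg <- generatorConfig(10, 4, design, mean_depth = 500, seed = 7,
                         dilinker_fraction = 0.05, no_anchor_fraction = 0.02)
  tx <- simulateTranscriptome(cfg)
  rd <- simulateReads(cfg, tx)
  # naive per-key recount of productive reads equals the truth-table sums
  reads <- as.character(rd$reads)
  for (s in design$sample_id) {
    k <- design$key[design$sample_id == s]
    withkey <- reads[startsWith(reads, k)]
    productive <- sum(substr(withkey, nchar(k) + 1, nchar(k) + 4) == "CATG")
    expect_identical(productive, sum(rd$truth[, s]))
  }
  # reruns are byte-identical
  rd2 <- simulateReads(cfg, tx)
  expect_identical(as.character(rd2$reads), reads)
})

test_that("pure productive runs emit only 96-nt reads; zero depth is empty", {
  design <- sampleDesign(cultivars = "Kuras", weeks = 9, replicates = 1:2)
  cfg <- generatorConfig(8, 4, design, mean_depth = 200, seed = 3,
                         dilinker_fraction = 0, no_anchor_fraction = 0)
  tx <- simulateTranscriptome(cfg)
  rd <- simulateReads(cfg, tx)
  expect_true(all(nchar(as.character(rd$reads)) == 96))
  ex <- extractTag(as.character(rd$reads), key_length = 4)
  expect_true(all(ex$status == "ok"))

  cfg0 <- generatorConfig(8, 4, design, mean_depth = 0, seed = 3)
  rd0 <- simulateReads(cfg0, simulateTranscriptome(cfg0))
  expect_length(rd0$reads, 0)
  expect_equal(sum(rd0$truth), 0)
})

test_that("dilinker reads are 73 nt and read-mix proportions hold at depth", {
  design <- sampleDesign(cultivars = "Kuras", weeks = 9, replicates = 1)
  cfg <- generatorConfig(10, 4, design, mean_depth = 12000, seed = 11,
                         dilinker_fraction = 0.1, no_anchor_fraction = 0.05)
  rd <- simulateReads(cfg, simulateTranscriptome(cfg))
  lens <- nchar(as.character(rd$reads))
  n <- length(rd$reads)
  expect_gte(n, 10000)
  expect_setequal(unique(lens), c(96, 73))
  n_dil <- sum(lens == 73)
  n_dec <- rd$decoys
  n_prod <- sum(rd$truth)
  expect_identical(n_dil, sum(rd$dispositionTruth$dilinker))
  expect_identical(n_prod + n_dil + n_dec, n)  # emitted reads conserve
  # proportions within 3 sigma of configuration
  for (frac in list(c(n_dil, 0.1), c(n_dec, 0.05))) {
    p <- frac[2]
    expect_lt(abs(frac[1] / n - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("the experiment orchestrator writes every pipeline input", {
  dir <- tempfile("simexp")
  cfg <- tinyConfig(seed = 2, n_genes = 10, mean_depth = 100,
                    samples = sampleDesign(cultivars = "Kuras", weeks = 9,
                                           replicates = 1:2))
  out <- simulateExperiment(cfg, dir)
  files <- c("transcripts.fa", "gene_map.tsv", "pathway_map.tsv",
             "design.tsv", "reads.fastq", "truth_counts.tsv",
             "assay_traces.tsv", "metabolite_peaks.tsv", "standards.tsv",
             "yield.tsv")
  expect_true(all(file.exists(file.path(dir, files))))
  # the written FASTQ feeds straight back into extraction
  tct <- countTags(fastq = file.path(dir, "reads.fastq"),
                   keys = cfg$samples)
  expect_equal(colSums(counts(tct)), colSums(out$reads$truth),
               ignore_attr = TRUE)
  # the written FASTA rebuilds the same index
  idx <- buildVirtualTags(file.path(dir, "transcripts.fa"), out$transcriptome$geneMap)
  expect_identical(sort(unique(tagIndex(idx)$tag)),
                   sort(unique(out$transcriptome$tagTruth$tag)))
  unlink(dir, recursive = TRUE)
})

test_that("expression effects must reference known genes", {
  design <- tinyDesign()
  cfg <- generatorConfig(10, 4, design, 100, expression_effects = data.frame(
    gene_id = "gene9999", cultivar = "Kuras", week = 12, fold = 0.1))
  expect_error(trueExpression(cfg), "unknown gene")
})

test_that("assay traces recover configured activities and ratios", {
  sim <- simulateAssayTraces(c(A = 1), noise_sd = 0, seed = 1, n_reps = 1,
                             dilution = 5)
  r <- computeRates(sim$traces)
  expect_equal(r$activity, sim$truth$activity, tolerance = 1e-12)

  sim2 <- simulateAssayTraces(c(A = 1, B = 0.46), noise_sd = 0, seed = 2)
  truth <- sim2$truth
  ratio <- mean(truth$activity[truth$cultivar == "A"]) /
    mean(truth$activity[truth$cultivar == "B"])
  expect_equal(ratio, 1 / 0.46, tolerance = 1e-12)

  sim3 <- simulateAssayTraces(c(A = 1), noise_sd = 0.01, seed = 9)
  sim4 <- simulateAssayTraces(c(A = 1), noise_sd = 0.01, seed = 9)
  expect_identical(sim3$traces, sim4$traces)
  expect_error(simulateAssayTraces(c(A = 1), noise_sd = -1), "noise_sd")
  expect_error(simulateAssayTraces(c(A = 0)), "> 0")
})

test_that("metabolite peaks round-trip exactly without noise", {
  cm <- data.frame(cultivar = "Kuras", week = 12, analyte = c("G1P", "G6P"),
                   conc_per_g = c(0.5, 0.2))
  sim <- simulateMetabolitePeaks(cm, loading_cv = 0, peak_cv = 0, n_reps = 6,
                                 seed = 1)
  expect_equal(sum(sim$peaks$analyte == "G1P"), 6)  # six replicate rows
  curves <- fitCurves(sim$standards)
  for (an in c("G1P", "G6P")) {
    p <- sim$peaks[sim$peaks$analyte == an, ]
    got <- quantifyAnalyte(p$peak_area, curves[[an]], p$tissue_mass,
                           sim$reconstitution_volume,
                           sim$extract_fraction)$conc_per_g
    expect_equal(got, rep(cm$conc_per_g[cm$analyte == an], 6),
                 tolerance = 1e-10)
  }
  # truth table carries the configured ratio verbatim
  tr <- sim$truth
  expect_equal(tr$conc_per_g[tr$analyte == "G1P"] /
                 tr$conc_per_g[tr$analyte == "G6P"], 2.5)
  expect_error(simulateMetabolitePeaks(
    data.frame(cultivar = "K", week = 1, analyte = "maltose",
               conc_per_g = 1)), "unknown analyte")
})
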