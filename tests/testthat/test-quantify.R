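test_that("normalization scales to the target library size", {
  m <- matrix(c(10, 990, 25, 975) * 1000, 2, 2,
              dimnames = list(c("g1", "g2"), c("A", "B")))
  # a library already at 2,000,000 is unchanged
  m2 <- m; m2[, 1] <- c(5e5, 15e5)
  norm <- normalizeCounts(m2)
  expect_equal(norm[, 1], m2[, 1])
  # count 10 in a 1,000,000-tag library doubles
  m3 <- matrix(c(10, 999990), 2, 1, dimnames = list(c("a", "b"), "L"))
  expect_equal(normalizeCounts(m3)["a", "L"], 20)
  # random tables: every column sums to the scale within 1e-6 relative
  set.seed(1)
  r <- matrix(rpois(200, 50), 20, 10,
              dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10)))
  expect_equal(colSums(normalizeCounts(r)), rep(2e6, 10),
               tolerance = 1e-6, ignore_attr = TRUE)
  # multiplying a library's raw counts by k leaves its normalized column alone
  r2 <- r; r2[, 3] <- r[, 3] * 7
  expect_equal(normalizeCounts(r2)[, 3], normalizeCounts(r)[, 3])
  # zero-total libraries are a hard, named error
  rz <- r; rz[, 2] <- 0
  expect_error(normalizeCounts(rz), "s2")
})

test_that("replicate pooling sums raw counts, skipping missing libraries", {
  design <- data.frame(
    sample_id = c("d9r1", "d9r2", "d9r3", "k15r1", "k15r2", "j9r2"),
    cultivar = c("Desiree", "Desiree", "Desiree", "Kuras", "Kuras",
                 "Jutlandia"),
    year = 2008L, week = c(9L, 9L, 9L, 15L, 15L, 9L))
  m <- matrix(1, 1, 6, dimnames = list("g", design$sample_id))
  m[1, ] <- c(826191, 1661343, 973030, 796137, 213351, 533883)
  comb <- combineReplicates(m, design)
  expect_equal(comb[1, "Desiree_2008_wk9"], 3460564)
  # a missing replicate is simply absent from the sum
  expect_equal(comb[1, "Kuras_2008_wk15"], 1009488)
  # a single-replicate group passes through unchanged
  expect_equal(comb[1, "Jutlandia_2008_wk9"], 533883)
  expect_error(combineReplicates(
    matrix(1, 1, 1, dimnames = list("g", "unknown")), design),
    "absent from design")
})

test_that("step aggregation sums member genes and conserves totals", {
  pm <- data.frame(step_name = c("stepA", "stepA", "stepB"),
                   gene_id = c("g1", "g2", "g3"))
  m <- matrix(c(5, 7, 3, 11), 4, 1,
              dimnames = list(c("g1", "g2", "g3", "g4"), "L"))
  st <- aggregateSteps(m, pm)
  ex <- SummarizedExperiment::assay(st, "expression")
  expect_equal(ex["stepA", "L"], 12)
  expect_equal(ex["stepB", "L"], 3)
  expect_equal(ex["non_pathway", "L"], 11)
  expect_equal(colSums(ex), colSums(m))
  # empty map: everything is non-pathway
  st0 <- aggregateSteps(m, pm[0, ])
  expect_equal(SummarizedExperiment::assay(st0, "expression")["non_pathway", "L"],
               sum(m))
  # a gene mapped to two steps violates the pathway-map invariant
  bad <- rbind(pm, data.frame(step_name = "stepB", gene_id = "g1"))
  expect_error(aggregateSteps(m, bad), "more than one step")
  # pathway genes missing from the table contribute zero, with a warning
  pm2 <- rbind(pm, data.frame(step_name = "stepB", gene_id = "g9"))
  expect_warning(st2 <- aggregateSteps(m, pm2), "g9")
  expect_equal(SummarizedExperiment::assay(st2, "expression")["stepB", "L"], 3)
})

test_that("starch fraction is the mapped share of raw library counts", {
  m <- matrix(c(10, 30, 60), 3, 1, dimnames = list(c("a", "b", "c"), "L"))
  expect_equal(starchFraction(m, data.frame(gene_id = c("a", "b", "c")))[["L"]],
               100)
  expect_equal(starchFraction(m, data.frame(gene_id = character(0)))[["L"]], 0)
  expect_equal(starchFraction(m, data.frame(gene_id = "a"))[["L"]], 10)
})

test_that("a configured 1% starch share is recovered within Poisson noise", {
  design <- sampleDesign(cultivars = "Desiree", weeks = 9, replicates = 1:3)
  cfg <- generatorConfig(20, 2, design, mean_depth = 20000, seed = 17,
                         dilinker_fraction = 0, no_anchor_fraction = 0,
                         replicate_cv = 0)
  tx <- simulateTranscriptome(cfg)
  genes <- sprintf("gene%04d", 1:20)
  starch <- tx$pathwayMap$gene_id
  w <- setNames(rep(0.99 / 18, 20), genes)
  w[starch] <- 0.01 / 2
  expr <- matrix(cfg$mean_depth * w, 20, 3,
                 dimnames = list(genes, design$sample_id))
  rd <- simulateReads(cfg, tx, expression = expr)
  gct <- annotateTags(countTags(rd$reads, design),
                      buildVirtualTags(tx$transcripts, tx$geneMap))
  frac <- starchFraction(counts(gct), tx$pathwayMap)
  n <- colSums(counts(gct))
  expect_true(all(abs(frac / 100 - 0.01) < 3 * sqrt(0.01 / n)))
})

test_that("pipeline pools raw counts before normalizing", {
  design <- sampleDesign(cultivars = c("Desiree", "Kuras"), weeks = 9)
  cfg <- generatorConfig(15, 6, design, mean_depth = 400, seed = 9)
  out <- runPipeline(cfg, focal = "Kuras")
  m <- counts(out$gct)
  manual <- aggregateSteps(
    normalizeCounts(.mat <- sapply(
      split(design$sample_id, paste0(design$cultivar, "_2008_wk9")),
      function(s) rowSums(m[, s]))), out$tx$pathwayMap)
  expect_equal(SummarizedExperiment::assay(out$st$combined, "expression"),
               SummarizedExperiment::assay(manual, "expression")[
                 , colnames(out$st$combined)])
  # SEM is sd/sqrt(n) of per-replicate normalized step values
  repl <- SummarizedExperiment::assay(out$st$replicate, "expression")
  grp <- design$sample_id[design$cultivar == "Kuras"]
  expect_equal(SummarizedExperiment::assay(out$st$combined, "sem")[
    , "Kuras_2008_wk9"],
    apply(repl[, grp], 1, sd) / sqrt(3))
})
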