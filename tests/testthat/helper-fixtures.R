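# Shared fixtures and independent oracles, all built in code.

tinyDesign <- function(weeks = 12) sampleDesign(weeks = weeks)

tinyConfig <- function(seed = 1, n_genes = 20, n_starch_genes = 6,
                       mean_depth = 400, samples = tinyDesign(), ...) {
  generatorConfig(n_genes = n_genes, n_starch_genes = n_starch_genes,
                  samples = samples, mean_depth = mean_depth, seed = seed, ...)
}

# the study's headline contrast: a 10-fold depression of the plastidial PGM
# step (both isoforms) in Kuras, one timepoint, biological triplicates
ppgmConfig <- function(seed, replicate_cv = 0.2, mean_depth_per_gene = 50,
                       n_genes = 30) {
  design <- sampleDesign(weeks = 12)
  eff <- data.frame(gene_id = c("gene0001", "gene0007"), cultivar = "Kuras",
                    week = 12, fold = 0.1)
  generatorConfig(n_genes = n_genes, n_starch_genes = 12, samples = design,
                  mean_depth = mean_depth_per_gene * n_genes,
                  expression_effects = eff, replicate_cv = replicate_cv,
                  gene_abundance_sdlog = 0.5, seed = seed)
}

# run the full extraction -> annotation -> quantify -> stats pipeline
runPipeline <- function(cfg, focal = "Kuras") {
  tx <- simulateTranscriptome(cfg)
  rd <- simulateReads(cfg, tx)
  tct <- countTags(rd$reads, cfg$samples)
  idx <- buildVirtualTags(tx$transcripts, tx$geneMap)
  gct <- annotateTags(tct, idx)
  st <- stepExpression(gct, cfg$samples, tx$pathwayMap)
  de <- deScan(st$replicate, st$combined, cfg$samples, focal)
  list(tx = tx, rd = rd, tct = tct, gct = gct, st = st, de = de)
}

# oracle: naive dictionary recount of reads, one read at a time
naiveRecount <- function(reads, keys) {
  reads <- toupper(as.character(reads))
  env <- new.env(parent = emptyenv())
  disp <- c(productive = 0L, rejected = 0L, unmatched = 0L)
  for (r in reads) {
    sid <- NA_character_
    for (i in seq_len(nrow(keys))) {
      k <- keys$key[i]
      if (substr(r, 1, nchar(k)) == k) { sid <- keys$sample_id[i]; break }
    }
    if (is.na(sid)) { disp["unmatched"] <- disp["unmatched"] + 1L; next }
    kl <- nchar(keys$key[match(sid, keys$sample_id)])
    if (nchar(r) >= kl + 21 && substr(r, kl + 1, kl + 4) == "CATG" &&
        !grepl("[^ACGT]", substr(r, kl + 1, kl + 21))) {
      tag <- substr(r, kl + 1, kl + 21)
      cell <- paste(tag, sid, sep = "\r")
      env[[cell]] <- (if (is.null(env[[cell]])) 0L else env[[cell]]) + 1L
      disp["productive"] <- disp["productive"] + 1L
    } else disp["rejected"] <- disp["rejected"] + 1L
  }
  cells <- ls(env)
  parts <- strsplit(cells, "\r", fixed = TRUE)
  tags <- sort(unique(vapply(parts, `[`, "", 1)))
  m <- matrix(0L, length(tags), nrow(keys),
              dimnames = list(tags, keys$sample_id))
  for (i in seq_along(cells))
    m[parts[[i]][1], parts[[i]][2]] <- env[[cells[i]]]
  list(counts = m, disp = disp)
}

# oracle: exhaustive scan for the rightmost CATG with 17 nt of headroom
exhaustiveTag <- function(seq) {
  seq <- toupper(seq)
  best <- NA_character_
  for (p in seq_len(max(nchar(seq) - 3, 0))) {
    if (substr(seq, p, p + 3) == "CATG" && p + 20 <= nchar(seq))
      best <- substr(seq, p, p + 20)
  }
  best
}

fitCurves <- function(standards) {
  out <- lapply(split(standards, standards$analyte), function(s)
    fitStandardCurve(s$concentration, s$area, s$analyte[1]))
  out
}
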