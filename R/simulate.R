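#' @importFrom Biostrings DNAStringSet BStringSet readDNAStringSet writeXStringSet width
NULL

.STEP_NAMES <- c("plastidial phosphoglucomutase",
                 "cytosolic phosphoglucomutase",
                 "AGPase",
                 "starch synthase",
                 "starch branching enzyme",
                 "sucrose synthase")
.STEP_EC <- c("5.4.2.2", "5.4.2.2", "2.7.7.27", "2.4.1.21", "2.4.1.18",
              "2.4.1.13")

#' Deterministic sample identification keys
#'
#' Evenly spaced selection from the lexicographic enumeration of all
#' `key_length`-mers; equal-length keys are automatically distinct and
#' prefix-free.
#'
#' @param n Number of keys.
#' @param key_length Key length in nt (default 4).
#' @return Character vector of `n` keys.
#' @export
makeKeys <- function(n, key_length = 4L) {
  total <- 4L^key_length
  if (n > total)
    stop(sprintf("cannot make %d distinct keys of length %d", n, key_length))
  bases <- c("A", "C", "G", "T")
  idx <- floor(seq(0L, total - 1L, length.out = n))
  vapply(idx, function(i) {
    k <- character(key_length)
    for (p in seq_len(key_length)) {
      k[key_length - p + 1L] <- bases[(i %% 4L) + 1L]
      i <- i %/% 4L
    }
    paste(k, collapse = "")
  }, character(1))
}

#' Full-factorial sample design with identification keys
#'
#' One pooled sequencing run per design: every (cultivar, year, week,
#' replicate) combination receives a unique key. Sample ids are
#' `cultivar_year_wkW_rR`.
#'
#' @param cultivars Character vector of cultivar labels.
#' @param years Integer vector of trial years.
#' @param weeks Integer vector of weeks after planting.
#' @param replicates Integer vector of replicate numbers (default `1:3`,
#'   biological triplicates).
#' @param key_length Key length in nt.
#' @return `data.frame` with columns `sample_id`, `cultivar`, `year`, `week`,
#'   `replicate`, `key`.
#' @examples
#' head(sampleDesign(c("Desiree", "Kuras"), weeks = c(9, 12)))
#' @export
sampleDesign <- function(cultivars = c("Desiree", "Jutlandia", "Kuras"),
                         years = 2008L, weeks = c(9L, 12L, 15L, 18L, 21L),
                         replicates = 1:3, key_length = 4L) {
  d <- expand.grid(replicate = as.integer(replicates),
                   week = as.integer(weeks),
                   year = as.integer(years),
                   cultivar = cultivars,
                   stringsAsFactors = FALSE)
  d <- d[, c("cultivar", "year", "week", "replicate")]
  d$sample_id <- sprintf("%s_%d_wk%d_r%d", d$cultivar, d$year, d$week,
                         d$replicate)
  d$key <- makeKeys(nrow(d), key_length)
  d[, c("sample_id", "cultivar", "year", "week", "replicate", "key")]
}

#' Configuration for the synthetic DeepSAGE experiment generator
#'
#' Bundles every knob of the generators and validates the invariants:
#' spurious-read fractions must leave room for productive reads, starch genes
#' are a subset of all genes, fold multipliers are positive, and transcripts
#' must be long enough to host a CATG anchor plus a 17-nt tag.
#'
#' @param n_genes Number of genes in the synthetic transcriptome.
#' @param n_starch_genes Number of genes assigned to starch-pathway steps.
#' @param samples Sample design as returned by [sampleDesign()].
#' @param mean_depth Expected productive reads per sample.
#' @param transcript_length_range Integer pair, transcript length bounds (nt).
#' @param dilinker_fraction Expected fraction of spurious linker-linker (73
#'   nt, no tag insert) reads.
#' @param no_anchor_fraction Expected fraction of decoy reads carrying an
#'   unknown identification key.
#' @param expression_effects `data.frame(gene_id, cultivar, week, fold)` of
#'   fold multipliers applied to expected expression (e.g. `fold = 0.1` for a
#'   10-fold depression).
#' @param replicate_cv Coefficient of variation of the per-gene, per-replicate
#'   log-normal expression factor.
#' @param gene_abundance_sdlog Spread (sdlog) of the log-normal baseline
#'   abundance across genes.
#' @param n_steps Number of metabolic steps in the synthetic pathway map.
#' @param step_names,step_ec Step labels and EC numbers (recycled/truncated to
#'   `n_steps`).
#' @param multi_transcript_fraction Fraction of genes given a second isoform
#'   sharing the 3' tag.
#' @param key_length Identification-key length (nt).
#' @param seed Integer master seed; every generator derives its stream from it
#'   (transcriptome: `seed`, expression: `seed + 1`, reads: `seed + 2`).
#' @return A validated `GeneratorConfig` (classed list).
#' @examples
#' cfg <- generatorConfig(n_genes = 20, n_starch_genes = 6,
#'                        samples = sampleDesign(weeks = 12),
#'                        mean_depth = 400, seed = 1)
#' @export
generatorConfig <- function(n_genes, n_starch_genes, samples, mean_depth,
                            transcript_length_range = c(300L, 1500L),
                            dilinker_fraction = 0.05,
                            no_anchor_fraction = 0.02,
                            expression_effects = NULL,
                            replicate_cv = 0.2,
                            gene_abundance_sdlog = 1,
                            n_steps = 6L,
                            step_names = .STEP_NAMES,
                            step_ec = .STEP_EC,
                            multi_transcript_fraction = 0.1,
                            key_length = 4L,
                            seed = 1L) {
  .assertScalarNumber(n_genes, "n_genes", positive = TRUE)
  .assertScalarNumber(n_starch_genes, "n_starch_genes", positive = TRUE)
  .assertScalarNumber(mean_depth, "mean_depth")
  if (mean_depth < 0) stop("'mean_depth' must be >= 0")
  if (n_starch_genes > n_genes)
    stop("n_starch_genes must not exceed n_genes")
  if (dilinker_fraction < 0 || no_anchor_fraction < 0 ||
      dilinker_fraction + no_anchor_fraction >= 1)
    stop("dilinker_fraction + no_anchor_fraction must lie in [0, 1)")
  if (length(transcript_length_range) != 2L ||
      transcript_length_range[1] > transcript_length_range[2])
    stop("transcript_length_range must be an increasing integer pair")
  if (transcript_length_range[1] < 21L + key_length)
    stop("transcript_length_range too short to host CATG + 17 nt")
  if (!is.null(expression_effects)) {
    need <- c("gene_id", "cultivar", "week", "fold")
    if (!all(need %in% names(expression_effects)))
      stop("expression_effects needs columns gene_id, cultivar, week, fold")
    if (any(expression_effects$fold <= 0))
      stop("all fold multipliers must be > 0")
  }
  if (replicate_cv < 0) stop("replicate_cv must be >= 0")
  need <- c("sample_id", "cultivar", "year", "week", "replicate", "key")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    stop("samples must be a design data.frame as from sampleDesign()")
  if (anyDuplicated(samples$key))
    stop("identification keys must be unique within a pooled run")
  n_steps <- min(as.integer(n_steps), as.integer(n_starch_genes))
  structure(list(
    n_genes = as.integer(n_genes),
    n_starch_genes = as.integer(n_starch_genes),
    samples = samples,
    mean_depth = mean_depth,
    transcript_length_range = as.integer(transcript_length_range),
    dilinker_fraction = dilinker_fraction,
    no_anchor_fraction = no_anchor_fraction,
    expression_effects = expression_effects,
    replicate_cv = replicate_cv,
    gene_abundance_sdlog = gene_abundance_sdlog,
    n_steps = n_steps,
    step_names = rep_len(step_names, n_steps),
    step_ec = rep_len(step_ec, n_steps),
    multi_transcript_fraction = multi_transcript_fraction,
    key_length = as.integer(key_length),
    seed = as.integer(seed)), class = "GeneratorConfig")
}

# virtual tag of one sequence under the 3'-most-CATG rule (17 nt headroom,
# fall back upstream); NA if no qualifying site
.senseTag <- function(seq) {
  pos <- gregexpr("CATG", seq, fixed = TRUE)[[1]]
  if (pos[1] == -1L) return(NA_character_)
  ok <- pos[pos + 20L <= nchar(seq)]
  if (!length(ok)) return(NA_character_)
  p <- max(ok)
  substr(seq, p, p + 20L)
}

#' Generate a synthetic transcript collection, gene map and pathway map
#'
#' Every transcript carries at least one sense-strand CATG with 17 nt of
#' downstream sequence, placed so that the virtual tag is well defined; a
#' configurable fraction of genes gets a second isoform sharing the same 3'
#' end (hence the same tag). The first `n_starch_genes` genes are assigned
#' round-robin to `n_steps` named metabolic steps, so steps own several
#' isoforms. Tags are unique across genes by construction. Deterministic under
#' `config$seed`.
#'
#' @param config A [generatorConfig()].
#' @return List with `transcripts` ([Biostrings::DNAStringSet-class]),
#'   `geneMap` (`transcript_id`, `gene_id`), `pathwayMap` (`step_name`,
#'   `ec_number`, `gene_id`) and `tagTruth` (`transcript_id`, `gene_id`,
#'   `tag`).
#' @export
simulateTranscriptome <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("gene%04d", seq_len(n))
  lens <- sample(seq(config$transcript_length_range[1],
                     config$transcript_length_range[2]), n, replace = TRUE)
  seqs <- .randomDNA(lens)
  # force the qualifying tag site: CATG at L-20 is always the 3'-most CATG
  # with >= 17 nt downstream (any later start lacks headroom)
  substr(seqs, lens - 20L, lens - 17L) <- "CATG"
  tags <- substr(seqs, lens - 20L, lens)
  # resolve rare cross-gene tag collisions by redrawing the 17-nt suffix
  repeat {
    dup <- which(duplicated(tags))
    if (!length(dup)) break
    for (i in dup) {
      tail17 <- .randomDNA(17L)
      substr(seqs[i], lens[i] - 16L, lens[i]) <- tail17
      tags[i] <- substr(seqs[i], lens[i] - 20L, lens[i])
    }
  }
  tx_id <- paste0(genes, ".1")
  tx_seq <- seqs
  tx_gene <- genes
  iso2 <- runif(n) < config$multi_transcript_fraction
  if (any(iso2)) {
    l2 <- sample(seq(config$transcript_length_range[1],
                     config$transcript_length_range[2]), sum(iso2),
                 replace = TRUE)
    s2 <- .randomDNA(l2)
    # isoforms share the 3'-terminal 21 nt, hence the virtual tag
    substr(s2, l2 - 20L, l2) <- tags[iso2]
    tx_id <- c(tx_id, paste0(genes[iso2], ".2"))
    tx_seq <- c(tx_seq, s2)
    tx_gene <- c(tx_gene, genes[iso2])
  }
  ord <- order(tx_id)
  transcripts <- DNAStringSet(setNames(tx_seq[ord], tx_id[ord]))
  geneMap <- data.frame(transcript_id = tx_id[ord], gene_id = tx_gene[ord],
                        stringsAsFactors = FALSE)
  starch <- genes[seq_len(config$n_starch_genes)]
  pathwayMap <- data.frame(
    step_name = config$step_names[((seq_along(starch) - 1L) %% config$n_steps) + 1L],
    ec_number = config$step_ec[((seq_along(starch) - 1L) %% config$n_steps) + 1L],
    gene_id = starch, stringsAsFactors = FALSE)
  tagTruth <- data.frame(transcript_id = geneMap$transcript_id,
                         gene_id = geneMap$gene_id,
                         tag = setNames(tags, genes)[geneMap$gene_id],
                         stringsAsFactors = FALSE, row.names = NULL)
  list(transcripts = transcripts, geneMap = geneMap, pathwayMap = pathwayMap,
       tagTruth = tagTruth)
}

#' Expected productive tag counts per gene and sample
#'
#' Baseline gene abundances are log-normal across genes (sdlog
#' `gene_abundance_sdlog`), normalized to relative weights; the expected count
#' for gene g in sample s is `mean_depth * weight_g * fold(g, cultivar_s,
#' week_s) * r_gs`, with `r_gs` a per-gene, per-replicate log-normal factor of
#' mean 1 and CV `replicate_cv`. Deterministic under `config$seed + 1`.
#'
#' @param config A [generatorConfig()].
#' @return Matrix of expected counts, genes x samples.
#' @export
trueExpression <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  set.seed(config$seed + 1L)
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  w <- rlnorm(config$n_genes, 0, config$gene_abundance_sdlog)
  w <- w / sum(w)
  s <- config$samples
  fold <- matrix(1, config$n_genes, nrow(s), dimnames = list(genes, s$sample_id))
  eff <- config$expression_effects
  if (!is.null(eff) && nrow(eff)) {
    bad <- setdiff(eff$gene_id, genes)
    if (length(bad))
      stop("expression_effects references unknown gene(s): ",
           paste(bad, collapse = ", "))
    for (i in seq_len(nrow(eff))) {
      cols <- which(s$cultivar == eff$cultivar[i] & s$week == eff$week[i])
      fold[eff$gene_id[i], cols] <- fold[eff$gene_id[i], cols] * eff$fold[i]
    }
  }
  repf <- matrix(.lnormFactor(config$n_genes * nrow(s), config$replicate_cv),
                 config$n_genes, nrow(s))
  config$mean_depth * w * fold * repf
}

.pickBadKey <- function(keys, key_length) {
  repeat {
    cand <- .randomDNA(key_length)
    if (!any(startsWith(cand, keys) | startsWith(keys, cand))) return(cand)
  }
}

#' Generate pooled DeepSAGE amplicon reads with a truth table
#'
#' Emulates one pooled sequencing run. A productive read is
#' `key + CATG + 17-nt tag + linker filler`, 96 nt in total, with the tag
#' taken from the 3'-most qualifying CATG site of the gene's transcript. A
#' dilinker read (spurious linker-linker ligation) carries the sample key but
#' no tag insert and is 73 nt. Decoy reads carry an identification key absent
#' from the design and fall out at demultiplexing. Per-sample, per-gene
#' productive counts are Poisson around `expression`; the exact emitted counts
#' are returned as the truth table. Deterministic under `config$seed + 2`.
#'
#' @param config A [generatorConfig()].
#' @param transcriptome Output of [simulateTranscriptome()].
#' @param expression Optional genes x samples matrix of expected productive
#'   counts; defaults to [trueExpression()] under the same config.
#' @param fastq Optional path; when given, reads are written as
#'   Phred+33 FASTQ with constant quality `"I"`.
#' @return List with `reads` ([Biostrings::DNAStringSet-class]), `truth`
#'   (genes x samples matrix of emitted productive counts), `expected` (the
#'   expression matrix used), `dispositionTruth` (per-sample productive and
#'   dilinker read counts) and `decoys` (total decoy reads emitted).
#' @export
simulateReads <- function(config, transcriptome, expression = NULL,
                          fastq = NULL) {
  stopifnot(inherits(config, "GeneratorConfig"))
  if (is.null(expression)) expression <- trueExpression(config)
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  if (!all(rownames(expression) %in% genes))
    stop("expression references unknown gene(s): ",
         paste(setdiff(rownames(expression), genes), collapse = ", "))
  set.seed(config$seed + 2L)
  s <- config$samples
  kl <- config$key_length
  tt <- transcriptome$tagTruth
  gene_tag <- tt$tag[!duplicated(tt$gene_id)]
  names(gene_tag) <- tt$gene_id[!duplicated(tt$gene_id)]
  gene_tag <- gene_tag[rownames(expression)]

  linker <- .randomDNA(96L)
  prod_fill <- substr(linker, 1L, 96L - kl - 21L)
  repeat {
    dl_fill <- .randomDNA(73L - kl)
    if (substr(dl_fill, 1L, 4L) != "CATG") break
  }
  bad_key <- .pickBadKey(s$key, kl)
  decoy_read <- paste0(bad_key, substr(linker, 1L, 96L - kl))

  truth <- matrix(rpois(length(expression), expression),
                  nrow(expression), ncol(expression),
                  dimnames = dimnames(expression))
  dl <- config$dilinker_fraction
  na <- config$no_anchor_fraction
  p_prod <- 1 - dl - na
  n_prod <- colSums(truth)
  n_dil <- rpois(ncol(truth), n_prod / p_prod * dl)
  n_dec <- rpois(ncol(truth), n_prod / p_prod * na)

  all_reads <- character(0)
  for (j in seq_len(ncol(truth))) {
    key <- s$key[match(colnames(truth)[j], s$sample_id)]
    prod_reads <- rep(paste0(key, gene_tag, prod_fill), truth[, j])
    all_reads <- c(all_reads, prod_reads,
                   rep(paste0(key, dl_fill), n_dil[j]),
                   rep(decoy_read, n_dec[j]))
  }
  if (length(all_reads)) all_reads <- all_reads[sample(length(all_reads))]
  reads <- DNAStringSet(all_reads)
  if (length(reads)) names(reads) <- sprintf("read%07d", seq_along(reads))
  if (!is.null(fastq)) writeFastq(reads, fastq)
  list(reads = reads, truth = truth, expected = expression,
       dispositionTruth = data.frame(sample_id = colnames(truth),
                                     productive = as.integer(n_prod),
                                     dilinker = as.integer(n_dil),
                                     stringsAsFactors = FALSE),
       decoys = sum(n_dec))
}

#' Write reads as Phred+33 FASTQ with constant quality
#'
#' @param reads A [Biostrings::DNAStringSet-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  if (!length(reads)) {
    file.create(path)
    return(invisible(path))
  }
  writeXStringSet(reads, path, format = "fastq",
                  qualities = BStringSet(strrep("I", width(reads))))
  invisible(path)
}

#' Generate phosphoglucomutase assay absorbance traces
#'
#' Linear-in-time A340 series with additive Gaussian noise plus a no-sample
#' control trace. The measured slope of a sample trace is
#' `control_slope + base_rate * activity`; the truth table records the
#' dilution-corrected activity `base_rate * activity * 60 * dilution`
#' (A340/min), i.e. exactly what [computeRate()] recovers on noiseless data.
#'
#' @param activities Named numeric vector, cultivar -> relative activity
#'   (all > 0).
#' @param n_timepoints Measurements per trace (>= 3).
#' @param noise_sd SD of the additive Gaussian absorbance noise (>= 0).
#' @param seed Integer seed.
#' @param n_reps Biological replicates per cultivar.
#' @param duration_s Trace duration in seconds.
#' @param base_rate Slope (A340/s) per unit relative activity.
#' @param control_slope Background slope of the no-sample control (A340/s).
#' @param dilution Extract dilution factor applied before the assay.
#' @param activity_cv Optional log-normal CV of per-replicate activity
#'   (default 0: additive trace noise is the only noise source).
#' @param start_a340 Absorbance at time zero.
#' @return List with `traces` (`time_s`, `a340`, `sample_id`, `cultivar`,
#'   `replicate`, `dilution`, `is_control`) and `truth` (`sample_id`,
#'   `cultivar`, `replicate`, `activity` in A340/min).
#' @export
simulateAssayTraces <- function(activities, n_timepoints = 10L,
                                noise_sd = 0.001, seed = 1L, n_reps = 3L,
                                duration_s = 300, base_rate = 5e-4,
                                control_slope = 2e-4, dilution = 5,
                                activity_cv = 0, start_a340 = 0.05) {
  if (is.null(names(activities)) || any(!nzchar(names(activities))))
    stop("'activities' must be a named vector (cultivar -> activity)")
  if (any(activities <= 0)) stop("activities must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_timepoints < 3L) stop("need at least 3 timepoints per trace")
  set.seed(seed)
  times <- seq(0, duration_s, length.out = n_timepoints)
  traces <- list()
  truth <- list()
  for (cv_name in names(activities)) {
    for (r in seq_len(n_reps)) {
      act <- activities[[cv_name]] * .lnormFactor(1L, activity_cv)
      slope <- control_slope + base_rate * act
      id <- sprintf("%s_r%d", cv_name, r)
      traces[[id]] <- data.frame(
        time_s = times,
        a340 = start_a340 + slope * times + rnorm(n_timepoints, 0, noise_sd),
        sample_id = id, cultivar = cv_name, replicate = r,
        dilution = dilution, is_control = FALSE, stringsAsFactors = FALSE)
      truth[[id]] <- data.frame(sample_id = id, cultivar = cv_name,
                                replicate = r,
                                activity = base_rate * act * 60 * dilution,
                                stringsAsFactors = FALSE)
    }
  }
  traces$control <- data.frame(
    time_s = times,
    a340 = start_a340 + control_slope * times +
      rnorm(n_timepoints, 0, noise_sd),
    sample_id = "control", cultivar = NA_character_, replicate = NA_integer_,
    dilution = 1, is_control = TRUE, stringsAsFactors = FALSE)
  list(traces = do.call(rbind, c(traces, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

.DEFAULT_CAL <- data.frame(
  analyte = c("sucrose", "G1P", "G6P"),
  slope = c(80, 120, 115),
  intercept = c(2, 1, 1),
  stringsAsFactors = FALSE)

#' Generate chromatogram peak tables and calibration points
#'
#' Each (cultivar, week, replicate) is one chromatogram holding one peak per
#' analyte. Peak area follows the analyte's linear calibration,
#' `area = slope * conc + intercept`, perturbed by a log-normal loading factor
#' shared by all peaks of the chromatogram (CV `loading_cv`, emulating
#' sample-preparation and injection variation) and an independent per-peak
#' factor (CV `peak_cv`). Calibration points are emitted exactly on the line,
#' so the noiseless round trip through [fitStandardCurve()] and
#' [quantifyAnalyte()] is the identity.
#'
#' @param conc_map `data.frame(cultivar, week, analyte, conc_per_g)` of true
#'   tissue concentrations (micromol per g fresh weight, >= 0); analytes must
#'   be among sucrose, G1P, G6P.
#' @param loading_cv Shared per-chromatogram log-normal CV.
#' @param peak_cv Independent per-peak log-normal CV.
#' @param n_reps Replicate chromatograms per (cultivar, week) (default 6).
#' @param seed Integer seed.
#' @param tissue_mass Extracted tissue mass in g.
#' @param reconstitution_volume Reconstitution volume in microlitre.
#' @param extract_fraction Fraction of the extract carried through transfers.
#' @param calibration Optional `data.frame(analyte, slope, intercept)`.
#' @param cal_levels Concentrations (mM) of the emitted standards.
#' @return List with `peaks` (`sample_id`, `cultivar`, `week`, `replicate`,
#'   `analyte`, `peak_area`, `tissue_mass`), `standards` (`analyte`,
#'   `concentration`, `area`), `calibration`, `truth` (the expanded
#'   `conc_map`) and the volume/fraction parameters echoed back.
#' @export
simulateMetabolitePeaks <- function(conc_map, loading_cv = 0.15,
                                    peak_cv = 0.03, n_reps = 6L, seed = 1L,
                                    tissue_mass = 0.5,
                                    reconstitution_volume = 100,
                                    extract_fraction = 1,
                                    calibration = .DEFAULT_CAL,
                                    cal_levels = c(0.05, 0.1, 0.25, 0.5, 1, 2)) {
  need <- c("cultivar", "week", "analyte", "conc_per_g")
  if (!all(need %in% names(conc_map)))
    stop("conc_map needs columns cultivar, week, analyte, conc_per_g")
  bad <- setdiff(conc_map$analyte, calibration$analyte)
  if (length(bad))
    stop("unknown analyte(s): ", paste(bad, collapse = ", "))
  if (any(conc_map$conc_per_g < 0)) stop("concentrations must be >= 0")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  set.seed(seed)
  standards <- do.call(rbind, lapply(seq_len(nrow(calibration)), function(i) {
    data.frame(analyte = calibration$analyte[i], concentration = cal_levels,
               area = calibration$slope[i] * cal_levels +
                 calibration$intercept[i], stringsAsFactors = FALSE)
  }))
  groups <- unique(conc_map[, c("cultivar", "week")])
  peaks <- list()
  for (i in seq_len(nrow(groups))) {
    sub <- conc_map[conc_map$cultivar == groups$cultivar[i] &
                      conc_map$week == groups$week[i], ]
    for (r in seq_len(n_reps)) {
      id <- sprintf("%s_wk%d_r%d", groups$cultivar[i], groups$week[i], r)
      loading <- .lnormFactor(1L, loading_cv)
      cal <- calibration[match(sub$analyte, calibration$analyte), ]
      conc_mM <- sub$conc_per_g * tissue_mass * extract_fraction /
        (reconstitution_volume / 1000)
      peaks[[id]] <- data.frame(
        sample_id = id, cultivar = groups$cultivar[i], week = groups$week[i],
        replicate = r, analyte = sub$analyte,
        peak_area = cal$slope * conc_mM * loading *
          .lnormFactor(nrow(sub), peak_cv) + cal$intercept,
        tissue_mass = tissue_mass, stringsAsFactors = FALSE)
    }
  }
  list(peaks = do.call(rbind, c(peaks, list(make.row.names = FALSE))),
       standards = standards, calibration = calibration, truth = conc_map,
       tissue_mass = tissue_mass,
       reconstitution_volume = reconstitution_volume,
       extract_fraction = extract_fraction)
}

#' Synthetic agronomic yield table
#'
#' @param baseline `data.frame(cultivar, tuber_yield, starch_percent)`;
#'   defaults to the three study cultivars at their field values (hkg/ha, %
#'   fresh weight).
#' @param cv Log-normal CV applied to tuber yield (default 0: return the
#'   baseline unchanged).
#' @param seed Integer seed.
#' @return A yield `data.frame` suitable for [starchYieldComparison()].
#' @export
simulateYieldTable <- function(baseline = data.frame(
                                 cultivar = c("Jutlandia", "Desiree", "Kuras"),
                                 tuber_yield = c(380, 478, 596),
                                 starch_percent = c(11.7, 15.4, 20.9),
                                 stringsAsFactors = FALSE),
                               cv = 0, seed = 1L) {
  set.seed(seed)
  out <- baseline
  out$tuber_yield <- baseline$tuber_yield * .lnormFactor(nrow(baseline), cv)
  out
}

#' Run every generator and write all pipeline inputs to a directory
#'
#' Convenience wrapper producing the full set of files the pipeline consumes:
#' transcripts FASTA, gene/pathway maps, sample design, pooled FASTQ, truth
#' tables, assay traces, metabolite peaks with standards, and a yield table.
#'
#' @param config A [generatorConfig()].
#' @param dir Output directory (created if missing).
#' @param activities,conc_map Optional inputs forwarded to
#'   [simulateAssayTraces()] / [simulateMetabolitePeaks()]; sensible defaults
#'   emulating a depressed-activity cultivar are used when omitted.
#' @return Invisibly, a list of generated objects and file paths.
#' @export
simulateExperiment <- function(config, dir, activities = NULL,
                               conc_map = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- simulateTranscriptome(config)
  rd <- simulateReads(config, tx, fastq = file.path(dir, "reads.fastq"))
  writeXStringSet(tx$transcripts, file.path(dir, "transcripts.fa"))
  wtsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  wtsv(tx$geneMap, "gene_map.tsv")
  wtsv(tx$pathwayMap, "pathway_map.tsv")
  wtsv(config$samples, "design.tsv")
  truth <- data.frame(gene_id = rownames(rd$truth), rd$truth,
                      check.names = FALSE)
  wtsv(truth, "truth_counts.tsv")
  if (is.null(activities))
    activities <- c(Desiree = 1, Jutlandia = 1, Kuras = 0.46)
  assay <- simulateAssayTraces(activities, seed = config$seed + 3L)
  wtsv(assay$traces, "assay_traces.tsv")
  if (is.null(conc_map)) {
    conc_map <- expand.grid(cultivar = unique(config$samples$cultivar),
                            week = unique(config$samples$week),
                            analyte = c("sucrose", "G1P", "G6P"),
                            stringsAsFactors = FALSE)
    conc_map$conc_per_g <- ifelse(conc_map$analyte == "sucrose", 5,
                                  ifelse(conc_map$analyte == "G6P", 0.2,
                                         ifelse(conc_map$cultivar == "Kuras",
                                                0.5, 0.2)))
  }
  met <- simulateMetabolitePeaks(conc_map, seed = config$seed + 4L)
  wtsv(met$peaks, "metabolite_peaks.tsv")
  wtsv(met$standards, "standards.tsv")
  yield <- simulateYieldTable()
  wtsv(yield, "yield.tsv")
  invisible(list(transcriptome = tx, reads = rd, assay = assay,
                 metabolites = met, yield = yield, dir = dir))
}
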