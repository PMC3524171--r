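---
title: "DeepSAGE profiling of tuber starch metabolism: models and methods"
author: "StarchSAGE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DeepSAGE profiling of tuber starch metabolism: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StarchSAGE)
```

# The analysis this package implements

DeepSAGE is a deep-sequencing form of serial analysis of gene expression: a
21-bp cDNA tag, anchored at the transcript's 3'-most NlaIII (CATG) restriction
site, is sequenced and counted as a digital measure of transcript abundance.
StarchSAGE implements the full analysis path for a pooled DeepSAGE experiment
on potato tubers — three field-grown cultivars of low, medium and high yield,
sampled across the tuber-bulking season in biological triplicates — together
with the biochemistry used to corroborate the expression findings:
phosphoglucomutase (PGM) activity assays, HPLC quantification of sucrose and
hexose phosphates, and the thermodynamic equilibrium of the PGM reaction.

The pipeline stages are:

1. **Demultiplexing** (`demultiplex`): pooled amplicon reads carry a short
   sample-specific identification key at their 5' end; a read belongs to the
   sample whose key is an exact prefix. Keys must be distinct and prefix-free.
2. **Tag extraction** (`extractTag`, `countTags`): a productive read shows the
   CATG anchor immediately after its key, followed by a 17-nt tag. Reads
   without the anchor — notably spurious 73-nt linker–linker ("dilinker")
   ligation products — are rejected as `no_anchor`; reads ending inside the
   tag are `too_short`; tags with non-ACGT bases are `ambiguous_base`.
   Extraction is exact-match only: SAGE pipelines conventionally use exact
   anchors, and tag error correction is deliberately out of scope.
3. **Annotation** (`buildVirtualTags`, `annotateTags`): each transcript's
   *virtual tag* is CATG plus the 17 nt after its 3'-most CATG with at least
   17 nt of downstream sequence (falling back to the next upstream site).
   Observed tags are matched 21/21 against this index. Tags hitting several
   transcripts of one gene count once; tags hitting two or more genes are
   quarantined in an `ambiguous` row rather than fractionally split — counts
   stay integral and conservation (genes + ambiguous + unannotated = library
   total) is exact by construction.
4. **Quantification** (`combineReplicates`, `normalizeCounts`,
   `aggregateSteps`, `stepExpression`): biological replicates are pooled by
   summing **raw** counts per (cultivar, year, week) group, and the combined
   libraries are normalized to tags per 2,000,000 — this order reproduces the
   published pooling arithmetic exactly (e.g. replicate libraries of 826,191,
   1,661,343 and 973,030 tags combine to 3,460,564). Normalized values are
   kept fractional; rounding would break conservation. Gene values are then
   summed into metabolic steps, since one enzymatic step is typically encoded
   by several isoform genes. Published descriptions of such analyses use
   tags-per-million and tags-per-2,000,000 interchangeably; the scale is
   therefore a parameter, with 2,000,000 as the default because it matches
   the smallest library of this design.
5. **Statistics** (`pcaReplicates`, `ttestStep`, `deScan`): replicate quality
   control by PCA on log2(x+1), gene-centred normalized counts; differential
   expression of steps by a two-sided pooled-variance Student's t-test on
   per-replicate normalized step values, with a step called out at a timepoint
   only when the focal cultivar differs from *every* other cultivar at
   p < 0.05. The term *significant* is used only for p < 0.05, and raw
   p-values are reported (a Benjamini–Hochberg switch exists but is off by
   default, mirroring the original analysis).
6. **Biochemistry** (`computeRate`, `fitStandardCurve`, `quantifyAnalyte`,
   `g1pG6pRatio`, `equilibriumRatio`): enzyme activities from A340 traces,
   metabolite concentrations from chromatogram peaks via linear standard
   curves, per-chromatogram G1P/G6P ratios, and the equilibrium ratio
   `Keq = exp(-ΔG°/RT)`.

# The synthetic experiment

No sequencing data accompany the study, so the package generates every input
it consumes, with truth tables alongside, under `simulateTranscriptome`,
`simulateReads`, `simulateAssayTraces`, `simulateMetabolitePeaks` and
`simulateYieldTable` (all orchestrated by `simulateExperiment`).

**Amplicon model.** A productive amplicon is 96 nt: key (default 4 nt,
configurable — the original protocol does not state the key length) + CATG +
17-nt tag + a constant linker filler. A dilinker read is 73 nt and carries a
valid key but no tag insert, so it fails extraction naturally; decoy reads
carry an unknown key and fall out at demultiplexing. Base qualities are
constant ("I"): extraction is exact-match and quality-blind, so a quality
model would add nothing the pipeline could use.

**Count model.** Baseline gene abundances are log-normal across genes;
per-sample expected counts are scaled by configurable fold effects per
(gene, cultivar, week) and by a per-gene, per-replicate log-normal factor of
mean 1 and CV `replicate_cv` (default 0.2); emitted counts are Poisson.
The study states no noise model; log-normal biological variation over Poisson
sampling is the conventional model for tag counts. The generator does not
simulate sequencing errors inside tags, PCR bias, or quality decay — passing
tests therefore demonstrate the correctness of the bookkeeping and
statistics, not robustness to base-calling artifacts.

**Headline contrast.** The study conditions used throughout the tests are a
10-fold depression of the plastidial PGM step in the high-yielding cultivar
(both isoform genes at fold 0.1), biological triplicates, replicate CV 0.2,
and a mean depth of 50 productive counts per gene over a 30-gene panel with
a moderate abundance spread (sdlog 0.5, so a typical gene actually carries
on the order of 50 counts). Over 50 seeds the pipeline flags the depressed
step against both other cultivars in every run and recovers a median fold of
about 9–10.

**Biochemical truth.** Assay traces are linear in time with additive Gaussian
noise plus a no-sample control; the configured cultivar contrasts follow the
measured activity ratios of the study seasons (2.17 and 2.28). Chromatogram
peak areas carry two noise components: a log-normal *loading* factor shared
by all peaks of one chromatogram (CV 0.15, emulating sample preparation and
injection) and a small independent per-peak factor (CV 0.03). This structure
is what makes the per-chromatogram ratio estimator meaningful: forming
G1P/G6P within a chromatogram cancels the shared factor, which is why ratios
are formed *before* averaging and why their variance is far below that of
ratios of separately determined concentrations.

# Numerical and design choices

* **Anchoring rule.** The 3'-most-CATG rule with 17-nt headroom and upstream
  fallback is the NlaIII SAGE convention; the original methods do not state
  the rule explicitly, so it is adopted and documented here.
* **Pooling order.** Raw-sum-then-normalize, never the average of normalized
  replicates; the test suite asserts the pipeline uses this order.
* **Missing replicates** are treated as absent from sums, which reproduces
  every published combined total including the groups with failed libraries.
* **t-test variant.** The original analysis names a spreadsheet t-test
  without recording paired/unpaired or one/two-tailed choices; the package
  defaults to unpaired, two-sided, pooled variance — the classical default —
  and exposes `var_equal` and `alternative` switches. Degenerate zero-variance
  inputs return p = 1 (equal means) or p = 0 by convention.
* **PCA outlier rule.** A replicate is flagged when its PC1–PC2 distance to
  its group centroid exceeds 3 times the median within-group distance. The
  plain centroid (not leave-one-out) is used; a gross outlier therefore drags
  its groupmates' distances up and they may be flagged along with it — flags
  are advisory QC, not an automatic exclusion. On clean data at the study's
  sequencing depth (about 10^6 tags per library) the rule flags essentially
  nothing; on very small gene panels at shallow depth, Poisson noise on
  low-count genes makes the log-scale distances heavy-tailed and occasional
  clean replicates can exceed the threshold.
* **Rounding.** Displayed integers (replicate means, percent yield increases)
  use half-away-from-zero rounding; internal values are never rounded.
* **Equilibrium temperature.** ΔG° for G1P → G6P is −7.28 kJ/mol; the
  original discussion states no temperature, so 298.15 K is the default,
  giving Keq ≈ 18.86 — the equilibrium lies far towards G6P, which is the
  thermodynamic backdrop for the G1P-import interpretation.
* **Yield fixture.** The printed sample-statistics table shows the yield
  columns shifted by one cultivar row relative to the running text; the text
  (Jutlandia 380 hkg/ha at 11.7%, Desiree 478 at 15.4%, Kuras 596 at 20.9%)
  is taken as authoritative for the packaged yield table.
* **Problem sizes.** The test suite and the acceptance script use 30-gene
  panels at 50 counts/gene for the end-to-end power experiments (50 seeds),
  1000-gene panels at 10^6 tags for the PCA check (20 seeds), and 1000 null
  replicates for the type-I calibration; these sizes give stable rates while
  keeping a full run in the tens of seconds.

# Worked example

```{r example, eval = FALSE}
design <- sampleDesign(weeks = 12)
cfg <- generatorConfig(
  n_genes = 30, n_starch_genes = 12, samples = design, mean_depth = 1500,
  expression_effects = data.frame(gene_id = c("gene0001", "gene0007"),
                                  cultivar = "Kuras", week = 12, fold = 0.1),
  gene_abundance_sdlog = 0.5, seed = 5)

tx  <- simulateTranscriptome(cfg)
rd  <- simulateReads(cfg, tx)
tct <- countTags(rd$reads, design)
gct <- annotateTags(tct, buildVirtualTags(tx$transcripts, tx$geneMap))
st  <- stepExpression(gct, design, tx$pathwayMap)
de  <- deScan(st$replicate, st$combined, design, focal_cultivar = "Kuras")
subset(de, step_name == "plastidial phosphoglucomutase")
```

# Known limitations

* Annotation is exact-match and transcript-level: no genome-aware (intron
  spanning) mapping, no antisense tags, no 1-mismatch rescue.
* No count-model differential expression (negative binomial and friends are
  out of scope; the analysis replicated here is t-test based).
* No between-year batch correction — the two field seasons are compared side
  by side, as in the original design.
* The generator's realism ends at the noise models above; conclusions about
  real sequencing data should be drawn accordingly.
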