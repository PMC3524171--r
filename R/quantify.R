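.assayMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) assay(x, 1L) else as.matrix(x)
}

#' Normalize library counts to tags per fixed scale
#'
#' Each value becomes `value * scale / library_total`, where the library total
#' is the raw column sum; every normalized column therefore sums to `scale`.
#' The default scale of 2,000,000 tags matches the smallest library of the
#' study design; values are kept fractional so that conservation identities
#' hold exactly.
#'
#' @param x A [TagCountTable-class], [GeneCountTable-class] or numeric matrix
#'   of raw counts.
#' @param scale Target library size (default 2,000,000).
#' @return Matrix of normalized values (same dimnames as the input counts).
#' @export
normalizeCounts <- function(x, scale = 2e6) {
  m <- .assayMatrix(x)
  totals <- colSums(m)
  zero <- totals == 0
  if (any(zero))
    stop("cannot normalize zero-total library: ",
         paste(colnames(m)[zero], collapse = ", "))
  sweep(m, 2L, totals, "/") * scale
}

.groupLabels <- function(design) {
  sprintf("%s_%d_wk%d", design$cultivar, design$year, design$week)
}

#' Pool biological replicates by summing raw counts
#'
#' Replicate libraries belonging to the same (cultivar, year, week) group are
#' summed at the raw-count level before any normalization — the pooling
#' arithmetic that turns replicate libraries into combined libraries (e.g.
#' three replicates of 826,191 + 1,661,343 + 973,030 tags combine to
#' 3,460,564). Replicates missing from the data are simply absent from the
#' sum.
#'
#' @param x A [TagCountTable-class], [GeneCountTable-class] or matrix of raw
#'   counts with sample-id columns.
#' @param design Sample design with columns `sample_id`, `cultivar`, `year`,
#'   `week`; every column of `x` must appear in it.
#' @return Object of the same kind as `x` (class preserved for count tables)
#'   with one column per (cultivar, year, week) group, named
#'   `cultivar_year_wkW`.
#' @export
combineReplicates <- function(x, design) {
  m <- .assayMatrix(x)
  miss <- setdiff(colnames(m), design$sample_id)
  if (length(miss))
    stop("libraries absent from design: ", paste(miss, collapse = ", "))
  d <- design[match(colnames(m), design$sample_id), ]
  groups <- .groupLabels(d)
  ug <- unique(groups)
  comb <- vapply(ug, function(g) rowSums(m[, groups == g, drop = FALSE]),
                 numeric(nrow(m)))
  if (nrow(m) == 1L) comb <- matrix(comb, nrow = 1L,
                                    dimnames = list(rownames(m), ug))
  if (is(x, "TagCountTable")) return(TagCountTable(comb))
  if (is(x, "GeneCountTable")) return(GeneCountTable(comb))
  comb
}

#' Aggregate normalized gene values into metabolic-step expression
#'
#' A step's value is the sum of the normalized values of its member genes
#' (isoforms of the enzymes catalyzing that step). Genes not assigned to any
#' step — including the reserved `ambiguous`/`unannotated` rows — are pooled
#' into `non_pathway`, so steps plus `non_pathway` reproduce each library
#' total exactly.
#'
#' @param x Normalized gene matrix (genes x libraries) or a
#'   [GeneCountTable-class] (its first assay is used as-is).
#' @param pathwayMap `data.frame(step_name, gene_id)` (optional `ec_number`);
#'   each gene may be assigned to exactly one step.
#' @return A [StepExpressionTable-class] with rows = steps plus `non_pathway`.
#' @export
aggregateSteps <- function(x, pathwayMap) {
  m <- .assayMatrix(x)
  pm <- unique(pathwayMap[, c("step_name", "gene_id")])
  if (anyDuplicated(pm$gene_id)) {
    dup <- pm$gene_id[duplicated(pm$gene_id)][1]
    stop(sprintf("gene '%s' is mapped to more than one step", dup))
  }
  missing <- setdiff(pm$gene_id, rownames(m))
  if (length(missing))
    warning("pathway genes absent from the table contribute 0: ",
            paste(missing, collapse = ", "))
  steps <- unique(pm$step_name)
  group <- rep("non_pathway", nrow(m))
  hit <- match(rownames(m), pm$gene_id)
  group[!is.na(hit)] <- pm$step_name[hit[!is.na(hit)]]
  agg <- rowsum(m, group = group, reorder = FALSE)
  rows <- c(steps, "non_pathway")
  out <- matrix(0, nrow = length(rows), ncol = ncol(m),
                dimnames = list(rows, colnames(m)))
  out[intersect(rownames(agg), rows), ] <- agg[intersect(rownames(agg), rows), ]
  StepExpressionTable(out)
}

#' Fraction of library tags derived from pathway genes
#'
#' Computed on raw counts: the summed counts of mapped genes divided by the
#' library total, as a percent.
#'
#' @param x Raw [GeneCountTable-class] or matrix.
#' @param pathwayMap `data.frame` with a `gene_id` column.
#' @return Named numeric vector of percentages, one per library.
#' @export
starchFraction <- function(x, pathwayMap) {
  m <- .assayMatrix(x)
  mapped <- rownames(m) %in% pathwayMap$gene_id
  100 * colSums(m[mapped, , drop = FALSE]) / colSums(m)
}

#' Replicate pooling, normalization and step aggregation in one call
#'
#' Runs the quantification stage the way the study design prescribes: raw
#' replicate counts are summed per (cultivar, year, week) group, the combined
#' libraries are normalized to `scale` tags, and gene values are aggregated
#' into metabolic steps. Per-replicate normalized step values are computed
#' alongside and provide the per-step standard error (SD of replicate-level
#' normalized values / sqrt(n), with n - 1 inside the SD) attached to the
#' combined table as assay `sem`.
#'
#' @param x Raw [GeneCountTable-class] or matrix (replicate-level libraries).
#' @param design Sample design (`sample_id`, `cultivar`, `year`, `week`).
#' @param pathwayMap Step map, see [aggregateSteps()].
#' @param scale Normalization scale (default 2,000,000).
#' @return List with `combined` (a [StepExpressionTable-class] with assays
#'   `expression` and `sem`, columns = groups) and `replicate` (a
#'   [StepExpressionTable-class] of per-replicate normalized step values).
#' @export
stepExpression <- function(x, design, pathwayMap, scale = 2e6) {
  m <- .assayMatrix(x)
  comb <- .assayMatrix(combineReplicates(m, design))
  combined <- aggregateSteps(normalizeCounts(comb, scale), pathwayMap)
  repl <- aggregateSteps(normalizeCounts(m, scale), pathwayMap)
  d <- design[match(colnames(m), design$sample_id), ]
  groups <- .groupLabels(d)
  rm_ <- assay(repl, "expression")
  sem <- vapply(colnames(combined), function(g) {
    v <- rm_[, groups == g, drop = FALSE]
    n <- ncol(v)
    if (n < 2L) rep(NA_real_, nrow(v)) else apply(v, 1L, sd) / sqrt(n)
  }, numeric(nrow(rm_)))
  se <- StepExpressionTable(assay(combined, "expression"), sem = sem)
  colData(se)$n_replicates <- as.integer(table(groups)[colnames(se)])
  list(combined = se, replicate = repl)
}
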