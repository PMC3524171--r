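#' Principal-component quality control of replicate libraries
#'
#' PCA is run on log2(x + 1)-transformed, gene-centred (no scaling)
#' normalized counts. A replicate is flagged as an outlier when its distance
#' to its (cultivar, year, week) group centroid in the PC1-PC2 plane exceeds
#' three times the median within-group distance across all replicates.
#' Deterministic up to component sign.
#'
#' @param x Normalized gene matrix (genes x replicate libraries) or a
#'   [GeneCountTable-class].
#' @param design Sample design (`sample_id`, `cultivar`, `year`, `week`).
#' @return A [PCAReport-class].
#' @export
pcaReplicates <- function(x, design) {
  m <- .assayMatrix(x)
  if (ncol(m) < 2L) stop("PCA needs at least 2 libraries")
  lm_ <- log2(m + 1)
  lm_ <- lm_ - rowMeans(lm_)
  pc <- prcomp(t(lm_), center = FALSE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  ve <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  scores <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  if (ncol(scores) < 2L) scores <- cbind(scores, PC2 = 0)
  d <- design[match(colnames(m), design$sample_id), ]
  groups <- .groupLabels(d)
  cent <- rowsum(scores, groups)
  cent <- cent / as.vector(table(groups)[rownames(cent)])
  dist <- sqrt(rowSums((scores - cent[groups, , drop = FALSE])^2))
  med <- median(dist)
  flag <- dist > 3 * med
  new("PCAReport",
      scores = DataFrame(sample_id = colnames(m), group = groups,
                         PC1 = scores[, 1L], PC2 = scores[, 2L],
                         centroid_dist = dist, outlier = flag),
      varianceExplained = ve)
}

#' Two-sample Student's t-test on per-replicate step values
#'
#' Classical two-sided pooled-variance (equal variance) Student's t-test by
#' default; Welch and one-sided variants are available as switches. Degenerate
#' inputs follow the conventions: when both groups have zero variance the
#' p-value is 1 for equal means and 0 otherwise.
#'
#' @param a,b Numeric vectors of per-replicate values (each of length >= 2).
#' @param var_equal Pooled (`TRUE`, default) or Welch (`FALSE`) variance.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return The p-value.
#' @examples
#' ttestStep(c(10, 12, 14), c(20, 22, 24))
#' @export
ttestStep <- function(a, b, var_equal = TRUE, alternative = "two.sided") {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (sd(a) == 0 && sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  t.test(a, b, var.equal = var_equal, alternative = alternative)$p.value
}

#' Fold change between two combined expression values
#'
#' @param a,b Combined normalized values (numerator, denominator).
#' @return List with `fold` (`a/b`), `reciprocal` (`b/a`, the "x-fold lower"
#'   orientation) and `status`: `"ok"`, `"infinite"` (`b = 0 < a`) or
#'   `"undefined"` (both zero).
#' @examples
#' foldChange(200, 20)$fold
#' @export
foldChange <- function(a, b) {
  status <- if (a == 0 && b == 0) "undefined" else
    if (b == 0 || a == 0) "infinite" else "ok"
  list(fold = if (status == "undefined") NaN else a / b,
       reciprocal = if (status == "undefined") NaN else b / a,
       status = status)
}

#' Differential-expression scan of metabolic steps against a focal cultivar
#'
#' For every step and timepoint the focal cultivar is tested against each
#' other cultivar by [ttestStep()] on per-replicate normalized step values.
#' A step is flagged at a timepoint when *every* pairwise test gives
#' p < `alpha` — the "significantly different from the two remaining
#' cultivars" rule. Fold changes are ratios of combined normalized values
#' (focal / other), reported with their reciprocal. Raw p-values are reported;
#' Benjamini-Hochberg adjustment is available as an option but off by
#' default.
#'
#' @param replicate Replicate-level [StepExpressionTable-class] (from
#'   [stepExpression()]).
#' @param combined Combined [StepExpressionTable-class], columns
#'   `cultivar_year_wkW`.
#' @param design Sample design for the replicate columns.
#' @param focal_cultivar Cultivar to test against all others.
#' @param alpha Significance threshold (default 0.05; the term significant is
#'   reserved for p < 0.05).
#' @param var_equal,alternative Passed to [ttestStep()].
#' @param p_adjust Optional p-value adjustment method (e.g. `"BH"`); `"none"`
#'   by default.
#' @return `data.frame` with one row per step x timepoint x other cultivar:
#'   `step_name`, `year`, `week`, `cultivar_a` (focal), `cultivar_b`,
#'   `fold_change`, `fold_lower`, `p_value`, `significant` (p < alpha) and
#'   `step_flagged` (all pairwise tests of that step x timepoint
#'   significant). Missing or single-replicate groups are skipped with a
#'   warning.
#' @export
deScan <- function(replicate, combined, design, focal_cultivar, alpha = 0.05,
                   var_equal = TRUE, alternative = "two.sided",
                   p_adjust = "none") {
  rm_ <- if (is(replicate, "SummarizedExperiment"))
    assay(replicate, "expression") else as.matrix(replicate)
  cm <- if (is(combined, "SummarizedExperiment"))
    assay(combined, "expression") else as.matrix(combined)
  d <- design[match(colnames(rm_), design$sample_id), ]
  steps <- setdiff(rownames(rm_), "non_pathway")
  others <- setdiff(unique(d$cultivar), focal_cultivar)
  if (!focal_cultivar %in% d$cultivar)
    stop(sprintf("focal cultivar '%s' not in design", focal_cultivar))
  res <- list()
  for (yw in unique(paste(d$year, d$week))) {
    year <- as.integer(strsplit(yw, " ")[[1]][1])
    week <- as.integer(strsplit(yw, " ")[[1]][2])
    fa <- d$cultivar == focal_cultivar & d$year == year & d$week == week
    ga <- sprintf("%s_%d_wk%d", focal_cultivar, year, week)
    for (step in steps) {
      for (cb in others) {
        fb <- d$cultivar == cb & d$year == year & d$week == week
        gb <- sprintf("%s_%d_wk%d", cb, year, week)
        if (sum(fa) < 2L || sum(fb) < 2L) {
          warning(sprintf("skipping %s vs %s (%d wk%d): missing group",
                          focal_cultivar, cb, year, week))
          next
        }
        fc <- foldChange(cm[step, ga], cm[step, gb])
        res[[length(res) + 1L]] <- data.frame(
          step_name = step, year = year, week = week,
          cultivar_a = focal_cultivar, cultivar_b = cb,
          fold_change = fc$fold, fold_lower = fc$reciprocal,
          p_value = ttestStep(rm_[step, fa], rm_[step, fb],
                              var_equal = var_equal,
                              alternative = alternative),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(step_name = character(0), year = integer(0),
                      week = integer(0), cultivar_a = character(0),
                      cultivar_b = character(0), fold_change = numeric(0),
                      fold_lower = numeric(0), p_value = numeric(0),
                      significant = logical(0), step_flagged = logical(0)))
  out <- do.call(rbind, res)
  if (!identical(p_adjust, "none"))
    out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_value < alpha
  key <- paste(out$step_name, out$year, out$week)
  flagged <- tapply(out$significant, key, all)
  out$step_flagged <- as.logical(flagged[key])
  out
}
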