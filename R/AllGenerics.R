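#' @importFrom BiocGenerics counts
NULL

#' Extract the count matrix
#'
#' @param object A [TagCountTable-class] or [GeneCountTable-class].
#' @param ... Ignored.
#' @return Numeric matrix of raw counts.
#' @aliases counts,TagCountTable-method counts,GeneCountTable-method
#' @export
setMethod("counts", "TagCountTable", function(object, ...) assay(object, 1L))

#' @export
setMethod("counts", "GeneCountTable", function(object, ...) assay(object, 1L))

#' Read-disposition bookkeeping of an extraction run
#'
#' @param x A [TagCountTable-class] produced by [countTags()].
#' @return A `data.frame` with one row per sample (plus one `<unmatched>` row)
#'   and columns `productive`, `no_anchor`, `too_short`, `ambiguous_base`;
#'   `NULL` when the table was built without bookkeeping.
#' @export
dispositions <- function(x) {
  stopifnot(is(x, "SummarizedExperiment"))
  metadata(x)$dispositions
}

#' Accessors for VirtualTagIndex
#'
#' `tagIndex()` returns the tag-to-transcript/gene table; `untaggable()` the
#' transcripts with no qualifying CATG site.
#'
#' @param x A [VirtualTagIndex-class].
#' @return A [S4Vectors::DataFrame-class] (`tagIndex`) or character vector
#'   (`untaggable`).
#' @export
tagIndex <- function(x) {
  stopifnot(is(x, "VirtualTagIndex"))
  x@tags
}

#' @rdname tagIndex
#' @export
untaggable <- function(x) {
  stopifnot(is(x, "VirtualTagIndex"))
  x@untaggable
}

#' Accessors for PCAReport
#'
#' @param x A [PCAReport-class].
#' @return `pcaScores()`: per-replicate scores, centroid distances and outlier
#'   flags; `outliers()`: sample ids flagged as outliers;
#'   `varianceExplained()`: per-component variance proportions.
#' @export
pcaScores <- function(x) {
  stopifnot(is(x, "PCAReport"))
  x@scores
}

#' @rdname pcaScores
#' @export
outliers <- function(x) {
  stopifnot(is(x, "PCAReport"))
  as.character(x@scores$sample_id[x@scores$outlier])
}

#' @rdname pcaScores
#' @export
varianceExplained <- function(x) {
  stopifnot(is(x, "PCAReport"))
  x@varianceExplained
}

#' @describeIn TagCountTable-class Compact display.
#' @param object A `TagCountTable`.
#' @export
setMethod("show", "TagCountTable", function(object) {
  cat(sprintf("TagCountTable: %d tags x %d libraries\n",
              nrow(object), ncol(object)))
  if (ncol(object)) {
    tot <- colSums(assay(object, 1L))
    cat(sprintf("  library totals: %s\n",
                paste(sprintf("%s=%s", colnames(object),
                              format(tot, big.mark = ",", trim = TRUE)),
                      collapse = " ")))
  }
  d <- dispositions(object)
  if (!is.null(d))
    cat(sprintf("  dispositions: %d productive / %d rejected / %d unmatched\n",
                sum(d$productive),
                sum(d$no_anchor + d$too_short + d$ambiguous_base),
                sum(d$unmatched)))
  invisible(NULL)
})

#' @describeIn GeneCountTable-class Compact display.
#' @param object A `GeneCountTable`.
#' @export
setMethod("show", "GeneCountTable", function(object) {
  nres <- sum(rownames(object) %in% c("ambiguous", "unannotated"))
  cat(sprintf("GeneCountTable: %d genes (+%d reserved rows) x %d libraries\n",
              nrow(object) - nres, nres, ncol(object)))
  invisible(NULL)
})

#' @describeIn StepExpressionTable-class Compact display.
#' @param object A `StepExpressionTable`.
#' @export
setMethod("show", "StepExpressionTable", function(object) {
  cat(sprintf("StepExpressionTable: %d steps x %d libraries (assays: %s)\n",
              nrow(object), ncol(object),
              paste(assayNames(object), collapse = ", ")))
  invisible(NULL)
})

#' @describeIn VirtualTagIndex-class Compact display.
#' @param object A `VirtualTagIndex`.
#' @export
setMethod("show", "VirtualTagIndex", function(object) {
  cat(sprintf(
    "VirtualTagIndex: %d tags over %d transcripts / %d genes (%d untaggable)\n",
    length(unique(object@tags$tag)), nrow(object@tags),
    length(unique(object@tags$gene_id)), length(object@untaggable)))
  invisible(NULL)
})

#' @describeIn StandardCurve-class Compact display.
#' @param object A `StandardCurve`.
#' @export
setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve[%s]: area = %.6g * conc + %.6g (r^2 = %.4f, n = %d)\n",
              object@analyte, object@slope, object@intercept,
              object@r_squared, object@n))
  invisible(NULL)
})

#' @describeIn PCAReport-class Compact display.
#' @param object A `PCAReport`.
#' @export
setMethod("show", "PCAReport", function(object) {
  out <- outliers(object)
  cat(sprintf("PCAReport: %d replicates, PC1 %.1f%% / PC2 %.1f%% variance, %s\n",
              nrow(object@scores),
              100 * object@varianceExplained[1L],
              100 * object@varianceExplained[2L],
              if (length(out)) paste("outliers:", paste(out, collapse = ", "))
              else "no outliers"))
  invisible(NULL)
})
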