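#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames colData colData<- rowData rowData<-
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
NULL

.checkCountAssay <- function(object) {
  msg <- NULL
  if (length(assays(object)) < 1L)
    return("object must carry at least one assay")
  a <- assay(object, 1L)
  if (any(is.na(a)))
    msg <- c(msg, "counts must not contain NA")
  else if (any(a < 0))
    msg <- c(msg, "counts must be non-negative")
  if (identical(assayNames(object)[1L], "counts") && !any(is.na(a)) &&
      any(abs(a - round(a)) > 1e-8))
    msg <- c(msg, "assay 'counts' must hold whole numbers")
  msg
}

#' TagCountTable: tags-by-library count matrix
#'
#' The central object of the DeepSAGE pipeline: one row per distinct 21-nt
#' CATG-anchored tag, one column per sample library, integer counts.
#' Read-disposition bookkeeping from the extraction run (productive reads,
#' anchor/length/base rejections, unmatched keys) lives in
#' `metadata(x)$dispositions` and is available through [dispositions()].
#'
#' Build one with [countTags()] or the `TagCountTable()` constructor.
#'
#' @seealso [countTags()], [annotateTags()], [normalizeCounts()]
#' @export
setClass("TagCountTable", contains = "SummarizedExperiment")

setValidity("TagCountTable", function(object) {
  msg <- .checkCountAssay(object)
  tags <- rownames(object)
  if (length(tags)) {
    if (any(nchar(tags) != 21L))
      msg <- c(msg, "tag rownames must be 21 nt")
    if (any(substr(tags, 1L, 4L) != "CATG"))
      msg <- c(msg, "every tag must begin with the CATG anchor")
    if (any(grepl("[^ACGT]", tags)))
      msg <- c(msg, "tags must contain only A/C/G/T")
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname TagCountTable-class
#' @param counts Integer matrix, tags x libraries; rownames are 21-nt tags
#'   starting with `CATG`, colnames are sample ids.
#' @param dispositions Optional per-sample read-disposition `data.frame`
#'   (see [countTags()]).
#' @return A `TagCountTable`.
#' @export
TagCountTable <- function(counts, dispositions = NULL) {
  counts <- as.matrix(counts)
  mode(counts) <- "numeric"
  se <- SummarizedExperiment(assays = SimpleList(counts = counts))
  if (!is.null(dispositions)) metadata(se)$dispositions <- dispositions
  new("TagCountTable", se)
}

#' GeneCountTable: gene-by-library counts after tag annotation
#'
#' Rows are gene ids plus two reserved rows, `"ambiguous"` (tags matching two
#' or more distinct genes) and `"unannotated"` (tags absent from the virtual
#' tag index). Column sums equal the column sums of the annotated
#' [TagCountTable-class] — annotation conserves counts. `rowData(x)$feature_type`
#' distinguishes `"gene"` from `"reserved"` rows.
#'
#' @seealso [annotateTags()], [aggregateSteps()]
#' @export
setClass("GeneCountTable", contains = "SummarizedExperiment")

setValidity("GeneCountTable", function(object) {
  msg <- .checkCountAssay(object)
  if (!all(c("ambiguous", "unannotated") %in% rownames(object)))
    msg <- c(msg, "reserved rows 'ambiguous' and 'unannotated' must be present")
  if (is.null(msg)) TRUE else msg
})

#' @rdname GeneCountTable-class
#' @param counts Numeric matrix including the reserved rows `ambiguous` and
#'   `unannotated`.
#' @return A `GeneCountTable`.
#' @export
GeneCountTable <- function(counts) {
  counts <- as.matrix(counts)
  mode(counts) <- "numeric"
  se <- SummarizedExperiment(assays = SimpleList(counts = counts))
  rowData(se)$feature_type <-
    ifelse(rownames(se) %in% c("ambiguous", "unannotated"), "reserved", "gene")
  new("GeneCountTable", se)
}

#' StepExpressionTable: metabolic-step expression values
#'
#' Rows are named metabolic steps (plus `non_pathway`, the pooled mass of all
#' features outside the pathway map); columns are libraries, either combined
#' (pooled biological replicates) or replicate level. The first assay,
#' `expression`, holds normalized values (tags per 2,000,000 by default,
#' fractional); combined tables built by [stepExpression()] carry a second
#' assay `sem` with the standard error across replicate-level normalized
#' values.
#'
#' @seealso [aggregateSteps()], [stepExpression()], [deScan()]
#' @export
setClass("StepExpressionTable", contains = "SummarizedExperiment")

setValidity("StepExpressionTable", function(object) {
  msg <- NULL
  if (!"expression" %in% assayNames(object))
    msg <- c(msg, "assay 'expression' is required")
  else if (any(assay(object, "expression") < 0, na.rm = TRUE))
    msg <- c(msg, "expression values must be non-negative")
  if ("sem" %in% assayNames(object) &&
      any(assay(object, "sem") < 0, na.rm = TRUE))
    msg <- c(msg, "SEM values must be non-negative")
  if (is.null(msg)) TRUE else msg
})

StepExpressionTable <- function(expression, sem = NULL) {
  assays <- SimpleList(expression = as.matrix(expression))
  if (!is.null(sem)) assays$sem <- as.matrix(sem)
  new("StepExpressionTable", SummarizedExperiment(assays = assays))
}

#' VirtualTagIndex: transcript-derived tag-to-gene map
#'
#' For every transcript the index records the virtual tag — `CATG` plus the 17
#' nt that follow the 3'-most CATG site with at least 17 nt of downstream
#' sequence (falling back to the next site upstream when the 3'-most CATG sits
#' too close to the transcript end). Transcripts with no qualifying site are
#' listed in `untaggable(x)`.
#'
#' @slot tags A [S4Vectors::DataFrame-class] with columns `tag`,
#'   `transcript_id`, `gene_id`.
#' @slot untaggable Character vector of transcript ids with no qualifying
#'   CATG site.
#' @seealso [buildVirtualTags()], [annotateTags()]
#' @export
setClass("VirtualTagIndex",
         slots = c(tags = "DataFrame", untaggable = "character"))

setValidity("VirtualTagIndex", function(object) {
  msg <- NULL
  tg <- object@tags
  need <- c("tag", "transcript_id", "gene_id")
  if (!all(need %in% colnames(tg)))
    return(sprintf("index needs columns: %s", paste(need, collapse = ", ")))
  if (nrow(tg)) {
    if (any(nchar(tg$tag) != 21L))
      msg <- c(msg, "virtual tags must be 21 nt")
    if (any(substr(tg$tag, 1L, 4L) != "CATG"))
      msg <- c(msg, "virtual tags must begin with CATG")
  }
  if (is.null(msg)) TRUE else msg
})

#' StandardCurve: linear calibration for one analyte
#'
#' Ordinary least-squares line `area = slope * concentration + intercept`
#' fitted from reference standards, used to convert chromatogram peak areas
#' into concentrations.
#'
#' @slot analyte Analyte label (`"sucrose"`, `"G1P"`, `"G6P"`, ...).
#' @slot slope,intercept Fitted line coefficients (area per concentration
#'   unit; area).
#' @slot r_squared Coefficient of determination of the fit.
#' @slot n Number of calibration points used.
#' @seealso [fitStandardCurve()], [quantifyAnalyte()]
#' @export
setClass("StandardCurve",
         slots = c(analyte = "character", slope = "numeric",
                   intercept = "numeric", r_squared = "numeric",
                   n = "integer"))

setValidity("StandardCurve", function(object) {
  msg <- NULL
  if (length(object@slope) != 1L || object@slope == 0)
    msg <- c(msg, "slope must be a single non-zero number")
  if (object@r_squared < 0 || object@r_squared > 1)
    msg <- c(msg, "r_squared must lie in [0, 1]")
  if (object@n < 2L)
    msg <- c(msg, "a curve needs at least 2 calibration points")
  if (is.null(msg)) TRUE else msg
})

#' PCAReport: replicate quality-control summary
#'
#' Scores of every replicate library on the first two principal components of
#' the log2(x+1), gene-centred normalized count matrix, with each replicate's
#' distance to its (cultivar, year, week) group centroid and an outlier flag.
#'
#' @slot scores A [S4Vectors::DataFrame-class] with columns `sample_id`,
#'   `group`, `PC1`, `PC2`, `centroid_dist`, `outlier`.
#' @slot varianceExplained Proportion of variance carried by each component,
#'   non-increasing, in `[0, 1]`.
#' @seealso [pcaReplicates()]
#' @export
setClass("PCAReport",
         slots = c(scores = "DataFrame", varianceExplained = "numeric"))

setValidity("PCAReport", function(object) {
  ve <- object@varianceExplained
  msg <- NULL
  if (length(ve) && (any(ve < -1e-12) || any(ve > 1 + 1e-12)))
    msg <- c(msg, "varianceExplained must lie in [0, 1]")
  if (length(ve) > 1L && any(diff(ve) > 1e-12))
    msg <- c(msg, "varianceExplained must be non-increasing")
  if (is.null(msg)) TRUE else msg
})
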