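#' Build a virtual-tag index from a transcript collection
#'
#' For each sense-strand transcript the virtual tag is `CATG` plus the 17 nt
#' following the 3'-most CATG occurrence — the NlaIII SAGE convention.
#' When the 3'-most site has fewer than 17 nt downstream, the next CATG
#' upstream is used; transcripts with no qualifying site are recorded as
#' untaggable. Empty sequences are skipped with a warning. Rebuilding from the
#' same collection yields an identical index.
#'
#' @param transcripts A named [Biostrings::DNAStringSet-class] or path to a
#'   FASTA file.
#' @param geneMap `data.frame(transcript_id, gene_id)` resolving transcripts
#'   to genes (e.g. across merged reference collections); transcripts missing
#'   from the map keep their own id as gene id.
#' @return A [VirtualTagIndex-class].
#' @examples
#' tx <- Biostrings::DNAStringSet(c(t1 = paste0("AAACATG", strrep("G", 17))))
#' buildVirtualTags(tx)
#' @export
buildVirtualTags <- function(transcripts, geneMap = NULL) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts))
    transcripts <- readDNAStringSet(transcripts)
  if (!is(transcripts, "DNAStringSet"))
    transcripts <- DNAStringSet(transcripts)
  if (!length(transcripts)) stop("transcript collection is empty")
  if (is.null(names(transcripts)))
    names(transcripts) <- sprintf("tx%05d", seq_along(transcripts))
  empty <- width(transcripts) == 0L
  if (any(empty)) {
    warning(sprintf("skipping %d empty transcript sequence(s)", sum(empty)))
    transcripts <- transcripts[!empty]
  }
  seqs <- toupper(as.character(transcripts))
  tags <- vapply(seqs, .senseTag, character(1), USE.NAMES = FALSE)
  tx_id <- names(transcripts)
  gene_id <- if (is.null(geneMap)) tx_id else {
    m <- match(tx_id, geneMap$transcript_id)
    ifelse(is.na(m), tx_id, geneMap$gene_id[m])
  }
  has <- !is.na(tags)
  new("VirtualTagIndex",
      tags = DataFrame(tag = tags[has], transcript_id = tx_id[has],
                       gene_id = gene_id[has]),
      untaggable = tx_id[!has])
}

#' Annotate observed tags to genes
#'
#' Each observed tag is looked up in the virtual-tag index by exact 21/21
#' match. A tag matching transcripts of exactly one gene contributes its
#' counts to that gene (once, regardless of how many isoforms share the tag);
#' a tag matching two or more distinct genes is quarantined in the reserved
#' `ambiguous` row; a tag absent from the index goes to `unannotated`.
#' Counts are conserved per library: gene rows plus the two reserved rows sum
#' to the tag-table column totals.
#'
#' @param tags A [TagCountTable-class].
#' @param index A [VirtualTagIndex-class] built from the transcript universe
#'   underlying the reads.
#' @return A [GeneCountTable-class] whose rows are all genes of the index
#'   (genes without observed tags get zero counts) plus `ambiguous` and
#'   `unannotated`.
#' @export
annotateTags <- function(tags, index) {
  stopifnot(is(tags, "TagCountTable"), is(index, "VirtualTagIndex"))
  itab <- index@tags
  genes <- sort(unique(itab$gene_id))
  obs <- rownames(tags)
  cmat <- counts(tags)
  # genes hit by each observed tag (unique within tag)
  gene_of <- split(itab$gene_id, itab$tag)
  hit <- gene_of[obs]
  n_hit <- vapply(hit, function(g) length(unique(g)), integer(1))
  n_hit[is.na(names(hit)) | vapply(hit, is.null, logical(1))] <- 0L
  dest <- character(length(obs))
  dest[n_hit == 0L] <- "unannotated"
  dest[n_hit >= 2L] <- "ambiguous"
  uniq <- n_hit == 1L
  dest[uniq] <- vapply(hit[uniq], function(g) unique(g)[1L], character(1))
  rows <- c(genes, "ambiguous", "unannotated")
  out <- matrix(0, nrow = length(rows), ncol = ncol(cmat),
                dimnames = list(rows, colnames(cmat)))
  if (length(obs)) {
    agg <- rowsum(cmat, group = dest, reorder = FALSE)
    out[rownames(agg), ] <- agg
  }
  gct <- GeneCountTable(out)
  metadata(gct)$dispositions <- dispositions(tags)
  gct
}

#' Read and write a serialized virtual-tag index
#'
#' The index round-trips through a three-column TSV (`tag`, `transcript_id`,
#' `gene_id`); untaggable transcripts are stored with an empty tag field.
#'
#' @param index A [VirtualTagIndex-class].
#' @param path TSV file path.
#' @return `writeTagIndex`: `path` invisibly; `readTagIndex`: the index.
#' @export
writeTagIndex <- function(index, path) {
  df <- as.data.frame(index@tags)
  if (length(index@untaggable))
    df <- rbind(df, data.frame(tag = "", transcript_id = index@untaggable,
                               gene_id = NA_character_))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTagIndex
#' @export
readTagIndex <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(tag = "character"))
  un <- !nzchar(df$tag) | is.na(df$tag)
  new("VirtualTagIndex",
      tags = DataFrame(tag = df$tag[!un], transcript_id = df$transcript_id[!un],
                       gene_id = df$gene_id[!un]),
      untaggable = df$transcript_id[un])
}
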