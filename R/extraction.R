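#' Identification-key table for demultiplexing
#'
#' Keys must be mutually distinct and prefix-free (no key may be a prefix of
#' another), otherwise demultiplexing would be ambiguous.
#'
#' @param key Character vector of key oligonucleotides.
#' @param sample_id Character vector of sample labels, same length.
#' @return Validated `data.frame(key, sample_id)`.
#' @examples
#' keyTable(c("ACGT", "TTAA"), c("S1", "S2"))
#' @export
keyTable <- function(key, sample_id) {
  key <- toupper(as.character(key))
  sample_id <- as.character(sample_id)
  if (length(key) != length(sample_id) || !length(key))
    stop("'key' and 'sample_id' must be non-empty and of equal length")
  if (anyDuplicated(key)) stop("keys must be mutually distinct")
  if (anyDuplicated(sample_id)) stop("sample ids must be distinct")
  if (any(grepl("[^ACGT]", key))) stop("keys must contain only A/C/G/T")
  for (i in seq_along(key)) {
    pre <- startsWith(key[-i], key[i])
    if (any(pre))
      stop(sprintf("keys are not prefix-free: '%s' is a prefix of '%s'",
                   key[i], key[-i][pre][1]))
  }
  data.frame(key = key, sample_id = sample_id, stringsAsFactors = FALSE)
}

.asReadChar <- function(reads) {
  if (is(reads, "XStringSet")) reads <- as.character(reads)
  toupper(unname(as.character(reads)))
}

#' Assign reads to samples by exact key prefix
#'
#' A read belongs to the sample whose identification key is an exact prefix of
#' the read sequence; reads matching no key (including empty reads) are
#' unmatched and reported as `NA`.
#'
#' @param reads Character vector or [Biostrings::DNAStringSet-class].
#' @param keys A [keyTable()].
#' @return Character vector of sample ids, `NA` for unmatched reads.
#' @export
demultiplex <- function(reads, keys) {
  reads <- .asReadChar(reads)
  out <- rep(NA_character_, length(reads))
  # longest keys first so shorter keys cannot shadow (prefix-freeness makes
  # at most one key match anyway)
  for (len in sort(unique(nchar(keys$key)), decreasing = TRUE)) {
    k <- keys[nchar(keys$key) == len, ]
    idx <- is.na(out)
    hit <- match(substr(reads[idx], 1L, len), k$key)
    out[idx][!is.na(hit)] <- k$sample_id[hit[!is.na(hit)]]
  }
  out
}

#' Extract the CATG-anchored 21-nt tag from demultiplexed reads
#'
#' A read yields a tag when the 4 nt immediately after its identification key
#' are the `CATG` anchor and at least 17 nt follow; the tag is the anchor plus
#' those 17 nt, uppercase. Otherwise the read is rejected with a reason:
#' `no_anchor` (anchor absent — dilinker reads end up here), `too_short`
#' (read ends before the anchor or within the 17-nt tail), or
#' `ambiguous_base` (non-ACGT base inside the tag).
#'
#' @param reads Character vector or [Biostrings::DNAStringSet-class] of
#'   demultiplexed reads (key still attached).
#' @param key_length Length of the identification key preceding the anchor.
#' @return `data.frame(tag, status)`: `tag` is the 21-nt tag or `NA`;
#'   `status` is `"ok"` or the rejection reason.
#' @examples
#' extractTag(paste0("ACGT", "CATG", strrep("A", 17), "GGG"), key_length = 4)
#' @export
extractTag <- function(reads, key_length) {
  reads <- .asReadChar(reads)
  n <- nchar(reads)
  status <- rep("ok", length(reads))
  tag <- rep(NA_character_, length(reads))
  anchor <- substr(reads, key_length + 1L, key_length + 4L)
  status[n < key_length + 4L] <- "too_short"
  status[status == "ok" & anchor != "CATG"] <- "no_anchor"
  status[status == "ok" & n < key_length + 21L] <- "too_short"
  ok <- status == "ok"
  tag[ok] <- substr(reads[ok], key_length + 1L, key_length + 21L)
  bad <- ok & grepl("[^ACGT]", tag)
  status[bad] <- "ambiguous_base"
  tag[!ok | bad] <- NA_character_
  data.frame(tag = tag, status = status, stringsAsFactors = FALSE)
}

.checkFastqFile <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(character(0))
  if (length(lines) %% 4L != 0L)
    stop(sprintf("malformed FASTQ '%s': record %d is truncated",
                 path, length(lines) %/% 4L + 1L))
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(quals))
  if (length(bad))
    stop(sprintf("malformed FASTQ '%s': record %d is invalid", path, bad[1]))
  invisible(lines)
}

#' Count CATG-anchored tags per sample from a pooled FASTQ run
#'
#' Streams over the reads in chunks: each read is demultiplexed by exact key
#' prefix, its tag extracted under the CATG-anchor rule, and counted into the
#' (tag, sample) cell. Bookkeeping is complete: every read is either
#' productive, rejected (`no_anchor` / `too_short` / `ambiguous_base`) or
#' unmatched, and these dispositions sum to the number of reads processed.
#'
#' @param reads Character vector or [Biostrings::DNAStringSet-class] of reads,
#'   or `NULL` when `fastq` is given.
#' @param keys A [keyTable()], or a sample design with `key` and `sample_id`
#'   columns.
#' @param fastq Optional path to a FASTQ file (optionally gzipped); the file
#'   is structurally validated first and a malformed record is reported by
#'   index.
#' @param chunk_size Reads per processing chunk.
#' @return A [TagCountTable-class] with one column per sample in `keys` (zero
#'   columns counted for samples without productive reads) and per-sample
#'   dispositions in `metadata(x)$dispositions` (unmatched reads are carried
#'   on a `<unmatched>` row).
#' @examples
#' kt <- keyTable(c("ACGT", "TGCA"), c("S1", "S2"))
#' rds <- c(paste0("ACGT", "CATG", strrep("A", 17)), "TTTTTTTT")
#' countTags(rds, kt)
#' @export
countTags <- function(reads = NULL, keys, fastq = NULL, chunk_size = 100000L) {
  keys <- keyTable(keys$key, keys$sample_id)
  if (!is.null(fastq)) {
    .checkFastqFile(fastq)
    reads <- readDNAStringSet(fastq, format = "fastq")
  }
  reads <- .asReadChar(reads)
  samples <- keys$sample_id
  disp <- matrix(0L, nrow = length(samples) + 1L, ncol = 4L,
                 dimnames = list(c(samples, "<unmatched>"),
                                 c("productive", "no_anchor", "too_short",
                                   "ambiguous_base")))
  acc_tag <- character(0)
  acc_sample <- character(0)
  acc_n <- integer(0)
  key_len <- setNames(nchar(keys$key), keys$sample_id)
  for (start in if (length(reads)) seq(1L, length(reads), by = chunk_size)
       else integer(0)) {
    chunk <- reads[seq(start, min(start + chunk_size - 1L, length(reads)))]
    sid <- demultiplex(chunk, keys)
    unmatched <- is.na(sid)
    disp["<unmatched>", "no_anchor"] <-
      disp["<unmatched>", "no_anchor"] + sum(unmatched)
    if (any(!unmatched)) {
      # keys may differ in length per sample: extract per key length
      sid_m <- sid[!unmatched]
      reads_m <- chunk[!unmatched]
      ex <- data.frame(tag = NA_character_, status = "",
                       stringsAsFactors = FALSE)[rep(1L, length(reads_m)), ]
      for (len in unique(key_len)) {
        sel <- key_len[sid_m] == len
        if (any(sel)) ex[sel, ] <- extractTag(reads_m[sel], len)
      }
      for (st in c("no_anchor", "too_short", "ambiguous_base")) {
        t <- table(sid_m[ex$status == st])
        disp[names(t), st] <- disp[names(t), st] + as.integer(t)
      }
      good <- ex$status == "ok"
      t <- table(sid_m[good])
      disp[names(t), "productive"] <- disp[names(t), "productive"] +
        as.integer(t)
      if (any(good)) {
        agg <- stats::aggregate(list(n = rep(1L, sum(good))),
                                by = list(tag = ex$tag[good],
                                          sample = sid_m[good]), FUN = sum)
        acc_tag <- c(acc_tag, agg$tag)
        acc_sample <- c(acc_sample, agg$sample)
        acc_n <- c(acc_n, agg$n)
      }
    }
  }
  tags <- sort(unique(acc_tag))
  counts <- matrix(0, nrow = length(tags), ncol = length(samples),
                   dimnames = list(tags, samples))
  if (length(acc_tag)) {
    idx <- cbind(match(acc_tag, tags), match(acc_sample, samples))
    for (i in seq_along(acc_n))
      counts[idx[i, 1L], idx[i, 2L]] <- counts[idx[i, 1L], idx[i, 2L]] +
        acc_n[i]
  }
  dispdf <- data.frame(sample_id = rownames(disp), disp,
                       unmatched = c(rep(0L, length(samples)),
                                     disp["<unmatched>", "no_anchor"]),
                       row.names = NULL, stringsAsFactors = FALSE)
  dispdf$no_anchor[dispdf$sample_id == "<unmatched>"] <- 0L
  tct <- TagCountTable(counts, dispositions = dispdf)
  metadata(tct)$reads_processed <- length(reads)
  tct
}
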