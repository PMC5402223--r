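#' Positional similarity between two reads
#'
#' Fraction of matching bases when the reads are laid side by side from
#' base 1, divided by the length of the longer read. No indel alignment is
#' attempted: reads from a fixed-cycle sequencing run are already
#' positionally registered, so positional identity is the natural metric
#' here. Symmetric and in \[0, 1\]; a length difference counts against the
#' overhang (two reads of lengths 100 and 90 with identical first 90 bases
#' score 90/100 = 0.90).
#'
#' @param a,b character strings or \code{DNAString}-like sequences.
#' @return similarity fraction.
#' @examples
#' readSimilarity(strrep("A", 100), paste0(strrep("A", 91), strrep("C", 9)))
#' @export
readSimilarity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b))
    stop("reads must be non-empty", call. = FALSE)
  ra <- charToRaw(a); rb <- charToRaw(b)
  k <- min(length(ra), length(rb))
  sum(ra[seq_len(k)] == rb[seq_len(k)]) / max(length(ra), length(rb))
}

#' PCR-duplicate predicate
#'
#' Two reads are PCR duplicates when their first \code{prefixLen} bases are
#' identical and the whole-read [readSimilarity()] is strictly greater than
#' \code{simThreshold}. Both inequalities are taken as printed: a pair at
#' exactly the threshold (e.g. 90 matching bases in 100) is \emph{not} a
#' duplicate.
#'
#' @param a,b reads (character or \code{DNAString}-like).
#' @param prefixLen prefix length in bases (default 10).
#' @param simThreshold similarity threshold, strict (default 0.90).
#' @return logical.
#' @export
isPCRDuplicate <- function(a, b, prefixLen = 10L, simThreshold = 0.90) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) <= prefixLen || nchar(b) <= prefixLen)
    stop("reads must be longer than prefixLen", call. = FALSE)
  if (substr(a, 1L, prefixLen) != substr(b, 1L, prefixLen))
    return(FALSE)
  readSimilarity(a, b) > simThreshold
}

#' Remove PCR duplicates from a set of reads
#'
#' Reads are bucketed by their \code{prefixLen}-base prefix and each bucket
#' is scanned in input order: a read is removed iff [isPCRDuplicate()] holds
#' against some already-kept read of its bucket, so the first occurrence of
#' each duplicate cluster is always retained. Output preserves input order.
#' The procedure is idempotent and, because buckets partition the reads,
#' agrees with the brute-force all-pairs keep-first scan.
#'
#' @param reads named \code{DNAStringSet} (or named character vector);
#'   qualities in \code{mcols()$qualities} are carried through.
#' @param prefixLen,simThreshold see [isPCRDuplicate()].
#' @return a [DedupResult-class].
#' @export
dedupReads <- function(reads, prefixLen = 10L, simThreshold = 0.90) {
  seqs <- as.character(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(seqs))
  if (length(seqs) && any(nchar(seqs) <= prefixLen))
    stop("all reads must be longer than prefixLen", call. = FALSE)

  keep <- logical(length(seqs))
  buckets <- split(seq_along(seqs), substr(seqs, 1L, prefixLen))
  rm_pairs_kept <- character(0); rm_pairs_rm <- character(0)
  for (idx in buckets) {
    kept_here <- integer(0)
    for (i in idx) {  # idx is ascending: input order within bucket
      # same bucket => identical prefix; only the similarity clause remains
      dup_against <- 0L
      for (j in kept_here) {
        if (readSimilarity(seqs[i], seqs[j]) > simThreshold) {
          dup_against <- j
          break
        }
      }
      if (dup_against > 0L) {
        rm_pairs_kept <- c(rm_pairs_kept, ids[dup_against])
        rm_pairs_rm <- c(rm_pairs_rm, ids[i])
      } else {
        keep[i] <- TRUE
        kept_here <- c(kept_here, i)
      }
    }
  }
  kept <- if (is(reads, "XStringSet")) reads[keep]
          else Biostrings::DNAStringSet(seqs[keep])
  if (is.null(names(kept))) names(kept) <- ids[keep]
  new("DedupResult",
      kept = kept,
      n_input = length(seqs),
      n_kept = sum(keep),
      n_removed = length(rm_pairs_rm),
      removed_pairs = data.frame(kept_id = rm_pairs_kept,
                                 removed_id = rm_pairs_rm,
                                 stringsAsFactors = FALSE))
}

#' Deduplicate a FASTQ file
#'
#' File-level wrapper around [dedupReads()]: reads \code{infile}, writes the
#' kept reads to \code{outfile} and, optionally, a report TSV
#' (\code{kept_id<TAB>removed_id} pairs preceded by a \code{#} summary
#' line).
#'
#' @param infile input FASTQ path.
#' @param outfile output FASTQ path.
#' @param report optional report TSV path.
#' @param prefixLen,simThreshold see [isPCRDuplicate()].
#' @return the [DedupResult-class], invisibly.
#' @export
dedupFastq <- function(infile, outfile, report = NULL,
                       prefixLen = 10L, simThreshold = 0.90) {
  reads <- tryCatch(readFastqReads(infile), error = function(e)
    stop("malformed FASTQ '", infile, "': ", conditionMessage(e),
         call. = FALSE))
  res <- dedupReads(reads, prefixLen = prefixLen,
                    simThreshold = simThreshold)
  writeFastqReads(keptReads(res), outfile)
  if (!is.null(report)) {
    con <- file(report, "w")
    on.exit(close(con))
    writeLines(sprintf("# n_input=%d n_kept=%d n_removed=%d",
                       res@n_input, res@n_kept, res@n_removed), con)
    writeLines("kept_id\tremoved_id", con)
    rp <- removedPairs(res)
    if (nrow(rp))
      writeLines(paste(rp$kept_id, rp$removed_id, sep = "\t"), con)
  }
  invisible(res)
}
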