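# Exhaustive short-read alignment and read classification.
#
# The contract is complete enumeration: every (reference, position, strand)
# whose Hamming distance to the read is <= v is reported, for the forward
# read and its reverse complement. The default implementation seeds on
# read segments (pigeonhole over v+1 segments) for speed; method = "naive"
# is the brute-force double loop used as the independent oracle.

#' Align reads exhaustively by Hamming distance
#'
#' @param reads character vector of reads (names become read ids; unnamed
#'   reads are numbered).
#' @param references named character vector of reference sequences.
#' @param max_mismatches maximum Hamming distance v (no indels). An N in
#'   read or reference counts as a mismatch at any position.
#' @param method "seeded" (k-mer seeded, default) or "naive" (brute-force
#'   double loop; the oracle both must agree with).
#' @return data.frame with columns `read_id`, `target`, `pos` (0-based),
#'   `strand` ("+"/"-"), `mismatches`; one row per hit.
#' @export
align_all <- function(reads, references, max_mismatches = 2L,
                      method = c("seeded", "naive")) {
  method <- match.arg(method)
  if (is.null(names(references)))
    stop("references must be named")
  ids <- names(reads) %||% as.character(seq_along(reads))
  h <- align_all_cpp(toupper(unname(reads)), toupper(unname(references)),
                     as.integer(max_mismatches), method == "naive")
  data.frame(read_id = ids[h$read],
             target = names(references)[h$ref],
             pos = h$pos,
             strand = c("+", "-")[h$strand + 1L],
             mismatches = h$mm,
             stringsAsFactors = FALSE)
}

#' Classify reads as unique, multi-mapping, or unmapped
#'
#' With `best_stratum = TRUE` (default) hits are first filtered per read to
#' the minimum-mismatch stratum, and "unique" means exactly one hit at that
#' stratum (so a read with one perfect hit and several 2-mismatch hits is
#' unique). With `best_stratum = FALSE` a read is unique only if it has one
#' hit overall.
#'
#' @param hits data.frame as returned by [align_all()] against the genome.
#' @param read_ids ids of all reads aligned (so unmapped reads appear).
#' @param best_stratum filter to the minimum-mismatch stratum first.
#' @return list with `classes` (data.frame read_id / class / n_hits) and
#'   `hits` (the retained, possibly stratum-filtered, hit table).
#' @export
classify_reads <- function(hits, read_ids, best_stratum = TRUE) {
  if (best_stratum && nrow(hits)) {
    minmm <- tapply(hits$mismatches, hits$read_id, min)
    hits <- hits[hits$mismatches == minmm[hits$read_id], , drop = FALSE]
  }
  n <- table(factor(hits$read_id, levels = read_ids))
  cls <- ifelse(n == 0L, "unmapped", ifelse(n == 1L, "unique", "multi"))
  list(classes = data.frame(read_id = read_ids, class = unname(cls),
                            n_hits = as.integer(n),
                            stringsAsFactors = FALSE),
       hits = hits)
}

#' Library size of a classified sample
#'
#' The library size convention is total genome-mapping reads: unique plus
#' multi-mapping, excluding unmapped. It is the CPM denominator downstream.
#'
#' @param classified output of [classify_reads()] or [read_sam()].
#' @return integer count.
#' @export
library_size <- function(classified) {
  sum(classified$classes$class != "unmapped")
}

#' Ingest pre-computed alignments from SAM
#'
#' Expects a SAM in which all (secondary) alignments of each read are
#' reported and each mapped record carries an NM tag. Records are grouped
#' by read name and classified with the same best-stratum rule as
#' [classify_reads()].
#'
#' @param path SAM file path.
#' @param best_stratum see [classify_reads()].
#' @return as [classify_reads()], plus element `seqs`: named character
#'   vector of primary-record read sequences (reverse-complemented back to
#'   original orientation for minus-strand primaries).
#' @export
read_sam <- function(path, best_stratum = TRUE) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "seq"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  qname <- x$qname
  flag <- x$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  nm <- x$tag$NM
  if (any(mapped & is.na(nm)))
    stop("mapped SAM record without NM tag (read '",
         qname[which(mapped & is.na(nm))[1]], "') and no reference to recompute")
  hits <- data.frame(read_id = qname[mapped],
                     target = as.character(x$rname[mapped]),
                     pos = x$pos[mapped] - 1L,
                     strand = as.character(x$strand[mapped]),
                     mismatches = nm[mapped],
                     stringsAsFactors = FALSE)
  read_ids <- unique(qname)
  out <- classify_reads(hits, read_ids, best_stratum)
  primary <- bitwAnd(flag, 256L) == 0L
  seqs <- as.character(x$seq[primary])
  # recover original read orientation for minus-strand primaries
  minus <- mapped[primary] & as.character(x$strand[primary]) == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  out$seqs <- setNames(seqs, qname[primary])
  out
}

#' Write alignments as SAM
#'
#' Dumps a classified hit set as a SAM file (primary record first per read,
#' remaining hits as secondary records with flag 0x100; unmapped reads get
#' flag 0x4 records). Round-trips through [read_sam()] to identical
#' classifications and counts.
#'
#' @param classified output of [classify_reads()].
#' @param seqs named character vector of the original read sequences.
#' @param references named character vector of reference sequences (for
#'   header lengths).
#' @param path output path.
#' @export
write_sam <- function(classified, seqs, references, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (rn in names(references))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", rn, nchar(references[[rn]])), con)
  cls <- classified$classes
  hits <- classified$hits
  un <- cls$read_id[cls$class == "unmapped"]
  if (length(un)) {
    usq <- unname(seqs[un])
    writeLines(paste(un, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, usq,
                     strrep("I", nchar(usq)), sep = "\t"), con)
  }
  h <- hits[order(hits$read_id), , drop = FALSE]
  if (nrow(h)) {
    first <- !duplicated(h$read_id)
    rlen <- nchar(seqs[h$read_id])
    fl <- ifelse(first, 0L, 256L) + ifelse(h$strand == "-", 16L, 0L)
    sq <- rep("*", nrow(h))
    fseq <- unname(seqs[h$read_id[first]])
    fmin <- h$strand[first] == "-"
    fseq[fmin] <- revcomp(fseq[fmin])
    sq[first] <- fseq
    ql <- rep("*", nrow(h))
    ql[first] <- strrep("I", nchar(fseq))
    writeLines(paste(h$read_id, fl, h$target, h$pos + 1L, 255L,
                     paste0(rlen, "M"), "*", 0L, 0L, sq, ql,
                     paste0("NM:i:", h$mismatches), sep = "\t"), con)
  }
  invisible(path)
}
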