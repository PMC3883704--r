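# The two-pass counting algorithm.
#
# Pass 1: uniquely mapping reads are counted by >= 1 bp overlap with the
# repeat annotation (larger-overlap tie-break between subfamilies, then
# lexicographic subfamily name). Pass 2: multi-mapping reads are aligned to
# per-subfamily pseudo-genomes (all instances concatenated with N spacers)
# and assigned 1/k to each of the k distinct subfamilies hit. Counts from
# both passes are added per subfamily and rounded half-up once, at the
# matrix stage.

#' Build per-subfamily pseudo-genomes
#'
#' Each subfamily's pseudo-genome is the concatenation, in annotation order,
#' of its genomic instance sequences joined by runs of N of `spacer_length`.
#' N never matches a read base, so no read can align across an instance
#' junction as long as the spacer is at least the read length. Minus-strand
#' instances are extracted as plus-strand genomic sequence (no reverse
#' complement): alignment is strand-agnostic, so orientation is immaterial.
#'
#' @param genome named character vector of contig sequences.
#' @param catalog a [repeat_catalog()].
#' @param spacer_length spacer run length; must be >= read length.
#' @param revcomp_minus reverse-complement minus-strand instances instead of
#'   taking the plus-strand genomic sequence. Immaterial for the
#'   strand-agnostic aligner; exposed because the convention is not fixed
#'   by the method description.
#' @param flank genomic flank in bp added on both sides of each instance
#'   (clipped at contig bounds). Default 0: flankless construction keeps
#'   the counting semantics exact.
#' @return a `pseudo_genomes` list: `seqs` (named character vector, one per
#'   subfamily), `offsets` (per subfamily, data.frame instance_id / offset /
#'   length), `spacer_length`.
#' @export
build_pseudogenomes <- function(genome, catalog, spacer_length = 50L,
                                revcomp_minus = FALSE, flank = 0L) {
  spacer <- strrep("N", spacer_length)
  subs <- sort(unique(catalog$subfamily))
  seqs <- character(0)
  offsets <- list()
  for (s in subs) {
    ins <- catalog[catalog$subfamily == s, , drop = FALSE]
    ins <- ins[order(ins$contig, ins$start), , drop = FALSE]
    pieces <- character(nrow(ins))
    lens <- integer(nrow(ins))
    for (i in seq_len(nrow(ins))) {
      ctg <- ins$contig[i]
      if (!ctg %in% names(genome))
        stop("instance ", ins$instance_id[i], " on unknown contig '", ctg, "'")
      if (ins$end[i] > nchar(genome[[ctg]]))
        stop("instance ", ins$instance_id[i], " extends beyond contig '",
             ctg, "'")
      st <- max(0L, ins$start[i] - flank)
      en <- min(nchar(genome[[ctg]]), ins$end[i] + flank)
      piece <- substring(genome[[ctg]], st + 1L, en)
      if (revcomp_minus && ins$strand[i] == "-") piece <- revcomp(piece)
      pieces[i] <- piece
      lens[i] <- en - st
    }
    off <- cumsum(c(0L, head(lens + spacer_length, -1L)))
    seqs[[s]] <- paste(pieces, collapse = spacer)
    offsets[[s]] <- data.frame(instance_id = ins$instance_id, offset = off,
                               length = lens, stringsAsFactors = FALSE)
  }
  structure(list(seqs = seqs, offsets = offsets,
                 spacer_length = as.integer(spacer_length)),
            class = "pseudo_genomes")
}

#' Count unique reads by repeat overlap
#'
#' A uniquely mapping read whose alignment interval overlaps an annotated
#' repeat instance by at least 1 bp is counted once for that instance's
#' subfamily. A read overlapping instances of several subfamilies goes to
#' the subfamily with the largest overlap (per subfamily, the best
#' instance), ties broken by lexicographic subfamily name. Reads overlapping
#' no instance contribute nothing (they stay in the library size).
#'
#' @param unique_hits hit table (one row per read: `read_id`, `target`,
#'   `pos`) for uniquely mapping reads.
#' @param read_lengths integer vector of read lengths aligned with the rows
#'   of `unique_hits` (recycled if length 1).
#' @param catalog a [repeat_catalog()].
#' @return list with `counts` (named numeric, zero-filled over the
#'   catalog's subfamilies) and `attribution` (data.frame read_id /
#'   subfamily, NA for non-overlapping reads).
#' @export
count_unique_overlaps <- function(unique_hits, read_lengths, catalog) {
  subs <- sort(unique(catalog$subfamily))
  counts <- setNames(numeric(length(subs)), subs)
  n <- nrow(unique_hits)
  attribution <- data.frame(read_id = unique_hits$read_id,
                            subfamily = rep(NA_character_, n),
                            stringsAsFactors = FALSE)
  if (n) {
    rl <- rep_len(read_lengths, n)
    reads_gr <- GenomicRanges::GRanges(
      unique_hits$target,
      IRanges::IRanges(start = unique_hits$pos + 1L, width = rl))
    cat_gr <- catalog_granges(catalog)
    ov <- GenomicRanges::findOverlaps(reads_gr, cat_gr, ignore.strand = TRUE)
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov)
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(reads_gr)[q],
        IRanges::ranges(cat_gr)[S4Vectors::subjectHits(ov)]))
      sf <- catalog$subfamily[S4Vectors::subjectHits(ov)]
      # per (read, subfamily) keep max instance overlap, then pick the
      # largest-overlap subfamily, lexicographic on ties
      key <- paste(q, sf, sep = "\r")
      best <- tapply(w, key, max)
      kq <- as.integer(sub("\r.*", "", names(best)))
      ksf <- sub(".*\r", "", names(best))
      ord <- order(kq, -as.numeric(best), ksf)
      first <- !duplicated(kq[ord])
      win_q <- kq[ord][first]
      win_sf <- ksf[ord][first]
      attribution$subfamily[win_q] <- win_sf
      tab <- table(win_sf)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  list(counts = counts, attribution = attribution)
}

#' Fractional 1/k assignment of multi-mapping reads
#'
#' Each multi-mapping read is aligned against every subfamily pseudo-genome;
#' the set of distinct subfamilies with at least one hit (multiple hits
#' within one pseudo-genome count once) determines the weight: a read
#' hitting k subfamilies contributes 1/k to each. Reads hitting no
#' pseudo-genome are recorded as unassigned and remain in the library size.
#'
#' @param multi_seqs named character vector of multi-mapping read sequences.
#' @param pseudo a `pseudo_genomes` object from [build_pseudogenomes()].
#' @param max_mismatches alignment mismatch cap (same v as the genomic
#'   pass).
#' @param method alignment method, see [align_all()].
#' @return list with `assignments` (data.frame read_id / subfamily /
#'   weight) and `unassigned` (character vector of read ids).
#' @export
assign_multimap <- function(multi_seqs, pseudo, max_mismatches = 2L,
                            method = "seeded") {
  if (!length(multi_seqs))
    return(list(assignments = data.frame(read_id = character(),
                                         subfamily = character(),
                                         weight = numeric(),
                                         stringsAsFactors = FALSE),
                unassigned = character(0)))
  hits <- align_all(multi_seqs, pseudo$seqs, max_mismatches, method)
  pairs <- unique(hits[, c("read_id", "target")])
  k <- table(pairs$read_id)
  assignments <- data.frame(read_id = pairs$read_id,
                            subfamily = pairs$target,
                            weight = 1 / as.numeric(k[pairs$read_id]),
                            stringsAsFactors = FALSE)
  assignments <- assignments[order(assignments$read_id,
                                   assignments$subfamily), , drop = FALSE]
  rownames(assignments) <- NULL
  list(assignments = assignments,
       unassigned = setdiff(names(multi_seqs), pairs$read_id))
}

round_half_up <- function(x) floor(x + 0.5)

#' Aggregate both passes into a subfamily count matrix
#'
#' The fractional-stage entry for a subfamily and sample is the unique-read
#' count plus the sum of fractional multi-read weights; the rounded stage
#' applies round-half-up once. Rows are zero-filled over all catalog
#' subfamilies.
#'
#' @param unique_counts named list (per sample) of named count vectors from
#'   [count_unique_overlaps()].
#' @param assignments named list (per sample) of assignment data.frames
#'   from [assign_multimap()].
#' @param catalog a [repeat_catalog()].
#' @param library_sizes named numeric vector of per-sample library sizes.
#' @return a `subfamily_counts` object: `fractional` and `rounded`
#'   (subfamily x sample matrices), `library_sizes`, `features` (subfamily /
#'   family / class data.frame).
#' @export
aggregate_counts <- function(unique_counts, assignments, catalog,
                             library_sizes) {
  samples <- names(unique_counts)
  if (!identical(sort(samples), sort(names(assignments))))
    stop("sample sets differ between unique and multi passes")
  if (!identical(sort(samples), sort(names(library_sizes))))
    stop("sample sets differ between counts and library sizes")
  feats <- catalog_subfamilies(catalog)
  subs <- feats$subfamily
  frac <- matrix(0, nrow = length(subs), ncol = length(samples),
                 dimnames = list(subs, samples))
  for (s in samples) {
    u <- unique_counts[[s]]
    frac[names(u), s] <- frac[names(u), s] + u
    a <- assignments[[s]]
    if (nrow(a)) {
      ws <- tapply(a$weight, a$subfamily, sum)
      bad <- setdiff(names(ws), subs)
      if (length(bad))
        stop("assignment to unknown subfamily: ", paste(bad, collapse = ", "))
      frac[names(ws), s] <- frac[names(ws), s] + as.numeric(ws)
    }
  }
  structure(list(fractional = frac, rounded = round_half_up(frac),
                 library_sizes = library_sizes[samples], features = feats),
            class = "subfamily_counts")
}

#' @export
print.subfamily_counts <- function(x, ...) {
  cat(sprintf("subfamily_counts: %d subfamilies x %d samples\n",
              nrow(x$fractional), ncol(x$fractional)))
  invisible(x)
}

#' Write / read a count matrix as TSV
#'
#' Rows are subfamilies with family and class columns, then one column per
#' sample; a comment header records the library sizes and stage.
#'
#' @param counts a `subfamily_counts` object.
#' @param path output path.
#' @param stage "rounded" (default) or "fractional".
#' @export
write_counts <- function(counts, path, stage = c("rounded", "fractional")) {
  stage <- match.arg(stage)
  m <- counts[[stage]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# stage: %s", stage),
               sprintf("# library_sizes: %s",
                       paste(sprintf("%s=%d", names(counts$library_sizes),
                                     as.integer(counts$library_sizes)),
                             collapse = " "))), con)
  df <- data.frame(counts$features[, c("subfamily", "family", "class")],
                   m, check.names = FALSE)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  stage <- sub("^# stage: ", "", grep("^# stage:", hdr, value = TRUE))
  ls_line <- sub("^# library_sizes: ", "",
                 grep("^# library_sizes:", hdr, value = TRUE))
  kv <- strsplit(strsplit(ls_line, " ")[[1]], "=")
  lib <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                  vapply(kv, `[`, "", 1))
  df <- read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                   header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(m) <- df$subfamily
  out <- list(fractional = m, rounded = round_half_up(m),
              library_sizes = lib,
              features = data.frame(df[, 1:3],
                                    n_instances = NA_integer_,
                                    stringsAsFactors = FALSE))
  if (stage == "rounded") out$fractional <- m
  structure(out, class = "subfamily_counts")
}
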