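# Repeat annotations and sequence I/O.
#
# All coordinates are 0-based half-open internally; conversion to and from
# 1-based inclusive happens only at format boundaries (RepeatMasker .out).
# BED is already 0-based half-open and passes through unchanged.

#' Construct a repeat catalog
#'
#' A repeat catalog is the set of annotated repeat instances on a genome:
#' one row per genomic instance carrying its interval, strand and the
#' subfamily / family / class labels. The subfamily (the RepeatMasker repeat
#' name) is the unit of quantification; it must map to a single
#' (family, class) pair.
#'
#' @param df data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open), `strand` ("+" or "-"), `subfamily`, `family`, `class`, and
#'   optionally `instance_id` (assigned sequentially when absent).
#' @return a `repeat_catalog` (a data.frame sorted by contig then start,
#'   with unique integer `instance_id`).
#' @export
repeat_catalog <- function(df) {
  needed <- c("contig", "start", "end", "strand", "subfamily", "family", "class")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("repeat catalog is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$instance_id)) df$instance_id <- seq_len(nrow(df))
  if (anyDuplicated(df$instance_id))
    stop("instance ids must be unique")
  if (nrow(df)) {
    if (any(df$start < 0) || any(df$end <= df$start))
      stop("invalid interval: require 0 <= start < end")
    if (!all(df$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    fc <- unique(df[, c("subfamily", "family", "class")])
    if (anyDuplicated(fc$subfamily))
      stop("subfamily must determine (family, class) uniquely")
    df <- df[order(df$contig, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("repeat_catalog", "data.frame")
  df
}

#' @export
print.repeat_catalog <- function(x, ...) {
  cat(sprintf("repeat_catalog: %d instances, %d subfamilies, %d contigs\n",
              nrow(x), length(unique(x$subfamily)), length(unique(x$contig))))
  NextMethod()
}

#' Subfamily table of a catalog
#'
#' @param catalog a [repeat_catalog()].
#' @return data.frame with one row per subfamily (`subfamily`, `family`,
#'   `class`, `n_instances`), sorted by subfamily name.
#' @export
catalog_subfamilies <- function(catalog) {
  u <- unique(as.data.frame(catalog)[, c("subfamily", "family", "class")])
  u <- u[order(u$subfamily), , drop = FALSE]
  u$n_instances <- as.integer(table(catalog$subfamily)[u$subfamily])
  rownames(u) <- NULL
  u
}

#' Catalog as a GRanges for overlap queries
#' @param catalog a [repeat_catalog()].
#' @return GRanges with 1-based coordinates and instance metadata columns.
#' @export
catalog_granges <- function(catalog) {
  GenomicRanges::GRanges(
    seqnames = catalog$contig,
    ranges   = IRanges::IRanges(start = catalog$start + 1L, end = catalog$end),
    strand   = catalog$strand,
    subfamily = catalog$subfamily, family = catalog$family,
    class = catalog$class, instance_id = catalog$instance_id)
}

#' Read a RepeatMasker .out annotation
#'
#' Parses the standard RepeatMasker `.out` dialect: three header lines,
#' whitespace-delimited columns, query coordinates 1-based inclusive,
#' strand column "+" or "C" (complement), a repeat-name column and a
#' "class/family" column. Coordinates are converted to 0-based half-open;
#' "C" becomes "-"; the class/family column is split on "/" (when there is
#' no "/", family is set equal to class).
#'
#' @param path path to a RepeatMasker .out file.
#' @return a [repeat_catalog()].
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3)
    stop("RepeatMasker .out file must have 3 header lines: ", path)
  body <- lines[-(1:3)]
  body_no <- which(nzchar(trimws(body))) + 3L
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    return(repeat_catalog(data.frame(
      contig = character(), start = integer(), end = integer(),
      strand = character(), subfamily = character(), family = character(),
      class = character(), stringsAsFactors = FALSE)))
  }
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) < 11)
      stop(sprintf("malformed RepeatMasker line %d: expected >= 11 fields, got %d",
                   body_no[i], length(f)))
    start1 <- suppressWarnings(as.integer(f[6]))
    end1 <- suppressWarnings(as.integer(f[7]))
    if (is.na(start1) || is.na(end1))
      stop(sprintf("malformed RepeatMasker line %d: non-numeric coordinates",
                   body_no[i]))
    if (!f[9] %in% c("+", "C"))
      stop(sprintf("malformed RepeatMasker line %d: strand '%s'", body_no[i], f[9]))
    cf <- strsplit(f[11], "/", fixed = TRUE)[[1]]
    klass <- cf[1]
    fam <- if (length(cf) >= 2) cf[2] else cf[1]
    # 1-based inclusive -> 0-based half-open
    start0 <- start1 - 1L
    end0 <- end1
    if (end0 <= start0)
      stop(sprintf("malformed RepeatMasker line %d: end < start after conversion",
                   body_no[i]))
    data.frame(contig = f[5], start = start0, end = end0,
               strand = if (f[9] == "C") "-" else "+",
               subfamily = f[10], family = fam, class = klass,
               stringsAsFactors = FALSE)
  })
  repeat_catalog(do.call(rbind, rows))
}

#' Write a RepeatMasker-style .out file
#'
#' Inverse of [read_repeatmasker_out()] for the columns this package uses;
#' coordinate conversion back to 1-based inclusive is exact, so
#' read -> write -> read is an identity.
#'
#' @param catalog a [repeat_catalog()].
#' @param path output path.
#' @export
write_repeatmasker_out <- function(catalog, path) {
  hdr <- c(
    "   SW  perc perc perc  query     position in query    matching repeat           position in repeat",
    "score  div. del. ins.  sequence  begin  end (left)    repeat    class/family  begin  end (left)  ID",
    "")
  cf <- ifelse(catalog$family == catalog$class, catalog$class,
               paste0(catalog$class, "/", catalog$family))
  body <- sprintf("  100   0.0  0.0  0.0  %s  %d  %d  (0)  %s  %s  %s  1  100  (0)  %d",
                  catalog$contig, catalog$start + 1L, catalog$end,
                  ifelse(catalog$strand == "-", "C", "+"),
                  catalog$subfamily, cf, catalog$instance_id)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write repeat catalogs as BED6
#'
#' BED is 0-based half-open, matching the internal convention, so no
#' coordinate conversion occurs. The name column encodes the labels as
#' `subfamily#class/family`; a bare name is taken as subfamily with family
#' and class equal to it. Write then read reproduces the catalog exactly.
#'
#' @param path BED6 file path.
#' @return [repeat_catalog()] for `read_bed`; invisibly the path for
#'   `write_bed`.
#' @export
read_bed <- function(path) {
  empty <- repeat_catalog(data.frame(
    contig = character(), start = integer(), end = integer(),
    strand = character(), subfamily = character(), family = character(),
    class = character(), stringsAsFactors = FALSE))
  if (!file.size(path)) return(empty)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 6)
    stop("BED6 requires at least 6 columns, got ", ncol(df))
  nm <- as.character(df[[4]])
  parse_name <- function(s) {
    h <- strsplit(s, "#", fixed = TRUE)[[1]]
    if (length(h) == 1) return(c(h, h, h))
    cf <- strsplit(h[2], "/", fixed = TRUE)[[1]]
    c(h[1], if (length(cf) >= 2) cf[2] else cf[1], cf[1])
  }
  lab <- t(vapply(nm, parse_name, character(3)))
  repeat_catalog(data.frame(
    contig = as.character(df[[1]]), start = as.integer(df[[2]]),
    end = as.integer(df[[3]]), strand = as.character(df[[6]]),
    subfamily = lab[, 1], family = lab[, 2], class = lab[, 3],
    instance_id = if (ncol(df) >= 7) as.integer(df[[7]]) else as.integer(df[[5]]),
    stringsAsFactors = FALSE))
}

#' @rdname read_bed
#' @param catalog a [repeat_catalog()].
#' @export
write_bed <- function(catalog, path) {
  if (!nrow(catalog)) {
    file.create(path)
    return(invisible(path))
  }
  name <- paste0(catalog$subfamily, "#", catalog$class, "/", catalog$family)
  out <- data.frame(catalog$contig, catalog$start, catalog$end, name,
                    catalog$instance_id, catalog$strand, catalog$instance_id)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write FASTA
#'
#' Sequences are upper-cased on read. Backed by Biostrings.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(toupper(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write FASTQ (Phred+33)
#'
#' @param path file path.
#' @return `read_fastq`: data.frame with columns `id`, `seq`, `qual`
#'   (sequences upper-cased).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("FASTQ record count is not a multiple of 4: ", path)
  n <- length(lines) / 4
  if (!n) return(data.frame(id = character(), seq = character(),
                            qual = character(), stringsAsFactors = FALSE))
  id <- sub("^@", "", sub("\\s.*$", "", lines[seq(1, by = 4, length.out = n)]))
  seq <- toupper(lines[seq(2, by = 4, length.out = n)])
  qual <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop(sprintf("FASTQ record %d ('%s'): sequence and quality lengths differ",
                 bad[1], id[bad[1]]))
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence and quality lengths differ")
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    out <- rbind(paste0("@", reads$id), reads$seq,
                 rep("+", nrow(reads)), reads$qual)
    writeLines(as.vector(out), con)
  }
  invisible(path)
}
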