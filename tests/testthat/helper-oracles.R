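# Independent oracles used across the suite. These deliberately avoid the
# package's production code paths: the alignment oracle is a plain R
# sliding-window scan, and the pipeline oracle re-derives classification,
# overlap attribution and 1/k assignment from first principles.

random_dna_str <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# all 0-based start positions where `read` matches `ref` with <= v
# mismatches (one strand); N mismatches everything
oracle_scan_one <- function(read, ref, v) {
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  L <- length(rd)
  n <- length(rf) - L + 1
  if (n < 1) return(data.frame(pos = integer(), mm = integer()))
  mm <- integer(n)
  for (i in seq_len(L)) {
    seg <- rf[i:(i + n - 1)]
    mm <- mm + (seg != rd[i] | seg == "N" | rd[i] == "N")
  }
  keep <- which(mm <= v)
  data.frame(pos = keep - 1L, mm = mm[keep])
}

# full hit table in align_all's format, via the R scan on both strands
oracle_align <- function(reads, references, v) {
  ids <- names(reads)
  if (is.null(ids)) ids <- as.character(seq_along(reads))
  out <- list()
  for (i in seq_along(reads)) {
    for (rn in names(references)) {
      fw <- oracle_scan_one(reads[[i]], references[[rn]], v)
      rv <- oracle_scan_one(rc_chr(reads[[i]]), references[[rn]], v)
      if (nrow(fw))
        out[[length(out) + 1]] <- data.frame(
          read_id = ids[i], target = rn, pos = fw$pos, strand = "+",
          mismatches = fw$mm, stringsAsFactors = FALSE)
      if (nrow(rv))
        out[[length(out) + 1]] <- data.frame(
          read_id = ids[i], target = rn, pos = rv$pos, strand = "-",
          mismatches = rv$mm, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(read_id = character(), target = character(),
                      pos = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

sort_hits <- function(h) {
  h <- h[order(h$read_id, h$target, h$pos, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# Brute-force two-pass pipeline oracle. Aligns every read with the naive
# double-loop scanner, then re-applies, in plain R, best-stratum
# classification, any-overlap unique counting with the larger-overlap /
# lexicographic tie-break, and the distinct-subfamily 1/k rule.
# Returns fractional per-subfamily counts plus the accounting ledger.
oracle_pipeline <- function(reads, genome, catalog, v = 2L,
                            spacer_length = NULL) {
  seqs <- setNames(reads$seq, reads$id)
  rl <- nchar(reads$seq[1])
  if (is.null(spacer_length)) spacer_length <- rl
  hits <- repquant::align_all(seqs, genome, v, method = "naive")

  cls <- setNames(rep("unmapped", length(seqs)), names(seqs))
  idx <- split(seq_len(nrow(hits)), hits$read_id)
  best_hits <- list()
  for (rid in names(idx)) {
    h <- hits[idx[[rid]], , drop = FALSE]
    h <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
    best_hits[[rid]] <- h
    cls[[rid]] <- if (nrow(h) == 1) "unique" else "multi"
  }

  subs <- sort(unique(catalog$subfamily))
  counts <- setNames(numeric(length(subs)), subs)
  n_uo <- 0L; n_unon <- 0L
  for (rid in names(cls)[cls == "unique"]) {
    h <- best_hits[[rid]]
    s0 <- h$pos; e0 <- h$pos + rl
    ov <- pmin(e0, catalog$end) - pmax(s0, catalog$start)
    ov[catalog$contig != h$target] <- 0
    if (all(ov <= 0)) { n_unon <- n_unon + 1L; next }
    per_sub <- tapply(ov, catalog$subfamily, max)
    per_sub <- per_sub[per_sub > 0]
    win <- names(per_sub)[order(-per_sub, names(per_sub))][1]
    counts[[win]] <- counts[[win]] + 1
    n_uo <- n_uo + 1L
  }

  # pseudo-genomes rebuilt directly (instances joined by N runs)
  pseudo <- vapply(subs, function(s) {
    ins <- catalog[catalog$subfamily == s, , drop = FALSE]
    ins <- ins[order(ins$contig, ins$start), , drop = FALSE]
    paste(vapply(seq_len(nrow(ins)), function(i)
      substring(genome[[ins$contig[i]]], ins$start[i] + 1, ins$end[i]), ""),
      collapse = strrep("N", spacer_length))
  }, "")

  multi_ids <- names(cls)[cls == "multi"]
  n_assigned <- 0L; n_unassigned <- 0L
  weights <- list()
  if (length(multi_ids)) {
    ph <- repquant::align_all(seqs[multi_ids], pseudo, v, method = "naive")
    fams <- split(ph$target, ph$read_id)
    for (rid in multi_ids) {
      fs <- unique(fams[[rid]])
      if (is.null(fs) || !length(fs)) { n_unassigned <- n_unassigned + 1L; next }
      n_assigned <- n_assigned + 1L
      weights[[rid]] <- fs
      counts[fs] <- counts[fs] + 1 / length(fs)
    }
  }
  list(counts = counts,
       ledger = c(total = length(seqs), unique_overlap = n_uo,
                  unique_nonoverlap = n_unon, multi_assigned = n_assigned,
                  multi_unassigned = n_unassigned,
                  unmapped = sum(cls == "unmapped")),
       classes = cls, weights = weights)
}

# NB count matrix for differential-layer simulations:
# feature x sample, mu = lib * prop, size = 1/dispersion
simulate_nb_counts <- function(props, groups, lib_sizes, dispersion) {
  stopifnot(ncol(props) == length(unique(groups)))
  n <- length(groups)
  m <- matrix(0, nrow(props), n,
              dimnames = list(rownames(props),
                              paste0("s", seq_len(n))))
  for (j in seq_len(n)) {
    mu <- props[, groups[j]] * lib_sizes[j]
    m[, j] <- if (dispersion > 0)
      rnbinom(nrow(props), mu = mu, size = 1 / dispersion)
    else rpois(nrow(props), mu)
  }
  m
}

# small subfamily landscape for fast pipeline tests
tiny_specs <- function(weights_by_group = cbind(c(2, 1, 4), c(2, 1, 4),
                                                c(2, 1, 4))) {
  nms <- c("LINE_X", "SINE_Y", "SAT_Z")
  fams <- c("L1", "Alu", "Satellite")
  cls <- c("LINE", "SINE", "Satellite")
  lens <- c(300, 200, 250)
  div <- c(0.10, 0.06, 0.02)
  lapply(1:3, function(i)
    repquant::subfamily_spec(nms[i], fams[i], cls[i], lens[i], 3,
                             div[i], weights_by_group[i, ]))
}
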