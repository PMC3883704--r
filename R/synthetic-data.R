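# Synthetic repeat landscapes and replicated read sets.
#
# The generator plants divergent copies of per-subfamily consensus sequences
# into random background DNA, then simulates replicated groups of single-end
# reads whose per-subfamily counts are negative-binomial across replicates
# (gamma-perturbed multinomial expectations). All randomness flows from one
# master seed through named substreams, so every artifact is reproducible.

BASES <- c("A", "C", "G", "T")

# deterministic substream seed: hash of (master, key), kept below 2^31
derive_seed <- function(master, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483563
  as.integer(((as.numeric(master) %% 2147483563) * 48271 + h) %% 2147483563)
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# i.i.d. substitutions at rate `rate` (each hit base becomes one of the
# other three, uniformly)
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1)
  paste(ch, collapse = "")
}

#' Specify a planted repeat subfamily
#'
#' @param name,family,class subfamily label and its family / class labels
#'   (e.g. an L1-like subfamily has family "L1", class "LINE").
#' @param consensus_length length in bp of the subfamily consensus; planted
#'   instances have exactly this length (substitution-only divergence).
#' @param n_instances number of genomic copies to plant (>= 1).
#' @param divergence per-base substitution probability applied independently
#'   to each instance (0 to 0.3). Low divergence makes reads multi-map
#'   within the subfamily; higher divergence yields unique mappers.
#' @param weights named or unnamed nonnegative expression weights, one per
#'   design group, proportional to the subfamily's expected read share.
#' @return a `subfamily_spec` list.
#' @export
subfamily_spec <- function(name, family, class, consensus_length, n_instances,
                           divergence, weights) {
  if (divergence < 0 || divergence > 0.3)
    stop("divergence must be in [0, 0.3]")
  if (n_instances < 1) stop("n_instances must be >= 1")
  if (any(weights < 0)) stop("weights must be nonnegative")
  structure(list(name = name, family = family, class = class,
                 consensus_length = as.integer(consensus_length),
                 n_instances = as.integer(n_instances),
                 divergence = divergence, weights = as.numeric(weights)),
            class = "subfamily_spec")
}

#' Specify the replicated group design of a simulated study
#'
#' Defaults mirror a three-age-group liver RNA-seq study: groups of 5-, 24-
#' and 36-month-old animals, triplicate biological replicates, single-end
#' 50 nt reads. Dispersion 0.1 is a typical biological-replicate value for
#' bulk RNA-seq counts.
#'
#' @param groups group labels, in design order.
#' @param replicates biological replicates per group (>= 2).
#' @param dispersion negative-binomial dispersion of per-subfamily counts
#'   across replicates (variance = mu + dispersion * mu^2).
#' @param background_fraction expected fraction of reads drawn from
#'   non-repeat background DNA (stands in for the genic transcriptome).
#' @param reads_per_sample exact number of reads per sample.
#' @param read_length single-end read length in bp; must not exceed the
#'   shortest planted instance.
#' @param error_rate per-base sequencing substitution error rate.
#' @param seed master seed for the whole study.
#' @return a `design_spec` list.
#' @export
design_spec <- function(groups = c("5mo", "24mo", "36mo"), replicates = 3L,
                        dispersion = 0.1, background_fraction = 0.5,
                        reads_per_sample = 20000L, read_length = 50L,
                        error_rate = 0.001, seed = 1L) {
  if (replicates < 2) stop("replicates must be >= 2 for any tested contrast")
  if (background_fraction < 0 || background_fraction > 1)
    stop("background_fraction must be in [0, 1]")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(groups = as.character(groups),
                 replicates = as.integer(replicates),
                 dispersion = dispersion,
                 background_fraction = background_fraction,
                 reads_per_sample = as.integer(reads_per_sample),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "design_spec")
}

#' Bundled example repeat landscape
#'
#' Twelve subfamilies across LINE-, SINE-, LTR- and satellite-like classes
#' at toy scale (consensus 200-500 bp, 3-8 instances each, divergence
#' 0.02-0.15), with log-spread baseline weights. Four subfamilies (two
#' L1-like, two satellite-like) are derepressed four-fold in the oldest
#' group only, emulating derepression concentrated at advanced age.
#'
#' @param derepression fold increase applied in the last group to the
#'   derepressed subfamilies (default 4, i.e. log2FC = 2).
#' @return list of [subfamily_spec()] objects.
#' @export
example_subfamily_specs <- function(derepression = 4) {
  base <- list(
    #           name      family      class       len  n  div   w5
    list("L1_A",   "L1",        "LINE",      500, 6, 0.10, 4.0),
    list("L1_B",   "L1",        "LINE",      450, 5, 0.05, 2.0),
    list("L1_C",   "L1",        "LINE",      400, 8, 0.15, 1.0),
    list("L1_D",   "L1",        "LINE",      350, 4, 0.08, 0.5),
    list("B1_A",   "Alu",       "SINE",      200, 8, 0.06, 8.0),
    list("B1_B",   "Alu",       "SINE",      200, 6, 0.12, 3.0),
    list("ERVK_A", "ERVK",      "LTR",       400, 5, 0.04, 1.5),
    list("ERVK_B", "ERVK",      "LTR",       350, 4, 0.10, 0.8),
    list("MTA_A",  "ERVL-MaLR", "LTR",       300, 6, 0.07, 2.5),
    list("MTA_B",  "ERVL-MaLR", "LTR",       250, 3, 0.13, 0.4),
    list("SATMAJ", "Satellite", "Satellite", 300, 8, 0.02, 6.0),
    list("SATMIN", "Satellite", "Satellite", 250, 5, 0.03, 1.2))
  up <- c("L1_A", "L1_B", "SATMAJ", "SATMIN")
  lapply(base, function(b) {
    w <- rep(b[[7]], 3)
    if (b[[1]] %in% up) w[3] <- w[3] * derepression
    subfamily_spec(b[[1]], b[[2]], b[[3]], b[[4]], b[[5]], b[[6]], w)
  })
}

#' Expected proportions and true fold changes implied by a spec list
#'
#' Proportions are per-group expected read shares among repeat-derived
#' reads (they sum to 1 per group; the design's background fraction scales
#' them uniformly at simulation time, so fold changes are unaffected).
#'
#' @param specs list of [subfamily_spec()].
#' @param groups group labels (length must match the weight vectors).
#' @return list with `proportions` (subfamily x group matrix) and `log2fc`
#'   (subfamily x contrast matrix, columns named "B_vs_A").
#' @export
simulation_truth <- function(specs, groups) {
  W <- do.call(rbind, lapply(specs, function(s) {
    if (length(s$weights) != length(groups))
      stop("spec '", s$name, "': ", length(s$weights),
           " weights for ", length(groups), " groups")
    s$weights
  }))
  rownames(W) <- vapply(specs, `[[`, "", "name")
  colnames(W) <- groups
  P <- sweep(W, 2, colSums(W), "/")
  cmb <- utils::combn(seq_along(groups), 2)
  FC <- matrix(NA_real_, nrow(P), ncol(cmb),
               dimnames = list(rownames(P), apply(cmb, 2, function(ij)
                 paste0(groups[ij[2]], "_vs_", groups[ij[1]]))))
  for (k in seq_len(ncol(cmb)))
    FC[, k] <- log2(P[, cmb[2, k]] / P[, cmb[1, k]])
  list(proportions = P, log2fc = FC)
}

#' Build a toy genome with planted repeat instances
#'
#' The background is i.i.d. random DNA of `background_length` bp. Each
#' subfamily receives a random consensus; each instance is an independently
#' substituted copy of it (at the subfamily's divergence rate), planted at a
#' uniformly chosen non-overlapping position on a random strand
#' (minus-strand instances are planted as the reverse complement). The
#' catalog records the exact planted intervals.
#'
#' @param specs list of [subfamily_spec()].
#' @param background_length genome length in bp; must comfortably exceed the
#'   total planted length.
#' @param seed integer seed (substream "genome" of the master seed).
#' @param contig contig name.
#' @param max_tries placement retries per instance before giving up.
#' @return list with `genome` (named character vector of one contig),
#'   `catalog` ([repeat_catalog()]), `consensus` (named character vector),
#'   and `truth` (see [simulation_truth()]; computed against the group count
#'   implied by the weight vectors).
#' @export
build_genome <- function(specs, background_length = 1e5, seed = 1L,
                         contig = "chrS", max_tries = 1000L) {
  total <- sum(vapply(specs, function(s) s$consensus_length * s$n_instances, 0))
  if (background_length < 1.2 * total)
    stop("background_length ", background_length,
         " too small for ", total, " bp of planted sequence")
  set.seed(derive_seed(seed, "genome"))
  L <- as.integer(background_length)
  bg <- sample(BASES, L, replace = TRUE)

  consensus <- setNames(
    vapply(specs, function(s) random_dna(s$consensus_length), ""),
    vapply(specs, `[[`, "", "name"))

  placed <- matrix(numeric(0), ncol = 2) # occupied [start, end) intervals
  rows <- list()
  iid <- 0L
  for (s in specs) {
    for (k in seq_len(s$n_instances)) {
      len <- s$consensus_length
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        st <- sample.int(L - len + 1L, 1L) - 1L
        en <- st + len
        if (!nrow(placed) || all(en <= placed[, 1] | st >= placed[, 2])) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        stop("could not place instance of '", s$name,
             "' without overlap after ", max_tries, " tries")
      placed <- rbind(placed, c(st, en))
      inst <- mutate_seq(consensus[[s$name]], s$divergence)
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") inst <- revcomp(inst)
      bg[(st + 1):en] <- strsplit(inst, "")[[1]]
      iid <- iid + 1L
      rows[[iid]] <- data.frame(
        contig = contig, start = st, end = en, strand = strand,
        subfamily = s$name, family = s$family, class = s$class,
        instance_id = iid, stringsAsFactors = FALSE)
    }
  }
  ngroup <- length(specs[[1]]$weights)
  list(genome = setNames(paste(bg, collapse = ""), contig),
       catalog = repeat_catalog(do.call(rbind, rows)),
       consensus = consensus,
       truth = simulation_truth(specs, paste0("g", seq_len(ngroup))))
}

# intervals of background (non-repeat) DNA wide enough to source a read
background_windows <- function(genome, catalog, read_length) {
  out <- list()
  for (ctg in names(genome)) {
    len <- nchar(genome[[ctg]])
    ins <- catalog[catalog$contig == ctg, , drop = FALSE]
    ins <- ins[order(ins$start), , drop = FALSE]
    starts <- c(0L, ins$end)
    ends <- c(ins$start, len)
    keep <- (ends - starts) >= read_length
    if (any(keep))
      out[[ctg]] <- data.frame(contig = ctg, start = starts[keep],
                               end = ends[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    stop("no background window of at least ", read_length, " bp")
  do.call(rbind, out)
}

#' Simulate one replicate sample of single-end reads
#'
#' Per-subfamily expected read shares are the truth proportions scaled by
#' (1 - background_fraction), each multiplied by an independent gamma factor
#' with shape 1/dispersion and mean 1 (so counts are gamma-Poisson, i.e.
#' negative binomial, across replicates); the read total is then allocated
#' by a single multinomial draw, keeping reads-per-sample exact. Each repeat
#' read picks an instance uniformly, a start uniformly within it, a strand
#' by fair coin, and suffers i.i.d. substitution errors; background reads
#' are drawn from non-repeat windows.
#'
#' @param genome named character vector of contig sequences.
#' @param catalog the [repeat_catalog()] of planted instances.
#' @param truth output of [simulation_truth()] (or the `truth` element of
#'   [build_genome()]); its proportion columns are matched positionally to
#'   the design groups.
#' @param design a [design_spec()].
#' @param group group label (must be one of `design$groups`).
#' @param replicate replicate number.
#' @param seed integer seed for this sample.
#' @return list with `reads` (data.frame id/seq/qual) and `read_truth`
#'   (data.frame read_id / origin_instance / subfamily, with "background"
#'   rows for background reads).
#' @export
simulate_sample <- function(genome, catalog, truth, design, group, replicate,
                            seed) {
  gi <- match(group, design$groups)
  if (is.na(gi)) stop("unknown group: ", group)
  subf <- rownames(truth$proportions)
  minlen <- min(catalog$end - catalog$start)
  if (design$read_length > minlen)
    stop("read_length ", design$read_length,
         " exceeds shortest planted instance (", minlen, " bp)")
  set.seed(seed)
  n <- design$reads_per_sample
  rl <- design$read_length
  p <- truth$proportions[, gi]
  f <- design$background_fraction
  if (f > 0) {
    # independent gamma-Poisson draws give exact NB marginals per
    # subfamily; the background pool absorbs the remainder so the read
    # total stays exactly reads-per-sample
    mu <- n * (1 - f) * p
    k <- NULL
    for (try in 1:100) {
      k <- if (design$dispersion > 0)
        rnbinom(length(p), mu = mu, size = 1 / design$dispersion)
      else rpois(length(p), mu)
      if (sum(k) <= n) break
      k <- NULL
    }
    if (is.null(k))
      stop("repeat reads exceed reads_per_sample; lower the weights, ",
           "dispersion, or raise background_fraction")
    counts <- c(k, n - sum(k))
  } else {
    # no background to absorb fluctuations: condition on the total via a
    # gamma-perturbed multinomial (NB up to the compositional constraint)
    gam <- if (design$dispersion > 0)
      rgamma(length(p), shape = 1 / design$dispersion,
             rate = 1 / design$dispersion) else rep(1, length(p))
    counts <- c(as.vector(rmultinom(1, n, p * gam)), 0L)
  }
  names(counts) <- c(subf, "background")

  src_iid <- integer(0); src_start <- integer(0); src_ctg <- character(0)
  src_sub <- character(0)
  for (s in subf) {
    cs <- counts[[s]]
    if (!cs) next
    ins <- catalog[catalog$subfamily == s, , drop = FALSE]
    pick <- ins[sample.int(nrow(ins), cs, replace = TRUE), , drop = FALSE]
    off <- floor(runif(cs, 0, pick$end - pick$start - rl + 1))
    src_iid <- c(src_iid, pick$instance_id)
    src_start <- c(src_start, pick$start + as.integer(off))
    src_ctg <- c(src_ctg, pick$contig)
    src_sub <- c(src_sub, rep(s, cs))
  }
  nbg <- counts[["background"]]
  if (nbg > 0) {
    win <- background_windows(genome, catalog, rl)
    wts <- win$end - win$start - rl + 1
    wi <- sample.int(nrow(win), nbg, replace = TRUE, prob = wts)
    off <- floor(runif(nbg, 0, wts[wi]))
    src_iid <- c(src_iid, rep(NA_integer_, nbg))
    src_start <- c(src_start, win$start[wi] + as.integer(off))
    src_ctg <- c(src_ctg, win$contig[wi])
    src_sub <- c(src_sub, rep("background", nbg))
  }

  seqs <- substring(genome[src_ctg], src_start + 1L, src_start + rl)
  minus <- runif(n) < 0.5
  seqs[minus] <- revcomp(seqs[minus])
  if (design$error_rate > 0) {
    nerr <- rbinom(n, rl, design$error_rate)
    for (i in which(nerr > 0)) {
      ch <- strsplit(seqs[i], "")[[1]]
      at <- sample.int(rl, nerr[i])
      for (j in at) ch[j] <- sample(setdiff(BASES, ch[j]), 1)
      seqs[i] <- paste(ch, collapse = "")
    }
  }
  ord <- sample.int(n)
  ids <- sprintf("%s_rep%d_read%06d", group, replicate, seq_len(n))
  list(reads = data.frame(id = ids, seq = unname(seqs[ord]),
                          qual = strrep("I", rl), stringsAsFactors = FALSE),
       read_truth = data.frame(
         read_id = ids,
         origin_instance = ifelse(is.na(src_iid[ord]), "background",
                                  as.character(src_iid[ord])),
         subfamily = src_sub[ord], stringsAsFactors = FALSE))
}

#' Simulate a full replicated study to disk
#'
#' Writes, under `out_dir`: the genome FASTA, the annotation (RepeatMasker
#' .out and BED6), one FASTQ and one read-level truth TSV per sample, a
#' subfamily truth TSV (proportions and true log2 fold changes), and a
#' sample manifest TSV. Deterministic given `design$seed`.
#'
#' @param specs list of [subfamily_spec()].
#' @param design a [design_spec()].
#' @param out_dir output directory (created if needed).
#' @param background_length genome length in bp.
#' @return invisibly, a list with `manifest` (data.frame), `catalog`,
#'   `truth`, and the file paths written.
#' @export
simulate_study <- function(specs, design, out_dir, background_length = 1e5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- build_genome(specs, background_length, seed = design$seed)
  truth <- simulation_truth(specs, design$groups)

  genome_path <- file.path(out_dir, "genome.fasta")
  write_fasta(gen$genome, genome_path)
  out_path <- file.path(out_dir, "repeats.out")
  write_repeatmasker_out(gen$catalog, out_path)
  write_bed(gen$catalog, file.path(out_dir, "repeats.bed"))

  rows <- list()
  for (g in design$groups) {
    for (r in seq_len(design$replicates)) {
      sid <- sprintf("%s_rep%d", g, r)
      fq <- file.path(out_dir, paste0(sid, ".fastq"))
      tt <- file.path(out_dir, paste0(sid, ".read_truth.tsv"))
      rows[[sid]] <- data.frame(sample = sid, group = g, replicate = r,
                                fastq = fq, read_truth = tt,
                                stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (anyDuplicated(manifest$fastq))
    stop("output path collision in sample manifest")
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample[i]
    sim <- simulate_sample(gen$genome, gen$catalog, truth, design,
                           manifest$group[i], manifest$replicate[i],
                           seed = derive_seed(design$seed, sid))
    write_fastq(sim$reads, manifest$fastq[i])
    write.table(sim$read_truth, manifest$read_truth[i], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  tr <- data.frame(subfamily = rownames(truth$proportions),
                   truth$proportions, truth$log2fc, check.names = FALSE,
                   stringsAsFactors = FALSE)
  truth_path <- file.path(out_dir, "subfamily_truth.tsv")
  write.table(tr, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(manifest = manifest, catalog = gen$catalog, truth = truth,
                 genome_path = genome_path, annotation_path = out_path,
                 truth_path = truth_path, manifest_path = manifest_path))
}
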