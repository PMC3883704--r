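# Orchestration: simulate -> quantify -> diff, with a read-accounting
# ledger per sample, provenance headers, and a thin command-line front end.

str_hash <- function(s) {
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", h)
}

config_hash <- function(x) str_hash(paste(deparse(x), collapse = ""))

provenance_header <- function(config, seed) {
  c(sprintf("# repquant %s", as.character(packageVersion("repquant"))),
    sprintf("# config_hash: %s", config_hash(config)),
    sprintf("# seed: %s", seed))
}

#' Quantify one sample through the two-pass counting algorithm
#'
#' Aligns reads to the genome, classifies them (unique / multi / unmapped),
#' counts unique reads by repeat overlap, assigns multi-mapping reads
#' fractionally across pseudo-genomes, and returns the per-sample pieces
#' plus a read-accounting ledger that must balance exactly:
#' unique-overlap + unique-non-overlap + multi-assigned + multi-unassigned
#' + unmapped = total reads.
#'
#' @param reads data.frame with `id`, `seq` (a FASTQ read table).
#' @param genome named character vector of contig sequences.
#' @param catalog a [repeat_catalog()].
#' @param pseudo `pseudo_genomes` from [build_pseudogenomes()].
#' @param max_mismatches mismatch cap v for both passes.
#' @param best_stratum see [classify_reads()].
#' @param method alignment method ("seeded" or "naive").
#' @param classified optional precomputed classification (e.g. from
#'   [read_sam()]); when given, the genomic alignment pass is skipped and
#'   multi-read sequences are taken from `classified$seqs` if present.
#' @return list: `unique_counts`, `assignments`, `library_size`, `ledger`,
#'   `classified`.
#' @export
quantify_sample <- function(reads, genome, catalog, pseudo,
                            max_mismatches = 2L, best_stratum = TRUE,
                            method = "seeded", classified = NULL) {
  if (is.null(classified)) {
    if (!nrow(reads)) stop("sample has no reads")
    seqs <- setNames(reads$seq, reads$id)
    ghits <- align_all(seqs, genome, max_mismatches, method)
    classified <- classify_reads(ghits, names(seqs), best_stratum)
    classified$seqs <- seqs
  }
  cls <- classified$classes
  seqs <- classified$seqs
  uniq_ids <- cls$read_id[cls$class == "unique"]
  uh <- classified$hits[classified$hits$read_id %in% uniq_ids, , drop = FALSE]
  uo <- count_unique_overlaps(uh, nchar(seqs[uh$read_id]), catalog)
  multi_ids <- cls$read_id[cls$class == "multi"]
  am <- assign_multimap(seqs[multi_ids], pseudo, max_mismatches, method)
  n_assigned <- length(unique(am$assignments$read_id))
  ledger <- c(total = nrow(cls),
              unique_overlap = sum(!is.na(uo$attribution$subfamily)),
              unique_nonoverlap = sum(is.na(uo$attribution$subfamily)),
              multi_assigned = n_assigned,
              multi_unassigned = length(am$unassigned),
              unmapped = sum(cls$class == "unmapped"))
  if (ledger[["total"]] != sum(ledger[-1]))
    stop("read-accounting ledger does not balance: ",
         paste(names(ledger), ledger, sep = "=", collapse = " "))
  list(unique_counts = uo$counts, assignments = am$assignments,
       library_size = library_size(classified), ledger = ledger,
       classified = classified)
}

#' Run the simulation stage
#'
#' @param spec_file path to a JSON file with fields `subfamilies` (list of
#'   subfamily-spec fields) and `design` (design-spec fields), or NULL to
#'   use [example_subfamily_specs()] with the default [design_spec()].
#' @param out_dir output directory.
#' @param seed optional master-seed override.
#' @return see [simulate_study()].
#' @export
run_simulate <- function(spec_file = NULL, out_dir, seed = NULL) {
  if (is.null(spec_file)) {
    specs <- example_subfamily_specs()
    design <- design_spec()
    bg <- 1e5
  } else {
    cfg <- jsonlite::read_json(spec_file, simplifyVector = TRUE)
    specs <- lapply(seq_len(nrow(cfg$subfamilies)), function(i) {
      s <- cfg$subfamilies[i, ]
      subfamily_spec(s$name, s$family, s$class, s$consensus_length,
                     s$n_instances, s$divergence, unlist(s$weights))
    })
    design <- do.call(design_spec, cfg$design)
    bg <- cfg$background_length %||% 1e5
  }
  if (!is.null(seed)) design$seed <- as.integer(seed)
  res <- simulate_study(specs, design, out_dir, background_length = bg)
  writeLines(c(provenance_header(list(design = design), design$seed),
               paste0("samples: ", nrow(res$manifest))),
             file.path(out_dir, "run_info.txt"))
  invisible(res)
}

#' Run the quantification stage over a study
#'
#' @param genome_path FASTA genome.
#' @param annotation_path RepeatMasker .out (default) or BED6 annotation
#'   (chosen by file extension).
#' @param manifest data.frame (or TSV path) with columns `sample`, `group`,
#'   `replicate` and either `fastq` or `sam`.
#' @param out_dir output directory for count matrices and accounting JSON.
#' @param max_mismatches,best_stratum,method aligner settings.
#' @param spacer_length pseudo-genome spacer (defaults to the first
#'   sample's read length).
#' @return the `subfamily_counts` object (invisibly); files written:
#'   `counts_fractional.tsv`, `counts_rounded.tsv`, `accounting.json`.
#' @export
run_quantify <- function(genome_path, annotation_path, manifest, out_dir,
                         max_mismatches = 2L, best_stratum = TRUE,
                         method = "seeded", spacer_length = NULL) {
  if (is.character(manifest))
    manifest <- read.table(manifest, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- read_fasta(genome_path)
  catalog <- if (grepl("\\.bed$", annotation_path))
    read_bed(annotation_path) else read_repeatmasker_out(annotation_path)

  use_sam <- "sam" %in% names(manifest)
  first_reads <- if (use_sam) NULL else read_fastq(manifest$fastq[1])
  if (is.null(spacer_length))
    spacer_length <- if (use_sam) 100L else max(nchar(first_reads$seq))
  pseudo <- build_pseudogenomes(genome, catalog, spacer_length)

  unique_counts <- list(); assignments <- list()
  lib <- numeric(0); ledgers <- list()
  failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample[i]
    res <- tryCatch({
      if (use_sam) {
        cl <- read_sam(manifest$sam[i], best_stratum)
        quantify_sample(NULL, genome, catalog, pseudo, max_mismatches,
                        best_stratum, method, classified = cl)
      } else {
        reads <- if (i == 1 && !is.null(first_reads)) first_reads
                 else read_fastq(manifest$fastq[i])
        if (!nrow(reads)) stop("sample '", sid, "': empty FASTQ")
        quantify_sample(reads, genome, catalog, pseudo, max_mismatches,
                        best_stratum, method)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", sid, conditionMessage(res)))
      next
    }
    unique_counts[[sid]] <- res$unique_counts
    assignments[[sid]] <- res$assignments
    lib[[sid]] <- res$library_size
    ledgers[[sid]] <- as.list(res$ledger)
  }
  if (length(failures))
    stop("sample failures:\n", paste(failures, collapse = "\n"))
  counts <- aggregate_counts(unique_counts, assignments, catalog, lib)
  write_counts(counts, file.path(out_dir, "counts_fractional.tsv"),
               "fractional")
  write_counts(counts, file.path(out_dir, "counts_rounded.tsv"), "rounded")
  jsonlite::write_json(
    list(library_sizes = as.list(lib), ledgers = ledgers),
    file.path(out_dir, "accounting.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(counts)
}

#' Run the differential stage
#'
#' TMM-normalizes the rounded matrix with the supplied library sizes,
#' estimates a common NB dispersion, fits and tests every requested
#' pairwise contrast, attaches Storey q-values, writes one results TSV and
#' one scatter plot per contrast.
#'
#' @param counts a `subfamily_counts` object or path to a counts TSV from
#'   [write_counts()].
#' @param design data.frame (or TSV path) with columns `sample`, `group`.
#' @param contrasts list of `c(A, B)` pairs (A versus B); default: all
#'   later-vs-earlier group pairs in design order.
#' @param out_dir output directory.
#' @param seed recorded in output headers (the stage itself is
#'   deterministic).
#' @param fdr_bins q-value bin edges for scatter point sizes.
#' @return named list of per-contrast result data.frames (invisibly).
#' @export
run_diff <- function(counts, design, contrasts = NULL, out_dir,
                     seed = NA, fdr_bins = c(0.05, 0.01, 0.001)) {
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(design))
    design <- read.table(design, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- colnames(counts$rounded)
  missing <- setdiff(samples, design$sample)
  if (length(missing))
    stop("samples missing from design: ", paste(missing, collapse = ", "))
  groups <- design$group[match(samples, design$sample)]
  glev <- unique(design$group)
  if (is.null(contrasts)) {
    cmb <- utils::combn(seq_along(glev), 2)
    contrasts <- lapply(seq_len(ncol(cmb)),
                        function(k) c(glev[cmb[2, k]], glev[cmb[1, k]]))
  }
  norm <- tmm_factors(counts$rounded, counts$library_sizes)
  phi <- estimate_dispersion(counts$rounded, groups,
                             offset = log(norm$effective_library_sizes))
  results <- list()
  hdr <- provenance_header(list(groups = groups, phi = phi), seed)
  for (ct in contrasts) {
    label <- paste0(ct[1], "_vs_", ct[2])
    res <- fit_and_test(counts$rounded, groups,
                        norm$effective_library_sizes, phi, ct)
    res <- cbind(res[, "feature", drop = FALSE],
                 counts$features[match(res$feature,
                                       counts$features$subfamily),
                                 c("family", "class")],
                 res[, -1])
    results[[label]] <- res
    path <- file.path(out_dir, paste0("results_", label, ".tsv"))
    writeLines(hdr, path)
    suppressWarnings(write.table(res, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    plot_cpm_scatter(res, ct, file.path(out_dir,
                                        paste0("scatter_", label, ".png")),
                     fdr_bins)
  }
  invisible(results)
}

#' Scatter of group-mean log2 CPM for one contrast
#'
#' Group B on x, group A on y; points above the diagonal are enriched in
#' A. Point size encodes the q-value bin.
#'
#' @param result one result data.frame from [fit_and_test()] / [run_diff()].
#' @param contrast the `c(A, B)` pair plotted.
#' @param file output PNG path.
#' @param fdr_bins decreasing q-value bin edges.
#' @export
plot_cpm_scatter <- function(result, contrast, file,
                             fdr_bins = c(0.05, 0.01, 0.001)) {
  xa <- result[[paste0("logCPM.", contrast[2])]]
  ya <- result[[paste0("logCPM.", contrast[1])]]
  q <- result$qvalue
  size <- 0.8 + rowSums(outer(ifelse(is.na(q), 1, q), fdr_bins, "<")) * 0.5
  grDevices::png(file, width = 700, height = 700)
  on.exit(grDevices::dev.off())
  graphics::plot(xa, ya, cex = size, pch = 19,
                 col = grDevices::adjustcolor("steelblue4", 0.7),
                 xlab = paste("mean log2 CPM,", contrast[2]),
                 ylab = paste("mean log2 CPM,", contrast[1]),
                 main = paste(contrast[1], "vs", contrast[2]))
  graphics::abline(0, 1, lty = 2)
  invisible(file)
}

#' Command-line entry point
#'
#' Subcommands: `simulate --spec SPEC --out DIR [--seed N]`,
#' `quantify --genome FASTA --annotation OUT_OR_BED --manifest TSV --out DIR
#' [--mismatches N]`, and
#' `diff --counts TSV --design TSV --out DIR [--contrasts A:B,C:D]`.
#'
#' @param args character vector of arguments (default: the command line).
#' @return exit status, invisibly (0 on success).
#' @export
repquant_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: repquant <simulate|quantify|diff> [options]",
    "  simulate --out DIR [--spec JSON] [--seed N]",
    "  quantify --genome FA --annotation OUT|BED --manifest TSV --out DIR",
    "           [--mismatches N] [--method seeded|naive]",
    "  diff     --counts TSV --design TSV --out DIR [--contrasts A:B,...]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- if (i + 1 <= length(args)) args[i + 1] else NA
    i <- i + 2
  }
  status <- tryCatch({
    switch(cmd,
      simulate = run_simulate(opt$spec, opt$out,
                              seed = if (!is.null(opt$seed))
                                as.integer(opt$seed)),
      quantify = run_quantify(opt$genome, opt$annotation, opt$manifest,
                              opt$out,
                              max_mismatches =
                                as.integer(opt$mismatches %||% "2"),
                              method = opt$method %||% "seeded"),
      diff = {
        ct <- if (!is.null(opt$contrasts))
          strsplit(strsplit(opt$contrasts, ",")[[1]], ":")
        run_diff(opt$counts, opt$design, contrasts = ct, out_dir = opt$out)
      },
      { message(usage); return(invisible(1L)) })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
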