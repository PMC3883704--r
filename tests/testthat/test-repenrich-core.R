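# Pseudo-genome construction, unique-overlap counting, 1/k assignment,
# aggregation, and the conservation audit.

test_that("pseudo-genome lengths and offsets follow the arithmetic", {
  genome <- c(c1 = random_dna_str(600))
  cat <- repeat_catalog(data.frame(
    contig = "c1", start = c(50L, 300L), end = c(150L, 450L),
    strand = c("+", "-"), subfamily = "S", family = "F", class = "K",
    stringsAsFactors = FALSE))
  pg <- build_pseudogenomes(genome, cat, spacer_length = 50L)
  # 100 + 150 instances + one 50 N spacer
  expect_equal(nchar(pg$seqs[["S"]]), 300)
  expect_equal(pg$offsets[["S"]]$offset, c(0L, 150L))
  # minus-strand instance enters as plus-strand genomic sequence
  expect_equal(substring(pg$seqs[["S"]], 151, 300),
               substring(genome[[1]], 301, 450))
  expect_equal(substring(pg$seqs[["S"]], 101, 150), strrep("N", 50))

  one <- repeat_catalog(cat[1, ])
  pg1 <- build_pseudogenomes(genome, one, 50L)
  expect_equal(pg1$seqs[["S"]], substring(genome[[1]], 51, 150))

  # config toggles: minus-strand reverse complement and genomic flanks
  pg_rc <- build_pseudogenomes(genome, cat, 50L, revcomp_minus = TRUE)
  expect_equal(substring(pg_rc$seqs[["S"]], 151, 300),
               rc_chr(substring(genome[[1]], 301, 450)))
  pg_fl <- build_pseudogenomes(genome, cat, 50L, flank = 10L)
  expect_equal(pg_fl$offsets[["S"]]$length, c(120L, 170L))
  expect_equal(substring(pg_fl$seqs[["S"]], 1, 120),
               substring(genome[[1]], 41, 160))

  bad <- cat
  bad$end[2] <- 1000L
  expect_error(build_pseudogenomes(genome, repeat_catalog(bad), 50L),
               "beyond contig")
})

test_that("error-free reads from planted instances align to their pseudo-genome", {
  gen <- build_genome(tiny_specs(), 3e4, seed = 19)
  pg <- build_pseudogenomes(gen$genome, gen$catalog, 50L)
  set.seed(19)
  for (s in unique(gen$catalog$subfamily)) {
    ins <- gen$catalog[gen$catalog$subfamily == s, ][1, ]
    for (k in 1:5) {
      st <- sample.int(ins$end - ins$start - 50 + 1, 1) - 1L
      rd <- substring(gen$genome[[ins$contig]], ins$start + st + 1,
                      ins$start + st + 50)
      h <- align_all(c(r = rd), pg$seqs[s], 2)
      expect_gt(nrow(h), 0)
    }
  }
})

test_that("unique-overlap counting applies the >=1 bp rule and tie-breaks", {
  genome <- c(c1 = random_dna_str(500))
  cat <- repeat_catalog(data.frame(
    contig = "c1", start = c(100L, 230L, 400L), end = c(200L, 300L, 450L),
    strand = "+", subfamily = c("AAA", "BBB", "CCC"),
    family = c("AAA", "BBB", "CCC"), class = rep("K", 3),
    stringsAsFactors = FALSE))
  hits <- data.frame(
    read_id = c("inside", "bg", "straddle", "edge"),
    target = "c1",
    pos = c(120L, 320L, 170L, 199L),
    strand = "+", stringsAsFactors = FALSE)
  # straddle: [170, 220) overlaps AAA by 30 bp, nothing else;
  # edge: [199, 249) overlaps AAA by 1 bp and BBB by 19 bp -> BBB
  res <- count_unique_overlaps(hits, 50L, cat)
  att <- setNames(res$attribution$subfamily, res$attribution$read_id)
  expect_equal(att[["inside"]], "AAA")
  expect_true(is.na(att[["bg"]]))
  expect_equal(att[["straddle"]], "AAA")
  expect_equal(att[["edge"]], "BBB")
  expect_equal(res$counts, c(AAA = 2, BBB = 1, CCC = 0))

  # true two-subfamily straddle with 30 vs 20 bp
  cat2 <- repeat_catalog(data.frame(
    contig = "c1", start = c(100L, 200L), end = c(200L, 260L), strand = "+",
    subfamily = c("S1", "S2"), family = c("S1", "S2"), class = "K",
    stringsAsFactors = FALSE))
  h2 <- data.frame(read_id = "r", target = "c1", pos = 170L, strand = "+",
                   stringsAsFactors = FALSE)
  r2 <- count_unique_overlaps(h2, 50L, cat2)
  expect_equal(r2$attribution$subfamily, "S1")
  # equal 25/25 overlap: lexicographic subfamily wins
  h3 <- data.frame(read_id = "r", target = "c1", pos = 175L, strand = "+",
                   stringsAsFactors = FALSE)
  r3 <- count_unique_overlaps(h3, 50L, cat2)
  expect_equal(r3$attribution$subfamily, "S1")
  cat3 <- cat2
  cat3$subfamily <- c("ZZ", "AA")
  cat3$family <- c("ZZ", "AA")
  r4 <- count_unique_overlaps(h3, 50L, repeat_catalog(cat3))
  expect_equal(r4$attribution$subfamily, "AA")
})

test_that("multi-map assignment implements the distinct-subfamily 1/k rule", {
  # four pseudo-genomes sharing a planted core, one with the core twice
  core <- random_dna_str(60)
  pg <- structure(list(
    seqs = c(P1 = paste0(random_dna_str(40), core, random_dna_str(40)),
             P2 = paste0(core, random_dna_str(30)),
             P3 = paste0(random_dna_str(25), core),
             P4 = paste0(core, strrep("N", 50), core),
             P5 = random_dna_str(120)),
    offsets = list(), spacer_length = 50L), class = "pseudo_genomes")
  read <- substring(core, 6, 55)

  r1 <- assign_multimap(c(m = read), structure(
    list(seqs = pg$seqs["P4"], offsets = list(), spacer_length = 50L),
    class = "pseudo_genomes"))
  # 2 hits inside one pseudo-genome still count once: weight 1.0
  expect_equal(r1$assignments$weight, 1.0)

  r4 <- assign_multimap(c(m = read), structure(
    list(seqs = pg$seqs[c("P1", "P2", "P3", "P4")], offsets = list(),
         spacer_length = 50L), class = "pseudo_genomes"))
  expect_equal(nrow(r4$assignments), 4)
  expect_equal(r4$assignments$weight, rep(0.25, 4))
  expect_equal(sum(r4$assignments$weight), 1)

  r0 <- assign_multimap(c(m = strrep("T", 50)), structure(
    list(seqs = pg$seqs["P5"], offsets = list(), spacer_length = 50L),
    class = "pseudo_genomes"))
  expect_equal(nrow(r0$assignments), 0)
  expect_equal(r0$unassigned, "m")
})

test_that("aggregation adds passes, rounds half-up once, zero-fills", {
  cat <- repeat_catalog(data.frame(
    contig = "c1", start = c(0L, 100L, 200L), end = c(50L, 150L, 260L),
    strand = "+", subfamily = c("A", "B", "C"),
    family = c("A", "B", "C"), class = "K", stringsAsFactors = FALSE))
  uc <- list(s1 = c(A = 10, B = 0, C = 0), s2 = c(A = 12, B = 1, C = 0))
  asg <- list(
    s1 = data.frame(read_id = c("r1", "r1", "r2", "r2", "r3"),
                    subfamily = c("A", "B", "A", "B", "A"),
                    weight = c(0.5, 0.5, 0.5, 0.5, 1.5),
                    stringsAsFactors = FALSE),
    s2 = data.frame(read_id = c("q1", "q2"), subfamily = c("A", "B"),
                    weight = c(0.4, 1), stringsAsFactors = FALSE))
  m <- aggregate_counts(uc, asg, cat, c(s1 = 100, s2 = 120))
  # unique 10 + fractional 2.5 -> 12.5, rounded half-up to 13
  expect_equal(m$fractional["A", "s1"], 12.5)
  expect_equal(m$rounded["A", "s1"], 13)
  # 12.4 rounds down
  expect_equal(m$fractional["A", "s2"], 12.4)
  expect_equal(m$rounded["A", "s2"], 12)
  expect_equal(m$fractional["C", "s1"], 0)
  expect_equal(m$rounded["B", "s1"], 1)
  expect_error(aggregate_counts(uc, asg[1], cat, c(s1 = 100, s2 = 120)),
               "sample sets differ")
})

test_that("count matrix TSV round-trips with library sizes", {
  cat <- repeat_catalog(data.frame(
    contig = "c1", start = c(0L, 100L), end = c(50L, 150L), strand = "+",
    subfamily = c("A", "B"), family = c("A", "B"), class = "K",
    stringsAsFactors = FALSE))
  uc <- list(s1 = c(A = 5, B = 2), s2 = c(A = 0, B = 7))
  asg <- list(s1 = data.frame(read_id = "r", subfamily = "A", weight = 0.5),
              s2 = data.frame(read_id = character(), subfamily = character(),
                              weight = numeric()))
  m <- aggregate_counts(uc, asg, cat, c(s1 = 50, s2 = 60))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts(m, f, "rounded")
  back <- read_counts(f)
  expect_equal(back$rounded, m$rounded)
  expect_equal(back$library_sizes, c(s1 = 50, s2 = 60))
})

test_that("per-sample accounting conserves every read and every weight", {
  gen <- build_genome(tiny_specs(), 3e4, seed = 23)
  des <- design_spec(groups = c("g1", "g2"), replicates = 2,
                     reads_per_sample = 1500L, seed = 23)
  pg <- build_pseudogenomes(gen$genome, gen$catalog, des$read_length)
  sim <- simulate_sample(gen$genome, gen$catalog, gen$truth, des, "g1", 1, 31)
  q <- quantify_sample(sim$reads, gen$genome, gen$catalog, pg)
  led <- q$ledger
  expect_equal(led[["total"]],
               led[["unique_overlap"]] + led[["unique_nonoverlap"]] +
               led[["multi_assigned"]] + led[["multi_unassigned"]] +
               led[["unmapped"]])
  # every assigned multi read's weights sum to exactly 1
  wsum <- tapply(q$assignments$weight, q$assignments$read_id, sum)
  expect_true(all(abs(wsum - 1) < 1e-12))
  # fractional total equals attributed unique + assigned multi reads
  m <- aggregate_counts(list(s = q$unique_counts), list(s = q$assignments),
                        gen$catalog, c(s = q$library_size))
  expect_equal(sum(m$fractional),
               led[["unique_overlap"]] + led[["multi_assigned"]])
})

test_that("adding reads from a subfamily never decreases its count", {
  gen <- build_genome(tiny_specs(), 3e4, seed = 29)
  des <- design_spec(groups = c("g1", "g2"), replicates = 2,
                     reads_per_sample = 600L, seed = 29)
  pg <- build_pseudogenomes(gen$genome, gen$catalog, des$read_length)
  sim <- simulate_sample(gen$genome, gen$catalog, gen$truth, des, "g1", 1, 37)
  q1 <- quantify_sample(sim$reads, gen$genome, gen$catalog, pg)
  # append 20 extra error-free reads from a SAT_Z instance
  ins <- gen$catalog[gen$catalog$subfamily == "SAT_Z", ][1, ]
  extra <- data.frame(
    id = paste0("extra", 1:20),
    seq = vapply(1:20, function(i) {
      st <- ins$start + i
      substring(gen$genome[[ins$contig]], st + 1, st + 50)
    }, ""),
    qual = strrep("I", 50), stringsAsFactors = FALSE)
  q2 <- quantify_sample(rbind(sim$reads, extra), gen$genome, gen$catalog, pg)
  tot1 <- q1$unique_counts[["SAT_Z"]] +
    sum(q1$assignments$weight[q1$assignments$subfamily == "SAT_Z"])
  tot2 <- q2$unique_counts[["SAT_Z"]] +
    sum(q2$assignments$weight[q2$assignments$subfamily == "SAT_Z"])
  expect_gte(tot2, tot1)
})
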