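---
title: "Repeat-subfamily enrichment: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat-subfamily enrichment: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repquant)
```

# The problem

Repetitive elements — LINEs, SINEs, LTR retrotransposons, satellites —
make up roughly half of a mammalian genome and are normally silenced by
heterochromatin. Their transcriptional derepression is of interest in
aging and disease, but quantifying it from RNA-seq is awkward: reads from
young, low-divergence repeat copies map to hundreds of near-identical loci
and are discarded or arbitrarily placed by standard gene-level pipelines.
`repquant` quantifies expression at the repeat *subfamily* level (the
RepeatMasker repeat name), keeping every mapping read, and tests for
differential enrichment between sample groups.

# The counting model

A sample's reads are partitioned by an exhaustive Hamming-distance
alignment against the genome (every position, both strands, up to `v`
mismatches; default `v = 2` for 50 nt reads, no indels):

* **unique** — exactly one hit on the best (minimum-mismatch) stratum;
* **multi** — two or more best-stratum hits;
* **unmapped** — no hit at all.

The *library size* of a sample is `unique + multi` — the total of
genome-mapping reads — and is supplied to normalization rather than
recomputed from the count matrix, because most mapping reads are genic and
never enter the repeat counts.

**Unique pass.** A unique read overlapping an annotated repeat instance by
at least 1 bp is counted once for that instance's subfamily. When a read
straddles instances of different subfamilies it is attributed to the
subfamily with the larger overlap; exact ties break by lexicographic
subfamily name. The annotation is used as given: overlapping or nested
annotations are not deduplicated, and the tie-break makes the outcome
deterministic either way. Strand is recorded but ignored — the library
preparation the pipeline is designed for is not strand-specific.

**Multi pass.** For every subfamily a *pseudo-genome* is built: its
genomic instances, in annotation order, concatenated with runs of `N`
whose length is at least the read length. `N` matches nothing (not even
another `N`), so no read can align across an instance junction. Each multi
read is aligned to every pseudo-genome with the same `v`; the number `k`
of *distinct* subfamilies hit (several hits inside one pseudo-genome count
once) sets its contribution: `1/k` to each subfamily hit. Reads hitting no
pseudo-genome stay in the library size but contribute no counts.

**Aggregation.** Per subfamily and sample, the unique count plus the sum
of fractional weights gives the *fractional* matrix; rounding half-up
(`floor(x + 0.5)`) — applied once, here — gives the *rounded* matrix used
by the statistical layer. A per-sample conservation ledger
(`unique-overlap + unique-non-overlap + multi-assigned + multi-unassigned
+ unmapped = total`) is verified on every run and failure aborts the
pipeline.

## Design choices left open by the method's description

* *Pseudo-genome orientation and flanks.* Whether minus-strand instances
  should be reverse-complemented, and whether instances should carry
  genomic flanks, is not fixed by the method. Defaults are plus-strand
  extraction and no flanks: the aligner is strand-agnostic, so orientation
  is immaterial, and flankless construction keeps the brute-force oracle
  semantics exact (a read either lies in an instance or it does not). Both
  are exposed as arguments (`revcomp_minus`, `flank`) of
  `build_pseudogenomes()`.
* *"Unique" alignment policy.* Defined on the best mismatch stratum — a
  read with one perfect hit and several 2-mismatch hits is unique. The
  alternative (unique-overall) is available via `best_stratum = FALSE`.
* *Spacer length.* Defaults to the read length, the smallest value that
  provably prevents junction artifacts.
* *Mismatch cap for the multi pass.* The same `v` as the genomic pass; no
  independent value is stated anywhere, and using one cap keeps the two
  passes comparable.

# The statistical layer

All statistics are implemented from formulas (the test suite cross-checks
TMM against edgeR and the Poisson limit against `stats::glm`, but the
package itself calls neither).

**TMM normalization.** The reference sample is the one whose
upper-quartile CPM is closest to the mean upper-quartile. For sample *s*
against reference *r*, over features nonzero in both,
`M = log2((y_s/N_s)/(y_r/N_r))` and `A = (1/2) log2((y_s/N_s)(y_r/N_r))`;
the most extreme 30 % of M and 5 % of A are trimmed two-sided and the
normalization factor is `2^(sum(M/w) / sum(1/w))` with the asymptotic
binomial variance `w = (N_s - y_s)/(N_s y_s) + (N_r - y_r)/(N_r y_r)`.
Factors are centred to geometric mean 1; effective library size =
library size × factor. The trim fractions and reference rule are the
published defaults of the method and are exposed as arguments.

**log2 CPM.** `log2((y + p)/(N_eff + 2p) * 1e6)` with prior count
`p = 0.5`; group summaries are arithmetic means of per-sample log2 CPM.

**Dispersion.** One common negative-binomial dispersion for the whole
matrix, maximizing the Cox–Reid adjusted profile likelihood
`sum_g [ loglik_g(phi) - 0.5 log det(X' W X) ]` over a log-spaced grid
(`1e-4` to `10`) refined by golden-section search; an optimum pinned at
the lower edge returns 0 (the Poisson boundary). With tens of subfamilies
a single dispersion is estimable and testable; trended or tagwise
shrinkage is deliberately out of scope. All-zero rows are dropped from
estimation.

**Testing.** Per subfamily, a group-means NB log-linear model with log
effective library sizes as offsets is fit by IRLS (tolerance `1e-8`, 100
iterations, linear predictor clamped to ±30 to keep empty groups finite).
A pairwise contrast A vs B is tested by the likelihood ratio against the
model merging A and B, with `p` from chi-square(1); `log2FC` is the
coefficient difference divided by `ln 2`. Non-converged fits are flagged,
get `p = NaN`, and are excluded from FDR. The LRT was chosen over Wald or
quasi-likelihood F because it has a clean 1-df chi-square null and an
exact independent oracle in the Poisson limit.

**FDR.** Storey q-values with fixed `lambda = 0.5`:
`pi0 = min(1, #{p > 0.5}/(m/2))`, `q(i) = min_{j >= i} pi0 * m * p(j)/j`,
capped at 1. The spline-smoothed pi0 estimator is intentionally not used:
with tens of features it is unstable, while the fixed-lambda estimator is
robust and exactly testable by hand. Note `pi0` can reach 0 when no
p-value exceeds 0.5; that is the estimator's literal behaviour and is kept.

# What the simulator emulates — and what it does not

`build_genome()` plants, for each subfamily spec, `n_instances`
independently substituted copies (per-base substitution probability =
`divergence`, no indels) of a random consensus at non-overlapping uniform
positions and random strands in i.i.d. background DNA.
`simulate_sample()` draws per-subfamily read counts and places reads
uniformly within uniformly chosen instances, on a fair-coin strand, with
i.i.d. substitution sequencing errors; background reads come from
non-repeat windows.

Count noise is gamma–Poisson: each subfamily's count is
`NB(mu = n(1-f) p_s, phi)` with `f` the background fraction and `p_s` the
group's expected repeat-read share, drawn *independently* per subfamily,
with the background pool absorbing the remainder so the sample total is
exact. (A first implementation perturbed a single multinomial; that
renormalization partially cancels the gamma fluctuation of any subfamily
holding a large share of the reads, deflating its variance well below
`mu + phi mu^2` — the independent-draw construction restores exact NB
marginals. When `f = 0` there is nothing to absorb the fluctuations and
the generator falls back to the gamma-perturbed multinomial.)

Defaults state the intended world: three groups ("5mo", "24mo", "36mo") ×
three replicates, single-end 50 nt reads, 20 000 reads per sample,
dispersion 0.1 (a typical bulk-RNA-seq biological-replicate value),
sequencing error 0.001, background fraction 0.5, a ~100 kb genome with
10–20 subfamilies of 3–10 instances each. The bundled landscape
(`example_subfamily_specs()`) spreads baseline weights log-wise across
LINE-, SINE-, LTR- and satellite-like subfamilies with divergences 0.02 to
0.15 — low-divergence satellites yield mostly multi-mapping reads, high-
divergence LINEs mostly unique ones — and derepresses two L1-like and two
satellite-like subfamilies four-fold in the oldest group only, mirroring
derepression concentrated at advanced age. No real per-subfamily abundance
distribution exists to copy; users calibrating to a tissue must supply
their own weights.

Not emulated: indels, paired ends, splicing, PCR duplicates,
position-dependent quality (qualities are flat Phred 40), GC or mappability
bias, and genuinely nested/overlapping annotations (instances are planted
disjoint; nesting is handled only through the counting tie-break). A green
simulation test therefore establishes algorithmic correctness and
statistical calibration under the stated model, not robustness to every
artifact of real libraries.

All randomness descends from one master seed through named substreams
(genome; one per sample), so studies are byte-reproducible.

Note on the truth tables: expected proportions are compositional. Raising
one subfamily's weight four-fold raises the denominator too, so the true
log2 fold change of its *proportion* is slightly below 2 and unchanged
subfamilies shift slightly negative; `simulation_truth()` records the
exact values.

# Numerical and degenerate-input policy

* Coordinates are 0-based half-open internally everywhere; conversion
  happens only at format boundaries (RepeatMasker `.out` is 1-based
  inclusive; BED passes through).
* `N` counts as a mismatch at any position, in read or reference.
* The seeded aligner (pigeonhole over `v + 1` read segments, 2-bit-encoded
  seed index) is contractually identical to exhaustive enumeration; the
  naive double-loop scanner ships alongside as `method = "naive"` and the
  suite enforces equivalence on fuzz cases.
* Reads matching both strands at one locus yield two hits, hence "multi".
* A sample with all reads unmapped has library size 0 and is refused by
  normalization, with the sample named.
* Ties in unique-overlap attribution and the TMM reference choice are
  resolved deterministically (lexicographic name; first minimizer), so
  whole-pipeline runs are exactly reproducible.
* Rounding is half-up (`floor(x + 0.5)`), applied once at the matrix
  stage; every internal tally is exact.

# Known limitations

* Hamming-only alignment (no indels) is faithful to short 50 nt reads but
  undercounts reads from indel-diverged copies.
* Locus-level (per-instance) quantification is out of scope; counts are
  per subfamily only, and family/class summaries are plain row sums.
* The common-dispersion NB model ignores subfamily-specific dispersion;
  with very many subfamilies a tagwise approach would gain power.
* The q-value implementation is the fixed-lambda estimator; results can
  differ from spline-smoothed implementations, mainly through `pi0`.
* The exhaustive aligner is built for toy-to-moderate scales (hundreds of
  kb of reference); aligning against a full mammalian genome requires an
  external aligner, whose output enters through the SAM route.
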