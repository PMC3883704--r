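# TMM, log2 CPM, common dispersion, NB GLM LRT, Storey q-values.

toy_counts <- function() {
  m <- cbind(s1 = c(100, 200, 300, 400, 500, 1000),
             s2 = c(80, 210, 700, 380, 520, 900))
  rownames(m) <- paste0("f", 1:6)
  m
}
toy_lib <- c(s1 = 5000, s2 = 5500)

test_that("identical compositions give unit TMM factors", {
  m <- toy_counts()
  same <- cbind(s1 = m[, 1], s2 = m[, 1])
  r <- tmm_factors(same, c(s1 = 5000, s2 = 5000))
  expect_equal(unname(r$factors), c(1, 1))
  # doubled counts with doubled library size: identical proportions
  dbl <- cbind(s1 = m[, 1], s2 = 2 * m[, 1])
  r2 <- tmm_factors(dbl, c(s1 = 5000, s2 = 10000))
  expect_equal(unname(r2$factors), c(1, 1))
  expect_equal(prod(r2$factors), 1)
})

test_that("TMM matches a hand-computed trimmed weighted mean to 1e-10", {
  m <- toy_counts()
  r <- tmm_factors(m, toy_lib)

  # -- independent spreadsheet-style computation ------------------------
  # reference: upper-quartile CPM closest to the mean upper-quartile
  uq <- c(quantile(m[, 1], 0.75) / toy_lib[1],
          quantile(m[, 2], 0.75) / toy_lib[2]) * 1e6
  ref <- which.min(abs(uq - mean(uq)))
  oth <- 3 - ref
  p_o <- m[, oth] / toy_lib[oth]
  p_r <- m[, ref] / toy_lib[ref]
  M <- log2(p_o / p_r)
  A <- 0.5 * log2(p_o * p_r)
  w <- (toy_lib[oth] - m[, oth]) / (toy_lib[oth] * m[, oth]) +
       (toy_lib[ref] - m[, ref]) / (toy_lib[ref] * m[, ref])
  # two-sided trim: drop the floor(6*.3) = 1 lowest and highest M;
  # floor(6*.05) = 0 dropped on A
  keepM <- order(M)[2:5]
  keepA <- order(A)[1:6]
  keep <- intersect(keepM, keepA)
  f_oth <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  fa <- c(1, f_oth); if (oth == 1) fa <- c(f_oth, 1)
  fa <- fa / exp(mean(log(fa)))
  # ---------------------------------------------------------------------
  expect_equal(unname(r$factors), unname(fa), tolerance = 1e-10)
  expect_equal(exp(mean(log(r$factors))), 1, tolerance = 1e-12)
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(41)
  m <- matrix(rnbinom(8 * 40, mu = 150, size = 5), nrow = 40,
              dimnames = list(paste0("f", 1:40), paste0("s", 1:8)))
  m[3, 2] <- 0  # a zero to exercise the both-nonzero filter
  lib <- setNames(round(runif(8, 8e3, 1.2e4)), colnames(m))
  ours <- tmm_factors(m, lib)$factors
  theirs <- edgeR::calcNormFactors(m, lib.size = lib, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
})

test_that("TMM on permuted sample order gives permuted factors", {
  set.seed(43)
  m <- matrix(rnbinom(6 * 30, mu = 100, size = 8), nrow = 30,
              dimnames = list(NULL, paste0("s", 1:6)))
  lib <- setNames(rep(6e3, 6), colnames(m))
  f1 <- tmm_factors(m, lib)$factors
  perm <- c(4, 2, 6, 1, 3, 5)
  f2 <- tmm_factors(m[, perm], lib[perm])$factors
  expect_equal(f2, f1[perm])
})

test_that("log2 CPM follows the plug-in formula and group means recompute", {
  m <- matrix(c(0, 10, 400, 3, 7, 801), nrow = 3,
              dimnames = list(paste0("f", 1:3), c("a", "b")))
  lib <- c(a = 1e6, b = 2e6)
  cpm <- log2_cpm(m, lib, prior = 0.5)
  expect_equal(cpm["f1", "a"], log2(0.5 / (1e6 + 1) * 1e6))
  expect_equal(cpm["f3", "a"], log2(400.5 / (1e6 + 1) * 1e6))
  # doubling a large count adds ~1
  m2 <- m; m2["f3", "a"] <- 800
  expect_equal(log2_cpm(m2, lib)["f3", "a"] - cpm["f3", "a"], 1,
               tolerance = 2e-3)

  set.seed(47)
  big <- matrix(rpois(5 * 6, 50), nrow = 5,
                dimnames = list(NULL, paste0("s", 1:6)))
  lib6 <- setNames(rep(5e3, 6), colnames(big))
  grp <- rep(c("x", "y"), each = 3)
  gm <- group_mean_log2_cpm(log2_cpm(big, lib6), grp)
  # independent recomputation, feature by feature
  for (i in 1:5) {
    want <- mean(log2((big[i, 1:3] + 0.5) / (lib6[1:3] + 1) * 1e6))
    expect_equal(unname(gm[i, "x"]), unname(want))
  }
})

test_that("common dispersion recovers Poisson and NB truths", {
  grp <- rep(c("a", "b"), each = 3)
  est_pois <- numeric(10); est_nb <- numeric(10)
  for (s in 1:10) {
    set.seed(500 + s)
    mu <- matrix(rep(exp(runif(20, log(50), log(500))), 6), nrow = 20)
    yp <- matrix(rpois(120, mu), nrow = 20,
                 dimnames = list(NULL, paste0("s", 1:6)))
    yn <- matrix(rnbinom(120, mu = mu, size = 10), nrow = 20,
                 dimnames = list(NULL, paste0("s", 1:6)))
    est_pois[s] <- estimate_dispersion(yp, grp, offset = rep(0, 6))
    est_nb[s] <- estimate_dispersion(yn, grp, offset = rep(0, 6))
  }
  expect_lt(median(est_pois), 0.01)
  expect_gt(median(est_nb), 0.05)
  expect_lt(median(est_nb), 0.2)
})

test_that("identical replicate columns with large counts hit the lower boundary", {
  y <- matrix(rep(c(1000, 2000, 4000, 800), 6), nrow = 4,
              dimnames = list(NULL, paste0("s", 1:6)))
  phi <- estimate_dispersion(y, rep(c("a", "b"), each = 3),
                             offset = rep(0, 6))
  expect_lt(phi, 1e-3)
  expect_error(estimate_dispersion(y[, c(1, 4), drop = FALSE],
                                   c("a", "b"), offset = rep(0, 2)),
               "replication")
})

test_that("dispersion-zero LRT equals the Poisson deviance difference", {
  set.seed(59)
  grp <- rep(c("g1", "g2", "g3"), each = 2)
  lib <- setNames(round(runif(6, 4e3, 6e3)), paste0("s", 1:6))
  y <- matrix(rnbinom(10 * 6, mu = 80, size = 8), nrow = 10,
              dimnames = list(paste0("f", 1:10), names(lib)))
  res <- fit_and_test(y, grp, lib, dispersion = 0, contrast = c("g3", "g1"))
  for (i in 1:10) {
    yi <- y[i, ]
    gf <- factor(grp)
    gr <- factor(ifelse(grp %in% c("g1", "g3"), "m", grp))
    full <- glm(yi ~ 0 + gf, family = poisson(), offset = log(lib))
    red <- glm(yi ~ 0 + gr, family = poisson(), offset = log(lib))
    stat <- red$deviance - full$deviance
    ours <- qchisq(res$PValue[i], df = 1, lower.tail = FALSE)
    expect_equal(ours, stat, tolerance = 1e-6)
  }
})

test_that("null data yield near-zero logFC and roughly uniform p", {
  grp <- rep(c("a", "b"), each = 3)
  lib <- setNames(rep(1e4, 6), paste0("s", 1:6))
  ps <- c(); fcs <- c()
  for (s in 1:25) {
    set.seed(700 + s)
    y <- matrix(rnbinom(20 * 6, mu = 200, size = 10), nrow = 20,
                dimnames = list(paste0("f", 1:20), names(lib)))
    r <- fit_and_test(y, grp, lib, dispersion = 0.1, contrast = c("b", "a"))
    ps <- c(ps, r$PValue)
    fcs <- c(fcs, r$logFC)
  }
  expect_lt(abs(mean(fcs)), 0.1)
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_lt(mean(ps < 0.05, na.rm = TRUE), 0.12)
})

test_that("a true log2FC of 2 is recovered within +/- 0.5", {
  grp <- rep(c("young", "old"), each = 3)
  lib <- setNames(rep(1e4, 6), paste0("s", 1:6))
  # at dispersion 0.05 the sampling sd of logFC at n = 3 vs 3 is ~0.27
  # log2 units, so +/- 0.5 captures ~94% of estimates
  ok <- logical(50)
  for (s in 1:50) {
    set.seed(900 + s)
    mu <- c(rep(500, 3), rep(2000, 3))
    y <- matrix(rnbinom(6, mu = mu, size = 20), nrow = 1,
                dimnames = list("f", names(lib)))
    # pad with null features so normalization has something to chew on
    pad <- matrix(rnbinom(19 * 6, mu = 300, size = 20), nrow = 19,
                  dimnames = list(paste0("p", 1:19), names(lib)))
    r <- fit_and_test(rbind(y, pad), grp, lib, dispersion = 0.05,
                      contrast = c("old", "young"))
    ok[s] <- abs(r$logFC[1] - 2) < 0.5
  }
  expect_gte(mean(ok), 0.9)
})

test_that("Storey q-values match the hand-worked oracle at lambda = 0.5", {
  p <- c(0.001, 0.01, 0.02, 0.5, 0.8, 0.9)
  # by hand: #{p > 0.5} = 2, pi0 = 2 / (6 * 0.5) = 2/3; pi0*m = 4;
  # raw q = 4p/j = .004, .02, .0266.., .5, .64, .6; right-to-left cummin
  expect_equal(storey_qvalues(p),
               c(0.004, 0.02, 0.08 / 3, 0.5, 0.6, 0.6))
  expect_equal(storey_qvalues(1), 1)
  # all p equal: q = pi0 * p
  expect_equal(storey_qvalues(rep(0.7, 4)), rep(0.7, 4))
  expect_equal(storey_qvalues(rep(0.2, 5)), rep(0, 5))
})

test_that("q-values are monotone in p and invariant to NaN rows", {
  set.seed(61)
  for (k in 1:10) {
    p <- runif(sample(5:40, 1))
    q <- storey_qvalues(p)
    o <- order(p)
    expect_true(all(diff(q[o]) > -1e-12))
    expect_true(all(q >= 0 & q <= 1))
    withnan <- c(p, NaN, NA)
    q2 <- storey_qvalues(withnan)
    expect_equal(q2[seq_along(p)], q)
    expect_true(all(is.na(q2[length(p) + 1:2])))
  }
})
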