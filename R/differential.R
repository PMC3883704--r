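# Differential enrichment statistics, implemented from formulas.
#
# TMM between-sample normalization with user-supplied library sizes,
# log2 counts-per-million, a common negative-binomial dispersion estimated
# by Cox-Reid adjusted profile likelihood, per-feature NB log-linear fits
# with library-size offsets, likelihood-ratio tests of pairwise group
# contrasts, and Storey q-values with fixed lambda = 0.5.

#' TMM normalization factors
#'
#' Trimmed mean of M-values: the reference sample is the one whose
#' upper-quartile CPM is closest to the mean upper-quartile. For each other
#' sample, M (log2 ratio of proportions) and A (average log2 abundance) are
#' computed over features nonzero in both sample and reference; the most
#' extreme 30 percent of M and 5 percent of A are trimmed two-sided, and the
#' factor is 2 to the precision-weighted mean of the retained M values
#' (weights are inverse asymptotic binomial variances). Factors are centred
#' so their geometric mean is 1.
#'
#' @param counts subfamily x sample count matrix (rounded stage).
#' @param library_sizes named per-sample library sizes (total mapping
#'   reads, supplied - not column sums).
#' @param trim_m,trim_a two-sided trim fractions for M and A.
#' @return list with `factors` (named, geometric mean 1) and
#'   `effective_library_sizes` (library size times factor).
#' @export
tmm_factors <- function(counts, library_sizes, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  samples <- colnames(counts)
  lib <- library_sizes[samples]
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("sample with all-zero counts: ", paste(samples[zero], collapse = ", "))
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  uq <- vapply(seq_along(samples),
               function(j) quantile(counts[, j], 0.75) / lib[j] * 1e6, 0)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_along(samples), function(j) {
    if (j == ref) return(1)
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- samples
  list(factors = f, effective_library_sizes = lib * f)
}

# one sample against the reference; the published TMM recipe
tmm_pair <- function(obs, ref, nobs, nref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  m <- log2((obs / nobs) / (ref / nref))
  a <- 0.5 * log2((obs / nobs) * (ref / nref))
  v <- (nobs - obs) / (nobs * obs) + (nref - ref) / (nref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (!length(m) || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm <- rank(m); ra <- rank(a)
  keep <- rm >= lo_m & rm <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
}

#' log2 counts per million
#'
#' `log2((count + prior) / (effective library size + 2 * prior) * 1e6)`.
#'
#' @param counts count matrix.
#' @param effective_library_sizes per-sample effective (TMM-scaled) library
#'   sizes.
#' @param prior prior count guarding zeros (default 0.5).
#' @return matrix of log2 CPM values.
#' @export
log2_cpm <- function(counts, effective_library_sizes, prior = 0.5) {
  counts <- as.matrix(counts)
  lib <- effective_library_sizes[colnames(counts)]
  if (any(lib <= 0)) stop("effective library sizes must be positive")
  log2(sweep(counts + prior, 2, lib + 2 * prior, "/") * 1e6)
}

#' Per-group mean log2 CPM
#'
#' @param cpm matrix from [log2_cpm()].
#' @param groups factor/character of group per sample (matched to columns).
#' @return feature x group matrix of arithmetic means.
#' @export
group_mean_log2_cpm <- function(cpm, groups) {
  groups <- as.character(groups)
  gs <- unique(groups)
  out <- vapply(gs, function(g)
    rowMeans(cpm[, groups == g, drop = FALSE]), numeric(nrow(cpm)))
  colnames(out) <- gs
  out
}

# ---- NB GLM internals -------------------------------------------------

# group-means design matrix (robust to a single level, unlike model.matrix)
group_design <- function(g) {
  lv <- sort(unique(as.character(g)))
  X <- vapply(lv, function(l) as.numeric(g == l), numeric(length(g)))
  if (is.null(dim(X))) X <- matrix(X, nrow = length(g))
  colnames(X) <- lv
  X
}

# NB (or Poisson when phi = 0) log-linear IRLS fit with offsets.
nb_irls <- function(y, X, offset, phi, tol = 1e-8, maxit = 100L) {
  mu <- pmax(y, 1 / 6)
  eta <- log(mu)
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    sw <- sqrt(w)
    fit <- tryCatch(qr.coef(qr(X * sw), z * sw), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit)) {
      fit0 <- if (is.null(fit)) rep(NA_real_, ncol(X)) else fit
      fit0[is.na(fit0)] <- -30
      fit <- fit0
    }
    fit <- pmin(pmax(fit, -30), 30)
    delta <- max(abs(fit - beta))
    beta <- fit
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    if (delta < tol) { converged <- TRUE; break }
  }
  mu <- pmax(exp(eta), 1e-10)
  list(beta = beta, mu = mu, converged = converged,
       deviance = nb_deviance(y, mu, phi),
       loglik = nb_loglik(y, mu, phi))
}

nb_deviance <- function(y, mu, phi) {
  yl <- ifelse(y > 0, y * log(y / mu), 0)
  if (phi == 0) return(2 * sum(yl - (y - mu)))
  2 * sum(yl - (y + 1 / phi) * log((y + 1 / phi) / (mu + 1 / phi)))
}

nb_loglik <- function(y, mu, phi) {
  if (phi == 0) return(sum(dpois(y, mu, log = TRUE)))
  sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

#' Estimate a common NB dispersion by Cox-Reid adjusted profile likelihood
#'
#' Maximizes, over a log-spaced dispersion grid refined by golden-section
#' search, the sum over features of the NB log-likelihood at the IRLS fit
#' minus the Cox-Reid adjustment `0.5 * log det(X' W X)`. Returns 0 when
#' the optimum sits at the Poisson boundary.
#'
#' @param counts feature x sample count matrix.
#' @param groups group per sample.
#' @param offset per-sample log effective library sizes (default: log of
#'   column sums).
#' @return scalar dispersion (>= 0).
#' @export
estimate_dispersion <- function(counts, groups,
                                offset = log(colSums(counts))) {
  counts <- as.matrix(counts)
  groups <- factor(groups)
  if (!any(table(groups) >= 2))
    stop("dispersion is inestimable without replication in any group")
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  X <- group_design(groups)
  apl <- function(log10phi) {
    phi <- 10^log10phi
    tot <- 0
    for (i in seq_len(nrow(counts))) {
      fit <- nb_irls(counts[i, ], X, offset, phi)
      w <- fit$mu / (1 + phi * fit$mu)
      d <- crossprod(X * sqrt(w))
      ld <- determinant(d, logarithm = TRUE)$modulus
      tot <- tot + fit$loglik - 0.5 * as.numeric(ld)
    }
    tot
  }
  grid <- seq(-4, 1, by = 0.5)
  vals <- vapply(grid, apl, 0)
  b <- which.max(vals)
  lo <- grid[max(1, b - 1)]; hi <- grid[min(length(grid), b + 1)]
  opt <- optimize(apl, c(lo, hi), maximum = TRUE, tol = 1e-3)
  phi <- 10^opt$maximum
  # Poisson boundary: profile still rising toward phi -> 0
  if (b == 1 && opt$maximum <= grid[1] + 0.05) return(0)
  phi
}

#' Fit NB GLMs and test one pairwise contrast
#'
#' Per feature, a negative-binomial log-linear model with group-means
#' parameterization and log effective-library-size offsets is fit by IRLS
#' (tolerance 1e-8, at most 100 iterations); the contrast is tested by a
#' likelihood-ratio test against the fit constraining the two contrast
#' groups equal, with the p-value from a 1-df chi-square. log2FC is the
#' coefficient difference divided by ln 2. Non-converged features are
#' flagged, given p = NaN, and excluded from FDR correction.
#'
#' @param counts feature x sample matrix (rounded stage).
#' @param groups group per sample (matched to columns).
#' @param effective_library_sizes named per-sample effective library sizes.
#' @param dispersion common NB dispersion (0 for Poisson).
#' @param contrast character pair `c(A, B)` tested as A versus B
#'   (log2FC > 0 means higher in A).
#' @param prior prior count for the reported group-mean log2 CPM columns.
#' @return data.frame: feature, logFC, one `logCPM.<group>` column per
#'   group, PValue, qvalue, converged.
#' @export
fit_and_test <- function(counts, groups, effective_library_sizes, dispersion,
                         contrast, prior = 0.5) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  if (!all(contrast %in% groups))
    stop("contrast groups not in design: ",
         paste(setdiff(contrast, groups), collapse = ", "))
  lib <- effective_library_sizes[colnames(counts)]
  offset <- log(lib)
  X_full <- group_design(groups)
  X_red <- group_design(ifelse(groups %in% contrast, ".merged", groups))

  nfeat <- nrow(counts)
  logFC <- numeric(nfeat); pval <- numeric(nfeat); conv <- logical(nfeat)
  for (i in seq_len(nfeat)) {
    y <- counts[i, ]
    full <- nb_irls(y, X_full, offset, dispersion)
    red <- nb_irls(y, X_red, offset, dispersion)
    conv[i] <- full$converged && red$converged
    logFC[i] <- (full$beta[match(contrast[1], colnames(X_full))] -
                 full$beta[match(contrast[2], colnames(X_full))]) / log(2)
    lrt <- max(0, 2 * (full$loglik - red$loglik))
    pval[i] <- if (conv[i]) pchisq(lrt, df = 1, lower.tail = FALSE) else NaN
  }
  cpm <- log2_cpm(counts, lib, prior)
  gm <- group_mean_log2_cpm(cpm, groups)
  out <- data.frame(feature = rownames(counts) %||% as.character(seq_len(nfeat)),
                    logFC = logFC, stringsAsFactors = FALSE)
  for (g in colnames(gm)) out[[paste0("logCPM.", g)]] <- gm[, g]
  out$PValue <- pval
  out$qvalue <- storey_qvalues(pval)
  out$converged <- conv
  out
}

#' Storey q-values with fixed lambda = 0.5
#'
#' `pi0 = min(1, #\{p > 0.5\} / (m / 2))`; for p sorted ascending,
#' `q(i) = min over j >= i of pi0 * m * p(j) / j`, capped at 1. NaN/NA
#' p-values are excluded and returned as NA.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA/NaN allowed).
#' @param lambda tuning constant of the pi0 estimator.
#' @return q-values in the original order.
#' @export
storey_qvalues <- function(p, lambda = 0.5) {
  out <- rep(NA_real_, length(p))
  ok <- which(is.finite(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must be in [0, 1]")
  m <- length(pv)
  pi0 <- min(1, sum(pv > lambda) / (m * (1 - lambda)))
  o <- order(pv)
  q <- pi0 * m * pv[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out[ok[o]] <- q
  out
}
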