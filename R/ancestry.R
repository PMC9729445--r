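# Per-individual ancestry: parental allele frequencies, ML hybrid index,
# K = 2 EM admixture, verification PCA, diagnostic loci, interspecific
# heterozygosity, and pure/hybrid classification.
#
# Orientation convention: q is the proportion of species-1 (black-capped)
# ancestry everywhere in this package; a Carolina-referenced hybrid index is
# 1 - q at reporting time.

#' Parental allele frequencies from reference panels
#'
#' Smoothed frequency of the counted allele in each parental panel:
#' `(allele count + pseudocount) / (2 n_nonmissing + 2 pseudocount)`. Raw
#' counts are retained so diagnostic (fixed-difference) loci can be judged on
#' unsmoothed data.
#'
#' @param gm a [genotype_matrix()].
#' @param panel0,panel1 individual ids of the species-0 (Carolina) and
#'   species-1 (black-capped) panels; disjoint, non-empty.
#' @param pseudocount Laplace smoothing constant (default 0.5); with a
#'   positive pseudocount frequencies are strictly inside (0, 1).
#' @return object of class `parental_freqs`: data frame with per-locus
#'   `p0`, `p1` (smoothed), `p0_raw`, `p1_raw`, allele-copy counts `n0`,
#'   `n1`, and `defined` (both panels had data).
#' @export
parental_allele_frequencies <- function(gm, panel0, panel1,
                                        pseudocount = 0.5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!length(panel0) || !length(panel1)) stop("empty reference panel")
  if (length(intersect(panel0, panel1))) stop("panels must be disjoint")
  missing_ids <- setdiff(c(panel0, panel1), gm$individuals)
  if (length(missing_ids))
    stop("panel individuals not in genotype matrix: ",
         paste(missing_ids, collapse = ", "))
  one <- function(ids) {
    v <- gm$values[ids, , drop = FALSE]
    cnt <- colSums(v, na.rm = TRUE)
    n <- 2 * colSums(!is.na(v))
    list(raw = ifelse(n > 0, cnt / n, NA_real_),
         sm = (cnt + pseudocount) / (n + 2 * pseudocount),
         n = n)
  }
  f0 <- one(panel0); f1 <- one(panel1)
  und <- f0$n == 0 | f1$n == 0
  if (any(und))
    warning(sum(und), " locus/loci with no non-missing calls in a panel; ",
            "frequencies flagged undefined")
  out <- data.frame(locus = seq_len(ncol(gm$values)),
                    p0 = ifelse(f0$n > 0, f0$sm, NA_real_),
                    p1 = ifelse(f1$n > 0, f1$sm, NA_real_),
                    p0_raw = f0$raw, p1_raw = f1$raw,
                    n0 = f0$n, n1 = f1$n, defined = !und)
  class(out) <- c("parental_freqs", "data.frame")
  out
}

# binomial log-likelihood of genotypes g at loci with per-locus success
# probability pi(h) = h p1 + (1 - h) p0; NA genotypes contribute 0
.hindex_loglik <- function(h, g, p0, p1) {
  pi <- h * p1 + (1 - h) * p0
  pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)
  sum(g * log(pi) + (2 - g) * log(1 - pi) +
        log(ifelse(g == 1L, 2, 1)))
}

#' Maximum-likelihood hybrid index
#'
#' Per individual, maximises over `h` in `[0, 1]` the binomial log-likelihood
#' of its genotypes given the smoothed parental frequencies, with profile
#' likelihood 95% intervals (drop of 1.92 log-likelihood units, the
#' asymptotic chi-square(1) cutoff).
#'
#' The likelihood is concave in `h`; the optimum is located from a coarse
#' grid of starting points refined by bounded 1-D optimisation.
#'
#' @param gm a [genotype_matrix()].
#' @param freqs a [parental_allele_frequencies()] result.
#' @return data frame (class `ancestry_estimate`): `individual`, `q`, `lo`,
#'   `hi`, `method`, `n_loci_used`, `degenerate` (flat likelihood).
#' @export
hybrid_index_ml <- function(gm, freqs) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(freqs, "parental_freqs"))
  use <- freqs$defined & is.finite(freqs$p0) & is.finite(freqs$p1)
  if (!any(use)) stop("no loci with defined parental frequencies")
  p0 <- freqs$p0[use]; p1 <- freqs$p1[use]
  V <- gm$values[, use, drop = FALSE]
  grid <- seq(0, 1, by = 0.05)
  res <- lapply(seq_len(nrow(V)), function(i) {
    g <- V[i, ]
    ok <- !is.na(g)
    if (!any(ok))
      return(data.frame(individual = gm$individuals[i], q = NA_real_,
                        lo = NA_real_, hi = NA_real_,
                        method = "hybrid_index_ml", n_loci_used = 0L,
                        degenerate = TRUE))
    gi <- g[ok]; a0 <- p0[ok]; a1 <- p1[ok]
    ll <- function(h) .hindex_loglik(h, gi, a0, a1)
    gv <- vapply(grid, ll, 0)
    if (diff(range(gv)) < 1e-9) {
      # p0 = p1 everywhere used: likelihood carries no ancestry information
      return(data.frame(individual = gm$individuals[i], q = 0.5, lo = 0,
                        hi = 1, method = "hybrid_index_ml",
                        n_loci_used = sum(ok), degenerate = TRUE))
    }
    j <- which.max(gv)
    lo_b <- grid[max(1, j - 1)]; hi_b <- grid[min(length(grid), j + 1)]
    opt <- optimize(ll, c(lo_b, hi_b), maximum = TRUE, tol = 1e-9)
    q <- opt$maximum; llmax <- opt$objective
    for (h_end in c(0, 1)) { # the optimum may sit on the boundary
      if (ll(h_end) > llmax) { q <- h_end; llmax <- ll(h_end) }
    }
    drop_fun <- function(h) ll(h) - (llmax - 1.92)
    lo <- if (drop_fun(0) >= 0) 0 else
      stats::uniroot(drop_fun, c(0, q), tol = 1e-8)$root
    hi <- if (drop_fun(1) >= 0) 1 else
      stats::uniroot(drop_fun, c(q, 1), tol = 1e-8)$root
    data.frame(individual = gm$individuals[i], q = q, lo = lo, hi = hi,
               method = "hybrid_index_ml", n_loci_used = sum(ok),
               degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("ancestry_estimate", "data.frame")
  out
}

# Exact per-individual maximiser of the concave admixture likelihood in q,
# vectorised over individuals: bisection on the score
# d/dq sum log Binom(g | 2, q f1 + (1-q) f0). Boundary optima are detected
# from the score sign at 0 and 1.
.qstep_exact <- function(V, obs, f0, f1, iters = 45) {
  n <- nrow(V)
  df <- matrix(f1 - f0, n, length(f0), byrow = TRUE)
  score <- function(q) {
    P <- outer(q, f1) + outer(1 - q, f0)
    S <- (V - 2 * P) * df / (P * (1 - P))
    S[!obs] <- 0
    rowSums(S)
  }
  lo <- rep(0 + 1e-12, n); hi <- rep(1 - 1e-12, n)
  s_lo <- score(lo); s_hi <- score(hi)
  q <- rep(0.5, n)
  at_lo <- s_lo <= 0       # decreasing from the start: maximum at 0
  at_hi <- s_hi >= 0       # still increasing at 1: maximum at 1
  interior <- !(at_lo | at_hi)
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    s <- score(mid)
    up <- s > 0
    lo[interior & up] <- mid[interior & up]
    hi[interior & !up] <- mid[interior & !up]
  }
  q[interior] <- (lo + hi)[interior] / 2
  q[at_lo] <- 0
  q[at_hi] <- 1
  no_data <- rowSums(obs) == 0
  q[no_data] <- NA_real_
  q
}

# full-data log-likelihood of the K = 2 admixture model
.adm_loglik <- function(V, q, f0, f1) {
  pi <- outer(q, f1) + outer(1 - q, f0)
  pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)
  sum((V * log(pi) + (2 - V) * log(1 - pi))[!is.na(V)])
}

#' K = 2 EM admixture estimation
#'
#' Maximum-likelihood admixture proportions without reference panels:
#' alternates (i) exact per-individual bounded 1-D maximisation of `q` given
#' the component allele frequencies and (ii) an EM re-estimation of the two
#' component frequency vectors given `q`. Both steps are ascent steps, so the
#' log-likelihood is non-decreasing; this is asserted each iteration.
#'
#' Label switching is resolved after fitting: with `anchors`, `q` is oriented
#' so the species-1 anchor panel has mean `q > 0.5`; without anchors, so the
#' individual with the highest PC1 score has `q > 0.5`.
#'
#' @param gm a [genotype_matrix()].
#' @param seed integer seed for the multi-start initialisations.
#' @param tol stop when the log-likelihood gain falls below `tol`.
#' @param max_iter iteration cap (a warning flag is set if reached).
#' @param anchors optional `list(panel0 = ids, panel1 = ids)` used only for
#'   orientation.
#' @param n_starts random initialisations; the best final likelihood is kept.
#' @return list with `estimates` (data frame `individual`, `q`, `method`),
#'   `f0`, `f1`, `loglik`, `n_iter`, `converged`.
#' @export
admixture_em <- function(gm, seed = 1, tol = 1e-6, max_iter = 2000,
                         anchors = NULL, n_starts = 5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  V <- gm$values
  if (nrow(V) < 2 || ncol(V) < 2) stop("need >= 2 individuals and >= 2 loci")
  n <- nrow(V); L <- ncol(V)
  obs <- !is.na(V)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    q <- runif(n, 0.05, 0.95)
    # frequency init: q-weighted allele proportions
    W1 <- matrix(q, n, L); W0 <- 1 - W1
    W1[!obs] <- 0; W0[!obs] <- 0
    Vz <- V; Vz[!obs] <- 0L
    f1 <- (colSums(W1 * Vz) + 0.5) / (2 * colSums(W1) + 1)
    f0 <- (colSums(W0 * Vz) + 0.5) / (2 * colSums(W0) + 1)
    ll_prev <- -Inf; it <- 0; converged <- FALSE
    repeat {
      it <- it + 1
      # (i) q-step: exact maximiser of the concave 1-D likelihood
      q <- .qstep_exact(V, obs, f0, f1)
      qc <- pmin(pmax(q, 1e-9), 1 - 1e-9)
      # (ii) EM step for f0, f1: expected origin of each allele copy
      QF1 <- outer(qc, f1); QF0 <- outer(1 - qc, f0)
      A <- QF1 / (QF1 + QF0)                       # counted-allele copies
      QN1 <- outer(qc, 1 - f1); QN0 <- outer(1 - qc, 1 - f0)
      B <- QN1 / (QN1 + QN0)                       # other-allele copies
      A[!obs] <- 0; B[!obs] <- 0
      num1 <- colSums(Vz * A); den1 <- num1 + colSums((2 - Vz) * B * obs)
      num0 <- colSums(Vz * (1 - A) * obs)
      den0 <- num0 + colSums((2 - Vz) * (1 - B) * obs)
      f1 <- pmin(pmax(ifelse(den1 > 0, num1 / den1, f1), 1e-6), 1 - 1e-6)
      f0 <- pmin(pmax(ifelse(den0 > 0, num0 / den0, f0), 1e-6), 1 - 1e-6)
      ll <- .adm_loglik(V, qc, f0, f1)
      if (ll < ll_prev - 1e-6)
        warning("admixture_em: log-likelihood decreased by ",
                format(ll_prev - ll), " at iteration ", it)
      if (is.finite(ll_prev) && ll - ll_prev < tol) { converged <- TRUE; break }
      if (it >= max_iter) break
      ll_prev <- ll
    }
    if (is.null(best) || ll > best$loglik)
      best <- list(q = q, f0 = f0, f1 = f1, loglik = ll, n_iter = it,
                   converged = converged)
  }
  if (!best$converged)
    warning("admixture_em did not converge within max_iter")
  # orientation
  flip <- FALSE
  if (!is.null(anchors)) {
    idx1 <- match(anchors$panel1, gm$individuals)
    flip <- mean(best$q[idx1], na.rm = TRUE) < 0.5
  } else {
    pc <- genotype_pca(gm, n_components = 1)
    flip <- best$q[which.max(pc$scores[, 1])] < 0.5
  }
  if (flip) {
    best$q <- 1 - best$q
    tmp <- best$f0; best$f0 <- best$f1; best$f1 <- tmp
  }
  est <- data.frame(individual = gm$individuals, q = best$q,
                    method = "admixture_em", stringsAsFactors = FALSE)
  class(est) <- c("ancestry_estimate", "data.frame")
  list(estimates = est, f0 = best$f0, f1 = best$f1, loglik = best$loglik,
       n_iter = best$n_iter, converged = best$converged)
}

#' Verification PCA on the genotype matrix
#'
#' Columns are mean-centred (missing calls imputed with the column mean,
#' verification use only) with optional `1 / sqrt(p (1 - p))` scaling; scores
#' come from the eigendecomposition of the individual-by-individual
#' covariance. When `q` is supplied, PC1's sign is fixed to correlate
#' positively with it.
#'
#' @param gm a [genotype_matrix()].
#' @param n_components number of score columns to return.
#' @param scale logical; scale columns by the binomial standard deviation.
#' @param q optional ancestry estimates for the PC1 sign convention.
#' @return list with `scores` (individuals x components) and `var_explained`.
#' @export
genotype_pca <- function(gm, n_components = 2, scale = FALSE, q = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  X <- gm$values
  if (nrow(X) < 2) stop("need >= 2 individuals")
  storage.mode(X) <- "double"
  cm <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- cm[j]
  X <- sweep(X, 2, cm)
  if (scale) {
    p <- cm / 2
    s <- sqrt(pmax(p * (1 - p), 1e-8))
    X <- sweep(X, 2, s, "/")
  }
  if (all(abs(X) < 1e-12)) stop("zero-variance genotype data; PCA undefined")
  K <- tcrossprod(X) / max(1, ncol(X) - 1)
  eig <- eigen(K, symmetric = TRUE)
  k <- min(n_components, ncol(eig$vectors))
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[seq_len(k)], 0)), k)
  rownames(scores) <- gm$individuals
  colnames(scores) <- paste0("PC", seq_len(k))
  if (!is.null(q) && k >= 1) {
    r <- suppressWarnings(cor(scores[, 1], q, use = "complete.obs"))
    if (is.finite(r) && r < 0) scores[, 1] <- -scores[, 1]
  }
  ev <- pmax(eig$values, 0)
  list(scores = scores, var_explained = ev[seq_len(k)] / sum(ev))
}

#' Diagnostic (fixed-difference) locus panel
#'
#' Loci whose raw panel frequencies differ by exactly 1 (fixed for alternative
#' alleles between the parental panels), requiring at least `min_n`
#' non-missing individuals in each panel. The orientation records which
#' allele is the species-1 allele (`+1` = counted/ALT allele, `-1` = the
#' other allele).
#'
#' @param gm a [genotype_matrix()].
#' @param panel0,panel1 parental panel individual ids.
#' @param min_n minimum non-missing individuals per panel per locus.
#' @return object of class `diagnostic_panel`: data frame `locus`,
#'   `orientation`.
#' @export
diagnostic_panel <- function(gm, panel0, panel1, min_n = 5) {
  freqs <- parental_allele_frequencies(gm, panel0, panel1, pseudocount = 0)
  n0_ind <- freqs$n0 / 2; n1_ind <- freqs$n1 / 2
  fixed <- freqs$defined & n0_ind >= min_n & n1_ind >= min_n &
    !is.na(freqs$p0_raw) & !is.na(freqs$p1_raw) &
    abs(freqs$p1_raw - freqs$p0_raw) == 1
  if (!any(fixed)) {
    warning("no diagnostic (fixed-difference) loci found")
    out <- data.frame(locus = integer(0), orientation = integer(0))
  } else {
    out <- data.frame(locus = freqs$locus[fixed],
                      orientation = ifelse(freqs$p1_raw[fixed] == 1, 1L, -1L))
  }
  class(out) <- c("diagnostic_panel", "data.frame")
  out
}

#' Interspecific heterozygosity
#'
#' Fraction of diagnostic panel loci at which an individual is heterozygous
#' (carries one allele from each species); near 1 for F1 hybrids, near 0 for
#' parentals.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a [diagnostic_panel()].
#' @return named numeric vector of `H` per individual (`NA` when every panel
#'   locus is missing).
#' @export
interspecific_heterozygosity <- function(gm, panel) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!nrow(panel)) stop("empty diagnostic panel")
  V <- gm$values[, panel$locus, drop = FALSE]
  het <- rowSums(V == 1L, na.rm = TRUE)
  n <- rowSums(!is.na(V))
  H <- ifelse(n > 0, het / n, NA_real_)
  names(H) <- gm$individuals
  H
}

#' Classify individuals as pure, hybrid, or backcross-like
#'
#' Two rules are applied to the admixture proportion `q`: an individual is
#' `pure1`/`pure0` when at least `pure_threshold` of its genome assigns to
#' one cluster, and `hybrid` when no cluster reaches more than
#' `hybrid_threshold` (boundary inclusive). Individuals caught by neither
#' rule are labelled `backcross_like`.
#'
#' @param estimates an `ancestry_estimate` data frame (column `q`).
#' @param pure_threshold assignment needed to call an individual pure
#'   (default 0.99).
#' @param hybrid_threshold maximum single-cluster assignment of a hybrid
#'   (default 0.95).
#' @return `estimates` with a `class` column added.
#' @export
classify_individuals <- function(estimates, pure_threshold = 0.99,
                                 hybrid_threshold = 0.95) {
  if (pure_threshold <= 0.5 || pure_threshold > 1 ||
      hybrid_threshold <= 0.5 || hybrid_threshold > 1)
    stop("thresholds must be in (0.5, 1]")
  if (hybrid_threshold > pure_threshold)
    stop("hybrid_threshold must not exceed pure_threshold")
  q <- estimates$q
  cls <- rep(NA_character_, length(q))
  mx <- pmax(q, 1 - q)
  cls[q >= pure_threshold] <- "pure1"
  cls[q <= 1 - pure_threshold] <- "pure0"
  cls[is.na(cls) & mx <= hybrid_threshold] <- "hybrid"
  cls[is.na(cls) & !is.na(q)] <- "backcross_like"
  estimates$class <- cls
  estimates
}
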