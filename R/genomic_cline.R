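# Bayesian genomic clines: the per-locus (alpha, beta) deviation of ancestry
# probability from the genome-wide hybrid index, fitted by random-walk
# Metropolis with the hybrid indices held fixed at the ancestry module's
# estimates.

#' Genomic cline function
#'
#' Probability of species-1 ancestry for an allele copy at a locus with cline
#' parameters `(alpha, beta)` in an individual with hybrid index `h`:
#' `Phi = h + 2 h (1 - h) (alpha + beta (2 h - 1))`, clamped to `[0, 1]`.
#' Positive `alpha` shifts ancestry towards species 1; positive `beta`
#' steepens the locus-specific cline (restricted introgression, excess
#' ancestry-based linkage disequilibrium); negative `beta` flattens it. The
#' endpoints are anchored: `Phi(0) = 0`, `Phi(1) = 1` for any `(alpha, beta)`.
#'
#' @param h hybrid index in `[0, 1]` (vectorised).
#' @param alpha,beta cline parameters.
#' @return ancestry probability in `[0, 1]`.
#' @export
phi <- function(h, alpha, beta) {
  if (any(h < 0 | h > 1, na.rm = TRUE)) stop("h must be in [0, 1]")
  pmin(pmax(h + 2 * h * (1 - h) * (alpha + beta * (2 * h - 1)), 0), 1)
}

#' Log-likelihood of one locus under the genomic cline model
#'
#' Called genotypes: `g_i ~ Binomial(2, pi_i)` with
#' `pi_i = Phi(h_i, alpha, beta) p1 + (1 - Phi) p0`; missing genotypes
#' contribute 0. An optional symmetric per-genotype error rate `eps` mixes
#' `pi` towards 0.5.
#'
#' @param g genotypes in `{0, 1, 2, NA}` over individuals.
#' @param h per-individual hybrid indices.
#' @param alpha,beta cline parameters.
#' @param p0,p1 parental frequencies of the counted allele, strictly inside
#'   (0, 1) (use smoothed frequencies).
#' @param eps per-genotype error rate (default 0).
#' @return the log-likelihood (finite).
#' @export
locus_log_likelihood <- function(g, h, alpha, beta, p0, p1, eps = 0) {
  if (any(p0 <= 0 | p0 >= 1 | p1 <= 0 | p1 >= 1))
    stop("p0 and p1 must be strictly inside (0, 1); smooth them first")
  ok <- !is.na(g)
  if (!any(ok)) return(0)
  ph <- phi(h[ok], alpha, beta)
  pi <- ph * p1 + (1 - ph) * p0
  if (eps > 0) pi <- pi * (1 - eps) + (1 - pi) * eps
  pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)
  gk <- g[ok]
  sum(gk * log(pi) + (2 - gk) * log(1 - pi) + log(ifelse(gk == 1L, 2, 1)))
}

#' Fit per-locus Bayesian genomic clines by MCMC
#'
#' Independent random-walk Metropolis chains per locus on `(alpha, beta)`
#' with `Normal(0, prior_sd^2)` priors, hybrid indices fixed, and proposal
#' scales tuned towards 0.2-0.5 acceptance during burnin only. Deterministic
#' given `seed`.
#'
#' @param gm a [genotype_matrix()] (admixed + parental individuals).
#' @param h per-individual hybrid indices aligned with `gm$individuals`.
#' @param freqs [parental_allele_frequencies()] (smoothed, strictly inside
#'   (0, 1)).
#' @param iterations post-burnin chain length (study-scale default 50000).
#' @param burnin burnin iterations (default 25000).
#' @param thin keep every `thin`-th post-burnin state (default 5).
#' @param proposal_sd initial random-walk proposal sd.
#' @param prior_sd prior standard deviation for alpha and beta.
#' @param eps per-genotype error rate passed to the likelihood.
#' @param seed integer seed.
#' @return object of class `genomic_cline_fit`: `summary` (per-locus data
#'   frame with posterior medians and 95% equal-tail intervals for alpha and
#'   beta, acceptance rate, chromosome, position), `samples` (list of thinned
#'   draws: matrices samples x loci), `chain` metadata.
#' @export
fit_genomic_clines_mcmc <- function(gm, h, freqs, iterations = 50000,
                                    burnin = 25000, thin = 5,
                                    proposal_sd = 0.2, prior_sd = 1.0,
                                    eps = 0, seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(h) != nrow(gm$values))
    stop("length(h) must equal the number of individuals")
  if (any(is.na(h))) stop("h contains NA; drop those individuals first")
  n_adm <- sum(h > 0.01 & h < 0.99)
  if (n_adm == 0)
    stop("no admixed individuals (0.01 < h < 0.99): clines unidentifiable")
  if (n_adm < 10)
    warning("only ", n_adm, " admixed individuals; cline posteriors will be ",
            "weakly informed")
  use <- freqs$defined & is.finite(freqs$p0) & is.finite(freqs$p1)
  if (!all(use)) stop("parental frequencies undefined for ",
                      sum(!use), " locus/loci; filter first")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  res <- .mcmc_genomic_clines(gm$values, h, freqs$p0, freqs$p1,
                              as.integer(iterations), as.integer(burnin),
                              as.integer(thin), proposal_sd, prior_sd, eps)
  qs <- function(m) apply(m, 2, quantile, probs = c(0.025, 0.5, 0.975),
                          names = FALSE)
  qa <- qs(res$alpha); qb <- qs(res$beta)
  summary <- data.frame(locus = seq_len(ncol(gm$values)),
                        chrom = gm$loci$chrom, pos = gm$loci$pos,
                        alpha_med = qa[2, ], alpha_lo = qa[1, ],
                        alpha_hi = qa[3, ],
                        beta_med = qb[2, ], beta_lo = qb[1, ],
                        beta_hi = qb[3, ],
                        accept = res$accept, stringsAsFactors = FALSE)
  structure(list(summary = summary,
                 samples = list(alpha = res$alpha, beta = res$beta),
                 chain = list(iterations = iterations, burnin = burnin,
                              thin = thin, proposal_sd = proposal_sd,
                              prior_sd = prior_sd, eps = eps, seed = seed,
                              n_admixed = n_adm)),
            class = "genomic_cline_fit")
}

#' @export
print.genomic_cline_fit <- function(x, ...) {
  cat(sprintf(
    "genomic cline fit: %d loci, chain %d + %d burnin (thin %d), %d admixed individuals\n",
    nrow(x$summary), x$chain$iterations, x$chain$burnin, x$chain$thin,
    x$chain$n_admixed))
  cat(sprintf("  mean acceptance rate %.2f\n", mean(x$summary$accept)))
  invisible(x)
}

#' Compare two chains for convergence
#'
#' Per-locus absolute difference of posterior medians between a long and a
#' shorter independent chain on the same data; loci exceeding `tol_median`
#' for alpha or beta are flagged.
#'
#' @param fit_long,fit_short `genomic_cline_fit` objects over the same loci.
#' @param tol_median maximum tolerated median difference.
#' @param min_samples chains with fewer thinned draws than this are flagged
#'   unreliable.
#' @return list with `delta` (per-locus data frame), `pass_rate`, `flagged`
#'   locus indices, `reliable`.
#' @export
check_convergence <- function(fit_long, fit_short, tol_median = 0.1,
                              min_samples = 50) {
  s1 <- fit_long$summary; s2 <- fit_short$summary
  if (nrow(s1) != nrow(s2) || any(s1$locus != s2$locus))
    stop("fits cover different loci")
  reliable <- nrow(fit_long$samples$alpha) >= min_samples &&
    nrow(fit_short$samples$alpha) >= min_samples
  if (!reliable)
    warning("a chain has fewer than ", min_samples,
            " thinned draws; convergence check unreliable")
  da <- abs(s1$alpha_med - s2$alpha_med)
  db <- abs(s1$beta_med - s2$beta_med)
  flagged <- which(da > tol_median | db > tol_median)
  list(delta = data.frame(locus = s1$locus, delta_alpha = da,
                          delta_beta = db),
       pass_rate = 1 - length(flagged) / nrow(s1),
       flagged = flagged, reliable = reliable)
}

#' Classify genomic-cline outlier loci
#'
#' A locus is an outlier for a parameter, in a direction, only when both
#' rules hold: its 95% equal-tail posterior interval excludes 0, and its
#' posterior median lies in the top (or bottom) `tail` fraction of all loci's
#' medians for that parameter. Categories combine freely (a locus can be
#' both `+alpha` and `+beta`).
#'
#' @param fit a [fit_genomic_clines_mcmc()] result.
#' @param ci posterior interval mass (default 0.95).
#' @param tail extreme-median fraction per side (default 0.01), in (0, 0.5).
#' @return object of class `outlier_table`: per-locus data frame with the
#'   posterior summaries, logical flags `alpha_pos`, `alpha_neg`, `beta_pos`,
#'   `beta_neg`, and `outlier`.
#' @export
classify_outliers <- function(fit, ci = 0.95, tail = 0.01) {
  stopifnot(inherits(fit, "genomic_cline_fit"))
  if (tail <= 0 || tail >= 0.5) stop("tail must be in (0, 0.5)")
  s <- fit$summary
  if (nrow(s) < 100)
    warning("fewer than 100 loci: tail quantiles are poorly defined")
  pr <- c((1 - ci) / 2, 1 - (1 - ci) / 2)
  alo <- apply(fit$samples$alpha, 2, quantile, probs = pr[1], names = FALSE)
  ahi <- apply(fit$samples$alpha, 2, quantile, probs = pr[2], names = FALSE)
  blo <- apply(fit$samples$beta, 2, quantile, probs = pr[1], names = FALSE)
  bhi <- apply(fit$samples$beta, 2, quantile, probs = pr[2], names = FALSE)
  qa <- quantile(s$alpha_med, c(tail, 1 - tail), names = FALSE)
  qb <- quantile(s$beta_med, c(tail, 1 - tail), names = FALSE)
  out <- data.frame(s,
                    alpha_pos = alo > 0 & s$alpha_med >= qa[2],
                    alpha_neg = ahi < 0 & s$alpha_med <= qa[1],
                    beta_pos = blo > 0 & s$beta_med >= qb[2],
                    beta_neg = bhi < 0 & s$beta_med <= qb[1])
  out$outlier <- out$alpha_pos | out$alpha_neg | out$beta_pos | out$beta_neg
  class(out) <- c("outlier_table", "data.frame")
  out
}
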