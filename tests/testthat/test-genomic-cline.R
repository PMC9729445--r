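# small admixed fixture shared by the MCMC tests
gc_fixture <- function(seed = 51, n_loci = 60, beta_truth = NULL,
                       n_per_site = 6, n_ref = 8) {
  ot <- if (!is.null(beta_truth))
    data.frame(locus = which(beta_truth != 0), alpha = 0,
               beta = beta_truth[beta_truth != 0])
  if (!is.null(ot) && nrow(ot) == 0) ot <- NULL
  cfg <- sim_config(n_loci = n_loci, seed = seed, n_ref = n_ref,
                    site_x = seq(-6, 6, length.out = 8),
                    n_per_site_per_period = n_per_site,
                    outlier_truth = ot,
                    cline_truth = c(pmin = 0, pmax = 1, c1 = 0, c2 = 0,
                                    w = 10))
  d <- simulate_hybrid_zone(cfg)
  p0i <- d$samples$individual[d$samples$panel %in% "ref0"]
  p1i <- d$samples$individual[d$samples$panel %in% "ref1"]
  list(d = d,
       freqs = parental_allele_frequencies(d$genotypes, p0i, p1i),
       h = d$truth$individuals$h)
}

test_that("the cline function anchors endpoints and matches arithmetic", {
  expect_equal(phi(0.5, 0, 0), 0.5)
  expect_equal(phi(0, 5, -3), 0)
  expect_equal(phi(1, 5, -3), 1)
  expect_equal(phi(0.5, 0.4, 0), 0.7)
  expect_error(phi(1.2, 0, 0), "h must be")
  # endpoint anchoring holds for arbitrary parameters
  set.seed(2)
  for (k in 1:50) {
    a <- rnorm(1, 0, 2); b <- rnorm(1, 0, 2)
    expect_equal(phi(0, a, b), 0)
    expect_equal(phi(1, a, b), 1)
    expect_true(all(phi(runif(20), a, b) >= 0 & phi(runif(20), a, b) <= 1))
  }
})

test_that("locus log-likelihood matches enumeration and handles missing", {
  expect_equal(locus_log_likelihood(1L, 0.5, 0, 0, 0.25, 0.75), log(0.5))
  expect_equal(locus_log_likelihood(rep(NA_integer_, 5), runif(5), 1, -1,
                                    0.2, 0.8), 0)
  expect_error(locus_log_likelihood(1L, 0.5, 0, 0, 0, 1), "strictly inside")
  set.seed(13)
  g <- sample(c(0:2, NA), 10, replace = TRUE)
  h <- runif(10)
  a <- 0.6; b <- -0.4; p0 <- 0.1; p1 <- 0.92
  ours <- locus_log_likelihood(g, h, a, b, p0, p1)
  ph <- pmin(pmax(h + 2 * h * (1 - h) * (a + b * (2 * h - 1)), 0), 1)
  pi <- ph * p1 + (1 - ph) * p0
  oracle <- sum(dbinom(g, 2, pi, log = TRUE), na.rm = TRUE)
  expect_equal(ours, oracle, tolerance = 1e-12)
})

test_that("MCMC is deterministic under a fixed seed", {
  fx <- gc_fixture(n_loci = 15)
  f1 <- fit_genomic_clines_mcmc(fx$d$genotypes, fx$h, fx$freqs,
                                iterations = 600, burnin = 300, seed = 9)
  f2 <- fit_genomic_clines_mcmc(fx$d$genotypes, fx$h, fx$freqs,
                                iterations = 600, burnin = 300, seed = 9)
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$samples, f2$samples)
})

test_that("MCMC refuses unidentifiable input", {
  fx <- gc_fixture(n_loci = 10)
  h_pure <- round(fx$h)
  expect_error(fit_genomic_clines_mcmc(fx$d$genotypes, h_pure, fx$freqs,
                                       iterations = 100, burnin = 50),
               "admixed")
})

test_that("null loci are calibrated: intervals cover zero for >= 90%", {
  # ~150 admixed individuals and study-scale parental panels (the real
  # panels held 34-51 birds; small panels leak frequency error into alpha),
  # with a chain long enough that interval-endpoint Monte Carlo noise does
  # not dominate the coverage count
  fx <- gc_fixture(seed = 57, n_loci = 60, n_per_site = 10, n_ref = 30)
  fit <- fit_genomic_clines_mcmc(fx$d$genotypes, fx$h, fx$freqs,
                                 iterations = 5000, burnin = 2000, seed = 5)
  s <- fit$summary
  cover_a <- mean(s$alpha_lo <= 0 & 0 <= s$alpha_hi)
  cover_b <- mean(s$beta_lo <= 0 & 0 <= s$beta_hi)
  expect_gte(cover_a, 0.9)
  expect_gte(cover_b, 0.9)
  expect_lt(mean(abs(s$beta_med)), 0.25)
  expect_true(all(s$accept > 0.05 & s$accept < 0.95))
})

test_that("a strong planted beta is detected and recovered in rank", {
  beta_truth <- c(rep(1.2, 5), rep(0, 55))
  fx <- gc_fixture(seed = 61, n_loci = 60, beta_truth = beta_truth)
  fit <- fit_genomic_clines_mcmc(fx$d$genotypes, fx$h, fx$freqs,
                                 iterations = 2500, burnin = 1200, seed = 2)
  s <- fit$summary
  expect_gte(mean(s$beta_med[1:5] > 0), 0.8)
  expect_gte(sum(s$beta_lo[1:5] > 0), 3)
})

test_that("posterior medians track planted beta on a 200-locus mixed fixture", {
  beta_truth <- c(rep(-1.2, 5), rep(-0.8, 5), rep(0.8, 5), rep(1.2, 5),
                  rep(0, 180))
  fx <- gc_fixture(seed = 63, n_loci = 200, beta_truth = beta_truth)
  fit <- fit_genomic_clines_mcmc(fx$d$genotypes, fx$h, fx$freqs,
                                 iterations = 2500, burnin = 1200, seed = 4)
  expect_gte(cor(beta_truth, fit$summary$beta_med), 0.7)
})

test_that("shrinking the prior shrinks posterior medians", {
  fx <- gc_fixture(seed = 67, n_loci = 25,
                   beta_truth = c(rep(0.8, 5), rep(0, 20)))
  f_wide <- fit_genomic_clines_mcmc(fx$d$genotypes, fx$h, fx$freqs,
                                    iterations = 1500, burnin = 800,
                                    prior_sd = 1.0, seed = 3)
  f_tight <- fit_genomic_clines_mcmc(fx$d$genotypes, fx$h, fx$freqs,
                                     iterations = 1500, burnin = 800,
                                     prior_sd = 0.3, seed = 3)
  expect_lt(mean(abs(f_tight$summary$beta_med)),
            mean(abs(f_wide$summary$beta_med)))
  expect_lt(mean(abs(f_tight$summary$alpha_med)),
            mean(abs(f_wide$summary$alpha_med)))
})

test_that("convergence check compares chains and guards short ones", {
  fx <- gc_fixture(seed = 71, n_loci = 20)
  f1 <- fit_genomic_clines_mcmc(fx$d$genotypes, fx$h, fx$freqs,
                                iterations = 2000, burnin = 1000, seed = 11)
  same <- check_convergence(f1, f1)
  expect_equal(same$pass_rate, 1)
  expect_true(all(same$delta$delta_alpha == 0))
  f2 <- fit_genomic_clines_mcmc(fx$d$genotypes, fx$h, fx$freqs,
                                iterations = 1000, burnin = 500, seed = 12)
  chk <- check_convergence(f1, f2, tol_median = 0.1)
  expect_gte(chk$pass_rate, 0.95)
  f_tiny <- fit_genomic_clines_mcmc(fx$d$genotypes, fx$h, fx$freqs,
                                    iterations = 50, burnin = 20, seed = 13)
  expect_warning(chk2 <- check_convergence(f1, f_tiny), "unreliable")
  expect_false(chk2$reliable)
})

# build a fit object with prescribed posterior draws
fake_fit <- function(alpha_samples, beta_samples, chrom = NULL) {
  L <- ncol(alpha_samples)
  qs <- function(m) apply(m, 2, quantile, probs = c(0.025, 0.5, 0.975),
                          names = FALSE)
  qa <- qs(alpha_samples); qb <- qs(beta_samples)
  structure(list(
    summary = data.frame(locus = seq_len(L),
                         chrom = chrom %||% rep("chr1", L),
                         pos = seq_len(L),
                         alpha_med = qa[2, ], alpha_lo = qa[1, ],
                         alpha_hi = qa[3, ], beta_med = qb[2, ],
                         beta_lo = qb[1, ], beta_hi = qb[3, ],
                         accept = 0.3),
    samples = list(alpha = alpha_samples, beta = beta_samples),
    chain = list(iterations = nrow(alpha_samples), burnin = 0, thin = 1,
                 prior_sd = 1, eps = 0, seed = 1, n_admixed = 100)),
    class = "genomic_cline_fit")
}

test_that("outlier classification applies the joint CI and tail rule", {
  # all posteriors at zero: nothing can be an outlier
  z <- matrix(0, 100, 120)
  expect_warning(out0 <- classify_outliers(fake_fit(z, z)), NA)
  expect_equal(sum(out0$outlier), 0)
  # one planted extreme positive-beta posterior among 1000 null loci
  set.seed(23)
  a <- matrix(rnorm(200 * 1000, 0, 0.05), 200)
  b <- matrix(rnorm(200 * 1000, 0, 0.05), 200)
  b[, 777] <- rnorm(200, 1.5, 0.1)
  out <- classify_outliers(fake_fit(a, b))
  expect_equal(which(out$beta_pos), 777L)
  expect_error(classify_outliers(fake_fit(a, b), tail = 0.6), "tail")
})

test_that("the tail rule caps the flagged fraction per category", {
  set.seed(29)
  a <- matrix(rnorm(150 * 400, 0, 0.3), 150)
  b <- matrix(rnorm(150 * 400, 0, 0.3), 150)
  out <- classify_outliers(fake_fit(a, b), tail = 0.01)
  for (cc in c("alpha_pos", "alpha_neg", "beta_pos", "beta_neg"))
    expect_lte(mean(out[[cc]]), 0.01 + 1 / 400)
})
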