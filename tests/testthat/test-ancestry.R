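test_that("parental frequencies use Laplace smoothing and raw counts", {
  gm <- toy_gm(matrix(2L, 10, 1))
  fr <- parental_allele_frequencies(gm, gm$individuals[1:5],
                                    gm$individuals[6:10])
  expect_equal(fr$p1, (10 + 0.5) / (10 + 1))
  expect_equal(fr$p1_raw, 1)
  gm0 <- toy_gm(matrix(0L, 6, 2))
  fr0 <- parental_allele_frequencies(gm0, gm0$individuals[1:3],
                                     gm0$individuals[4:6], pseudocount = 0)
  expect_equal(fr0$p0, c(0, 0))
  expect_error(parental_allele_frequencies(gm, character(0),
                                           gm$individuals[1:2]), "empty")
  expect_error(parental_allele_frequencies(gm, gm$individuals[1:3],
                                           gm$individuals[3:5]), "disjoint")
})

test_that("parental frequencies match a brute-force recount oracle", {
  set.seed(11)
  v <- matrix(sample(c(0:2, NA), 12 * 30, replace = TRUE), 12, 30)
  gm <- toy_gm(v)
  p0i <- gm$individuals[1:6]; p1i <- gm$individuals[7:12]
  fr <- suppressWarnings(parental_allele_frequencies(gm, p0i, p1i,
                                                     pseudocount = 0.5))
  for (j in sample(30, 8)) {
    g <- v[1:6, j]
    g <- g[!is.na(g)]
    expect_equal(fr$p0[j], (sum(g) + 0.5) / (2 * length(g) + 1))
  }
})

test_that("loci with an empty panel are flagged undefined", {
  v <- matrix(1L, 6, 2)
  v[1:3, 2] <- NA
  gm <- toy_gm(v)
  expect_warning(fr <- parental_allele_frequencies(gm, gm$individuals[1:3],
                                                   gm$individuals[4:6]),
                 "undefined")
  expect_false(fr$defined[2])
  expect_true(is.na(fr$p0[2]))
})

test_that("ML hybrid index is forced to the boundary by diagnostic data", {
  gm <- toy_gm(matrix(2L, 1, 100))
  fr <- structure(data.frame(locus = 1:100, p0 = 0.005, p1 = 0.995,
                             p0_raw = 0, p1_raw = 1, n0 = 20, n1 = 20,
                             defined = TRUE),
                  class = c("parental_freqs", "data.frame"))
  est <- hybrid_index_ml(gm, fr)
  expect_gte(est$q, 0.99)
  expect_false(est$degenerate)
})

test_that("uninformative frequencies give q = 0.5 with a degeneracy flag", {
  gm <- toy_gm(matrix(1L, 2, 20))
  fr <- structure(data.frame(locus = 1:20, p0 = 0.5, p1 = 0.5,
                             p0_raw = 0.5, p1_raw = 0.5, n0 = 10, n1 = 10,
                             defined = TRUE),
                  class = c("parental_freqs", "data.frame"))
  est <- hybrid_index_ml(gm, fr)
  expect_equal(est$q, c(0.5, 0.5))
  expect_equal(est$lo, c(0, 0))
  expect_equal(est$hi, c(1, 1))
  expect_true(all(est$degenerate))
})

test_that("ML hybrid index matches a dense grid-search oracle", {
  d <- small_sim(seed = 17, n_loci = 20, missing_rate = 0.1)
  p0i <- d$samples$individual[d$samples$panel %in% "ref0"]
  p1i <- d$samples$individual[d$samples$panel %in% "ref1"]
  fr <- parental_allele_frequencies(d$genotypes, p0i, p1i)
  est <- hybrid_index_ml(d$genotypes, fr)
  grid <- seq(0, 1, by = 1e-4)
  for (i in sample(nrow(est), 8)) {
    g <- d$genotypes$values[i, ]
    ok <- !is.na(g)
    ll <- vapply(grid, function(h) {
      p <- h * fr$p1[ok] + (1 - h) * fr$p0[ok]
      sum(dbinom(g[ok], 2, p, log = TRUE))
    }, 0)
    expect_equal(est$q[i], grid[which.max(ll)], tolerance = 1e-3)
  }
})

test_that("profile-likelihood CIs bracket the estimate and cover truth", {
  d <- small_sim(seed = 23, n_loci = 200)
  p0i <- d$samples$individual[d$samples$panel %in% "ref0"]
  p1i <- d$samples$individual[d$samples$panel %in% "ref1"]
  fr <- parental_allele_frequencies(d$genotypes, p0i, p1i)
  est <- hybrid_index_ml(d$genotypes, fr)
  expect_true(all(est$lo <= est$q & est$q <= est$hi))
  h <- d$truth$individuals$h
  expect_gte(mean(est$lo - 0.02 <= h & h <= est$hi + 0.02), 0.9)
})

test_that("EM admixture separates two pure clusters", {
  cfg <- sim_config(n_loci = 200, seed = 31, n_ref = 15, site_x = c(-60, 60),
                    n_per_site_per_period = 5,
                    cline_truth = c(pmin = 0, pmax = 1, c1 = 0, c2 = 0,
                                    w = 5))
  d <- simulate_hybrid_zone(cfg)
  em <- admixture_em(d$genotypes, seed = 3, n_starts = 3)
  h <- d$truth$individuals$h
  expect_lt(mean(abs(em$estimates$q[h < 0.001] - 0)), 0.02)
  expect_lt(mean(abs(em$estimates$q[h > 0.999] - 1)), 0.02)
  expect_lt(max(abs(em$estimates$q - h)), 0.05)
  expect_true(em$converged)
})

test_that("EM gives identical estimates to duplicated individuals", {
  d <- small_sim(seed = 37, n_loci = 80)
  gm <- d$genotypes
  v <- rbind(gm$values, gm$values[7, , drop = FALSE])
  gm2 <- genotype_matrix(v, gm$loci, c(gm$individuals, "dup"))
  em <- admixture_em(gm2, seed = 5, n_starts = 2)
  expect_equal(em$estimates$q[7], em$estimates$q[nrow(v)], tolerance = 1e-6)
})

test_that("EM log-likelihood never decreases (no decrease warnings)", {
  d <- small_sim(seed = 41, n_loci = 60, missing_rate = 0.1)
  expect_no_warning(admixture_em(d$genotypes, seed = 2, n_starts = 2,
                                 max_iter = 500))
})

test_that("EM tracks the true hybrid index on an admixed transect", {
  cfg <- sim_config(n_loci = 300, seed = 43, n_ref = 10,
                    site_x = seq(-15, 15, length.out = 8),
                    n_per_site_per_period = 4)
  d <- simulate_hybrid_zone(cfg)
  p0i <- d$samples$individual[d$samples$panel %in% "ref0"]
  p1i <- d$samples$individual[d$samples$panel %in% "ref1"]
  em <- admixture_em(d$genotypes, seed = 4, n_starts = 2,
                     anchors = list(panel0 = p0i, panel1 = p1i))
  expect_gte(cor(em$estimates$q, d$truth$individuals$h), 0.98)
})

test_that("PCA scores match a direct eigendecomposition oracle", {
  set.seed(19)
  v <- matrix(sample(0:2, 16, replace = TRUE), 4, 4)
  gm <- toy_gm(v)
  sc <- genotype_pca(gm, n_components = 2)$scores
  X <- scale(v, scale = FALSE)
  e <- eigen(tcrossprod(X) / (ncol(X) - 1), symmetric = TRUE)
  ref <- e$vectors[, 1:2] %*% diag(sqrt(pmax(e$values[1:2], 0)))
  for (k in 1:2) {
    expect_true(isTRUE(all.equal(sc[, k], ref[, k], tolerance = 1e-8,
                                 check.attributes = FALSE)) ||
                  isTRUE(all.equal(sc[, k], -ref[, k], tolerance = 1e-8,
                                   check.attributes = FALSE)))
  }
})

test_that("identical individuals get identical PCA scores", {
  v <- rbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L), c(2L, 1L, 0L, 2L))
  sc <- genotype_pca(toy_gm(v))$scores
  expect_equal(sc[1, ], sc[2, ], tolerance = 1e-6)
  expect_error(genotype_pca(toy_gm(matrix(1L, 3, 4))), "zero-variance")
})

test_that("diagnostic panel finds fixed differences and enforces min_n", {
  v <- rbind(matrix(0L, 5, 3), matrix(2L, 5, 3))
  v[1, 2] <- 1L               # locus 2 not fixed in panel 0
  v[1:6, 3] <- NA             # locus 3 under min_n in panel 0
  gm <- toy_gm(v)
  dp <- suppressWarnings(diagnostic_panel(gm, gm$individuals[1:5],
                                          gm$individuals[6:10], min_n = 5))
  expect_equal(dp$locus, 1L)
  expect_equal(dp$orientation, 1L)
  # reversed orientation is recorded
  v2 <- rbind(matrix(2L, 5, 1), matrix(0L, 5, 1))
  dp2 <- diagnostic_panel(toy_gm(v2), sprintf("ind%02d", 1:5),
                          sprintf("ind%02d", 6:10), min_n = 5)
  expect_equal(dp2$orientation, -1L)
})

test_that("diagnostic panel recovers nearly all truly fixed loci", {
  set.seed(5)
  n_fixed <- 60
  v <- cbind(rbind(matrix(0L, 10, n_fixed), matrix(2L, 10, n_fixed)),
             matrix(sample(0:2, 20 * 40, replace = TRUE), 20, 40))
  v[sample(length(v), round(0.1 * length(v)))] <- NA
  gm <- toy_gm(v)
  dp <- diagnostic_panel(gm, gm$individuals[1:10], gm$individuals[11:20],
                         min_n = 5)
  expect_gte(mean(seq_len(n_fixed) %in% dp$locus), 0.95)
})

test_that("interspecific heterozygosity hits the F1 and parental anchors", {
  panel <- structure(data.frame(locus = 1:10, orientation = 1L),
                     class = c("diagnostic_panel", "data.frame"))
  gm <- toy_gm(rbind(rep(1L, 10), rep(0L, 10), rep(2L, 10),
                     c(rep(1L, 5), rep(NA, 5))))
  H <- interspecific_heterozygosity(gm, panel)
  expect_equal(unname(H), c(1, 0, 0, 1))
  gm_all_na <- toy_gm(matrix(NA_integer_, 1, 10))
  expect_true(is.na(interspecific_heterozygosity(gm_all_na, panel)))
})

test_that("mid-zone heterozygosity matches the 2h(1-h) expectation", {
  cfg <- sim_config(n_loci = 150, seed = 47, n_ref = 10, site_x = 0,
                    n_per_site_per_period = 60, h_concentration = 200,
                    cline_truth = c(pmin = 0, pmax = 1, c1 = 0, c2 = 0,
                                    w = 10))
  d <- simulate_hybrid_zone(cfg)
  p0i <- d$samples$individual[d$samples$panel %in% "ref0"]
  p1i <- d$samples$individual[d$samples$panel %in% "ref1"]
  dp <- diagnostic_panel(d$genotypes, p0i, p1i)
  expect_gt(nrow(dp), 30)
  H <- interspecific_heterozygosity(d$genotypes, dp)
  mid <- is.na(d$samples$panel)
  h <- d$truth$individuals$h[mid]
  expected <- mean(2 * h * (1 - h))
  se <- sd(H[mid]) / sqrt(sum(mid))
  expect_lt(abs(mean(H[mid]) - expected), 3 * se + 0.01)
})

test_that("classification applies the pure and hybrid rules with bounds", {
  est <- data.frame(q = c(0.999, 0.95, 0.97, 0.001, 0.05, 0.5))
  out <- classify_individuals(est)
  expect_equal(out$class, c("pure1", "hybrid", "backcross_like", "pure0",
                            "hybrid", "hybrid"))
  expect_error(classify_individuals(est, pure_threshold = 0.4), "thresholds")
  expect_error(classify_individuals(est, pure_threshold = 0.96,
                                    hybrid_threshold = 0.98),
               "hybrid_threshold")
})
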