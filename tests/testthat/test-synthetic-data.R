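test_that("identical config and seed give identical datasets and files", {
  cfg <- sim_config(n_loci = 50, seed = 33, missing_rate = 0.1,
                    outlier_truth = data.frame(locus = 45:48, alpha = 0,
                                               beta = 1))
  d1 <- simulate_hybrid_zone(cfg)
  d2 <- simulate_hybrid_zone(cfg)
  expect_identical(d1$genotypes$values, d2$genotypes$values)
  expect_identical(d1$truth, d2$truth)
  t1 <- tempfile(); t2 <- tempfile()
  write_dataset(d1, t1); write_dataset(d2, t2)
  for (f in list.files(t1)) {
    expect_identical(unname(tools::md5sum(file.path(t1, f))),
                     unname(tools::md5sum(file.path(t2, f))))
  }
})

test_that("config validation names the offending field", {
  expect_error(sim_config(n_loci = 10, chrom_plan = c(chr1 = 5)), "chrom_plan")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(h_concentration = 0), "h_concentration")
  expect_error(sim_config(cline_truth = c(pmin = 0.5, pmax = 0.4, c1 = 0,
                                          c2 = 0, w = 10)), "pmin")
  expect_error(sim_config(n_loci = 10,
                          outlier_truth = data.frame(locus = 11, alpha = 0,
                                                     beta = 1)),
               "out of range")
})

test_that("missing_rate 0 yields complete genotypes", {
  d <- small_sim(seed = 2, missing_rate = 0)
  expect_false(anyNA(d$genotypes$values))
})

test_that("zero planted shift leaves period means equal up to noise", {
  cfg <- sim_config(n_loci = 5, seed = 12, n_ref = 0,
                    site_x = seq(-10, 10, length.out = 5),
                    n_per_site_per_period = 100,
                    cline_truth = c(pmin = 0, pmax = 1, c1 = 0, c2 = 0,
                                    w = 10))
  d <- simulate_hybrid_zone(cfg)
  ti <- d$truth$individuals
  m <- tapply(ti$h, ti$period, mean)
  expect_lt(abs(diff(m)), 0.05)
})

test_that("individual h follows the Beta around the site cline expectation", {
  # p(x) = 0.8 at x = 2.5 * log(4) for centre 0, width 10
  x80 <- 2.5 * log(4)
  cfg <- sim_config(n_loci = 2, seed = 8, n_ref = 0, site_x = x80,
                    n_per_site_per_period = 250,
                    h_concentration = 50,
                    cline_truth = c(pmin = 0, pmax = 1, c1 = 0, c2 = 0,
                                    w = 10))
  d <- simulate_hybrid_zone(cfg)
  expect_equal(mean(d$truth$individuals$h), 0.8, tolerance = 0.03 / 0.8)
})

test_that("pure individuals reproduce the parental allele frequencies", {
  # alpha = beta = 0 everywhere: reference individuals with h = 1 draw
  # alleles straight from p1
  cfg <- sim_config(n_loci = 200, seed = 21, n_ref = 40, site_x = c(-5, 5),
                    n_per_site_per_period = 2)
  d <- simulate_hybrid_zone(cfg)
  ref1 <- d$samples$panel %in% "ref1"
  emp <- colMeans(d$genotypes$values[ref1, , drop = FALSE]) / 2
  p1 <- d$truth$loci$p1
  se <- sqrt(p1 * (1 - p1) / (2 * sum(ref1)))
  within3 <- abs(emp - p1) < pmax(3 * se, 1e-9) + 1e-12
  expect_gte(mean(within3), 0.98)   # ~0.3% of loci may exceed 3 SE by chance
})

test_that("planted positive-beta loci depress mid-zone heterozygosity", {
  planted <- 1:40
  cfg <- sim_config(n_loci = 400, seed = 14, n_ref = 0, site_x = 0,
                    n_per_site_per_period = 160, h_concentration = 8,
                    outlier_truth = data.frame(locus = planted, alpha = 0,
                                               beta = 1.5),
                    cline_truth = c(pmin = 0, pmax = 1, c1 = 0, c2 = 0,
                                    w = 10))
  d <- simulate_hybrid_zone(cfg)
  mid <- d$truth$individuals$h > 0.4 & d$truth$individuals$h < 0.6
  expect_gte(sum(mid), 100)
  het <- d$genotypes$values[mid, , drop = FALSE] == 1L
  h_planted <- colMeans(het[, planted])
  h_null <- colMeans(het[, -planted])
  tt <- t.test(h_planted, h_null, alternative = "less")
  expect_lt(tt$p.value, 0.05)
})

test_that("climate stack obeys the planted linear trend", {
  # noiseless: consecutive years differ by exactly the region rate
  cc <- climate_sim_config(noise_sd = 0, seed = 1, years = c(1980, 1990))
  cs <- simulate_climate_stack(cc)
  d <- cs$stack[["1981"]]$values - cs$stack[["1980"]]$values
  expect_equal(unique(d[cs$masks[[1]]]), 0.03)
  expect_equal(unique(d[cs$masks[[2]]]), 0.02)
  expect_equal(unique(d[!(cs$masks[[1]] | cs$masks[[2]])]), 0)
})

test_that("noiseless two-region rates give an exactly 50% contrast", {
  cc <- climate_sim_config(noise_sd = 0, seed = 1, years = c(1976, 2016))
  cs <- simulate_climate_stack(cc)
  m1 <- window_mean(cs$stack, c(1976, 1980))
  m2 <- window_mean(cs$stack, c(2012, 2016))
  r <- rate_of_change(m1, m2, 36)
  ctr <- regional_contrast(r, cs$masks[[1]], r, cs$masks[[2]])
  expect_equal(ctr$contrast_pct, 50)
})

test_that("noisy region rates are recovered by a least-squares oracle", {
  cc <- climate_sim_config(noise_sd = 0.1, seed = 6, years = c(1980, 2016))
  cs <- simulate_climate_stack(cc)
  yrs <- 1980:2016
  for (k in 1:2) {
    means <- vapply(as.character(yrs),
                    function(y) mean(cs$stack[[y]]$values[cs$masks[[k]]]), 0)
    slope <- unname(coef(lm(means ~ yrs))[2])
    expect_equal(slope, cc$regions[[k]]$rate, tolerance = 0.002 /
                   cc$regions[[k]]$rate)
  }
})

test_that("overlapping climate regions are rejected", {
  expect_error(climate_sim_config(
    regions = list(list(name = "a", lon = c(-94, -92), lat = c(37.5, 38.5),
                        rate = 0.02),
                   list(name = "b", lon = c(-93, -91), lat = c(37.5, 38.5),
                        rate = 0.03))),
    "overlap")
})

test_that("a written dataset round-trips through the standard formats", {
  d <- small_sim(seed = 4, missing_rate = 0.1)
  cc <- climate_sim_config(noise_sd = 0, seed = 2, years = c(2000, 2004))
  d$climate <- list(tmean = simulate_climate_stack(cc))
  td <- tempfile()
  write_dataset(d, td)
  expect_true(all(file.exists(file.path(td,
    c("genotypes.vcf", "samples.csv", "truth_individuals.csv",
      "truth_loci.csv", "truth_clines.csv", "tmean_2000.asc")))))
  d2 <- read_dataset(td)
  expect_identical(unname(d2$genotypes$values), unname(d$genotypes$values))
  expect_identical(d2$samples$individual, d$samples$individual)
  expect_equal(d2$samples$lon, d$samples$lon, tolerance = 1e-12)
  expect_equal(d2$truth$individuals$h, d$truth$individuals$h,
               tolerance = 1e-12)
  g <- read_ascii_grid(file.path(td, "tmean_2002.asc"))
  expect_equal(g$values, d$climate$tmean$stack[["2002"]]$values)
})

test_that("a hand-sized dataset writes the expected VCF records", {
  gm <- toy_gm(rbind(c(0L, 1L, NA), c(2L, 1L, 0L)))
  d <- structure(list(genotypes = gm,
                      samples = data.frame(individual = gm$individuals,
                                           site = "S", lon = 0, lat = 0,
                                           period = "p",
                                           panel = NA_character_),
                      truth = list(individuals = data.frame(),
                                   loci = data.frame(),
                                   clines = data.frame())),
                 class = "sim_dataset")
  td <- tempfile()
  write_dataset(d, td)
  recs <- grep("^[^#]", readLines(file.path(td, "genotypes.vcf")),
               value = TRUE)
  expect_length(recs, 3)
  gt <- t(vapply(strsplit(recs, "\t"), function(x) x[10:11], character(2)))
  expect_equal(gt, rbind(c("0/0", "1/1"), c("0/1", "0/1"), c("./.", "0/0")))
})
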