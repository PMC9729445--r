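# Study-design replication experiments: fixed synthetic conditions that
# mirror the temporal chickadee-transect design, used by the test suite and
# the acceptance script. Each function runs the full inference path on
# freshly simulated data and returns the measured quantities.

.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131071 + k * 7919) %% .Machine$integer.max)
}

#' Cline-shift recovery experiment
#'
#' Simulates the two-period transect design (30 sites per period, two
#' individuals per site, 1,000 divergent loci, planted centre shift 5.66 km,
#' width 10 km), estimates per-individual ancestry by ML hybrid index, fits
#' per-period geographic clines with bootstrap CIs, and measures the
#' recovered shift against the planted truth across seeded replicates.
#'
#' @param seed integer seed; replicate seeds are derived from it.
#' @param n_replicates number of independent replicates (default 20).
#' @param n_boot bootstrap resamples per period per replicate (default 200,
#'   the test-scale setting).
#' @param delta_true planted centre shift in km (default 5.66).
#' @param interval_years elapsed years (default 36).
#' @return list with `replicates` (data frame: `delta_c`, `lo`, `hi`,
#'   `abs_err`, `covered`), and summary fields `mean_delta_c`, `mean_abs_err`,
#'   `n_within_1km`, `n_covered`, `rate_km_per_yr`.
#' @export
experiment_cline_shift <- function(seed = 1, n_replicates = 20, n_boot = 200,
                                   delta_true = 5.66, interval_years = 36) {
  reps <- lapply(seq_len(n_replicates), function(r) {
    rs <- .derive_seed(seed, r)
    cfg <- sim_config(n_loci = 1000, seed = rs,
                      site_x = seq(-20, 25, length.out = 30),
                      n_per_site_per_period = 2, n_ref = 10,
                      cline_truth = c(pmin = 0, pmax = 1, c1 = 0,
                                      c2 = delta_true, w = 10))
    d <- simulate_hybrid_zone(cfg)
    panel0 <- d$samples$individual[d$samples$panel %in% "ref0"]
    panel1 <- d$samples$individual[d$samples$panel %in% "ref1"]
    freqs <- parental_allele_frequencies(d$genotypes, panel0, panel1)
    est <- hybrid_index_ml(d$genotypes, freqs)
    x <- project_to_transect(d$samples, cfg$baseline)
    fits <- list(); boots <- list()
    for (pd in cfg$periods$label) {
      sel <- d$samples$period == pd & is.na(d$samples$panel)
      fits[[pd]] <- fit_geographic_cline(x[sel], est$q[sel], seed = rs,
                                         period = pd)
      boots[[pd]] <- bootstrap_cline(x[sel], est$q[sel], n_boot = n_boot,
                                     seed = rs, fit = fits[[pd]])
    }
    mv <- estimate_movement(fits[[1]], fits[[2]], interval_years,
                            boots[[1]], boots[[2]], seed = rs)
    data.frame(delta_c = mv$delta_c_km, lo = mv$ci[1], hi = mv$ci[2],
               abs_err = abs(mv$delta_c_km - delta_true),
               covered = mv$ci[1] <= delta_true & delta_true <= mv$ci[2])
  })
  reps <- do.call(rbind, reps)
  list(replicates = reps,
       mean_delta_c = mean(reps$delta_c),
       mean_abs_err = mean(reps$abs_err),
       n_within_1km = sum(reps$abs_err < 1),
       n_covered = sum(reps$covered),
       rate_km_per_yr = mean(reps$delta_c) / interval_years,
       delta_true = delta_true, n_replicates = n_replicates)
}

#' Genomic-cline calibration and power experiment
#'
#' Simulates 2,000 loci across five chromosomes (200 on Z) with 20 planted
#' positive-beta loci (beta = 1) including a four-locus consecutive run on Z,
#' roughly 150 admixed individuals, fits per-locus genomic clines with a
#' test-scale chain (5,000 + 2,500 burnin, thin 5), classifies outliers, and
#' measures detection power, null false-positive rates, and the planted-run
#' permutation p.
#'
#' @param seed integer seed.
#' @param iterations,burnin chain settings (test-scale defaults).
#' @param n_perm permutations for the run test.
#' @return list with `power_beta_pos`, `fpr_by_category` (named, null loci),
#'   `fpr_max_category`, `fpr_union`, `run_detected` (planted Z run found at
#'   full length), `perm_p`, `beta_cor` (planted beta vs posterior medians),
#'   `n_admixed`, and the underlying `outliers` table.
#' @export
experiment_genomic_calibration <- function(seed = 1, iterations = 5000,
                                           burnin = 2500, n_perm = 10000) {
  chrom_plan <- c(chr1 = 600, chr2 = 500, chr3 = 400, chr4 = 300, Z = 200)
  run_loci <- 1851:1854   # consecutive on Z
  scatter <- c(101, 230, 417, 555, 689, 803, 947, 1101, 1234, 1380, 1449,
               1538, 1627, 1703, 1762, 1990)
  planted <- c(run_loci, scatter)
  ot <- data.frame(locus = planted, alpha = 0, beta = 1.0)
  cfg <- sim_config(n_loci = 2000, chrom_plan = chrom_plan,
                    seed = .derive_seed(seed, 1),
                    site_x = seq(-7, 7, length.out = 10),
                    n_per_site_per_period = 8, n_ref = 10,
                    divergence = 0.3, outlier_truth = ot,
                    cline_truth = c(pmin = 0, pmax = 1, c1 = 0, c2 = 0,
                                    w = 10))
  d <- simulate_hybrid_zone(cfg)
  panel0 <- d$samples$individual[d$samples$panel %in% "ref0"]
  panel1 <- d$samples$individual[d$samples$panel %in% "ref1"]
  freqs <- parental_allele_frequencies(d$genotypes, panel0, panel1)
  est <- hybrid_index_ml(d$genotypes, freqs)
  fit <- fit_genomic_clines_mcmc(d$genotypes, est$q, freqs,
                                 iterations = iterations, burnin = burnin,
                                 thin = 5, seed = .derive_seed(seed, 2))
  out <- classify_outliers(fit)
  isp <- out$locus %in% planted
  null <- out[!isp, ]
  fpr <- c(alpha_pos = mean(null$alpha_pos), alpha_neg = mean(null$alpha_neg),
           beta_pos = mean(null$beta_pos), beta_neg = mean(null$beta_neg))
  runs <- find_outlier_runs(out, min_run = 3)
  run_detected <- any(runs$chrom == "Z" & runs$start_locus <= min(run_loci) &
                        runs$end_locus >= max(run_loci))
  perm <- run_permutation_test(out$beta_pos, out[, c("chrom", "pos")],
                               min_run = 3, n_perm = n_perm,
                               seed = .derive_seed(seed, 3))
  list(power_beta_pos = mean(out$beta_pos[isp]),
       fpr_by_category = fpr,
       fpr_max_category = max(fpr),
       fpr_union = mean(null$outlier),
       run_detected = run_detected,
       perm_p = perm$p,
       beta_cor = cor(ifelse(isp, 1, 0), out$beta_med),
       n_admixed = fit$chain$n_admixed,
       outliers = out, runs = runs)
}

#' Ancestry-estimation accuracy experiment
#'
#' Simulates a 500-divergent-locus transect without missingness and measures
#' (i) the RMSE of the ML hybrid index against true h, (ii) the Pearson
#' correlation of the K = 2 EM admixture estimate with truth, and (iii) the
#' correlation of PC1 with the hybrid index.
#'
#' @param seed integer seed.
#' @param em_starts EM random restarts (default 3 at test scale).
#' @return list with `rmse_ml`, `r_em`, `r_pca`, `n_individuals`.
#' @export
experiment_ancestry_accuracy <- function(seed = 1, em_starts = 3) {
  cfg <- sim_config(n_loci = 500, seed = .derive_seed(seed, 11),
                    site_x = seq(-20, 20, length.out = 15),
                    n_per_site_per_period = 4, n_ref = 10,
                    missing_rate = 0,
                    cline_truth = c(pmin = 0, pmax = 1, c1 = 0, c2 = 0,
                                    w = 12))
  d <- simulate_hybrid_zone(cfg)
  h_true <- d$truth$individuals$h
  panel0 <- d$samples$individual[d$samples$panel %in% "ref0"]
  panel1 <- d$samples$individual[d$samples$panel %in% "ref1"]
  freqs <- parental_allele_frequencies(d$genotypes, panel0, panel1)
  ml <- hybrid_index_ml(d$genotypes, freqs)
  em <- admixture_em(d$genotypes, seed = .derive_seed(seed, 12),
                     n_starts = em_starts,
                     anchors = list(panel0 = panel0, panel1 = panel1))
  pca <- genotype_pca(d$genotypes, q = ml$q)
  list(rmse_ml = sqrt(mean((ml$q - h_true)^2)),
       r_em = cor(em$estimates$q, h_true),
       r_pca = abs(cor(pca$scores[, 1], ml$q)),
       n_individuals = length(h_true))
}

#' Regional climate-contrast experiment
#'
#' Simulates two-region yearly temperature stacks with planted warming rates
#' in ratio 1.5 (0.03 vs 0.02 degrees C per year, cell noise sd 0.05),
#' computes 5-year window means at both ends of a 1976-2016 record, the
#' per-year rate of change, and the between-region contrast.
#'
#' @param seed integer seed.
#' @return list with `contrast_pct` (expected 50 under the planted rates),
#'   `mean_rate_A`, `mean_rate_B`.
#' @export
experiment_climate_contrast <- function(seed = 1) {
  cc <- climate_sim_config(noise_sd = 0.05, seed = .derive_seed(seed, 21))
  cs <- simulate_climate_stack(cc)
  m_start <- window_mean(cs$stack, c(1976, 1980))
  m_end <- window_mean(cs$stack, c(2012, 2016))
  rate <- rate_of_change(m_start, m_end, 2016 - 1980)
  ctr <- regional_contrast(rate, cs$masks[[1]], rate, cs$masks[[2]])
  list(contrast_pct = ctr$contrast_pct, mean_rate_A = ctr$mean_A,
       mean_rate_B = ctr$mean_B)
}

#' Percent change between two period means
#'
#' Reporting helper for temporal summaries such as the change in a site's
#' mean hybrid index between sampling periods:
#' `100 * (to - from) / from`.
#'
#' @param from,to the earlier and later values.
#' @return percent change.
#' @export
percent_change <- function(from, to) 100 * (to - from) / from
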