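# End-to-end orchestration: simulate (or load) -> filter -> ancestry ->
# geographic clines -> genomic clines -> genome scan -> climate, with a run
# manifest and deterministic per-stage seeds derived from one global seed.

# stable per-stage seed: global seed plus a stage-name hash, kept within
# 32-bit integer range
.stage_seed <- function(seed, stage) {
  hash <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((seed * 1009 + hash * 97) %% .Machine$integer.max)
}

#' Configure a pipeline run
#'
#' @param sim a [sim_config()] (synthetic input), or `NULL` to read
#'   `vcf_path` / `samples_path`.
#' @param vcf_path,samples_path input files when `sim` is `NULL`.
#' @param climate_sim a [climate_sim_config()] or `NULL` to skip the climate
#'   stage.
#' @param presence minimum locus call fraction (default 0.9).
#' @param drop_singletons apply the singleton filter (default `TRUE`).
#' @param one_snp_per_locus collapse RAD loci to one SNP (default `TRUE`).
#' @param pure_threshold,hybrid_threshold classification thresholds.
#' @param baseline a [transect_baseline()] for the transect projection.
#' @param interval_years elapsed years between periods; default is the
#'   difference of the period anchor years.
#' @param n_boot bootstrap resamples per period cline.
#' @param mcmc list of genomic-cline chain settings (`iterations`, `burnin`,
#'   `thin`, `prior_sd`).
#' @param min_run,n_perm genome-scan settings.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param outdir output directory, or `NULL` for no file output.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, vcf_path = NULL, samples_path = NULL,
                            climate_sim = NULL,
                            presence = 0.9, drop_singletons = TRUE,
                            one_snp_per_locus = TRUE,
                            pure_threshold = 0.99, hybrid_threshold = 0.95,
                            baseline = transect_baseline(-94.0, 38.2, 45),
                            interval_years = NULL, n_boot = 200,
                            mcmc = list(iterations = 5000, burnin = 2500,
                                        thin = 5, prior_sd = 1.0),
                            min_run = 3, n_perm = 10000,
                            seed = 1, outdir = NULL) {
  if (is.null(sim)) {
    if (is.null(vcf_path) || is.null(samples_path))
      stop("either `sim` or both `vcf_path` and `samples_path` are required")
    if (!file.exists(vcf_path)) stop("vcf_path does not exist: ", vcf_path)
    if (!file.exists(samples_path))
      stop("samples_path does not exist: ", samples_path)
  }
  if (presence <= 0 || presence > 1) stop("presence must be in (0, 1]")
  structure(list(sim = sim, vcf_path = vcf_path,
                 samples_path = samples_path, climate_sim = climate_sim,
                 presence = presence, drop_singletons = drop_singletons,
                 one_snp_per_locus = one_snp_per_locus,
                 pure_threshold = pure_threshold,
                 hybrid_threshold = hybrid_threshold, baseline = baseline,
                 interval_years = interval_years, n_boot = n_boot,
                 mcmc = mcmc, min_run = min_run, n_perm = n_perm,
                 seed = seed, outdir = outdir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate/load, filter, ancestry,
#' geographic clines + movement, genomic clines, genome scan, climate —
#' writing per-stage CSV artifacts and a run manifest when `outdir` is set.
#' Rerunning with the same config and seed reproduces identical numbers.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return list of stage artifacts (class `pipeline_result`): `genotypes`,
#'   `samples`, `ancestry`, `clines`, `movement`, `genomic_fit`, `outliers`,
#'   `gtests`, `runs`, `run_perm`, `climate`, `manifest`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_all <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    if (verbose) message("stage: ", name)
    val <- force(expr)
    t_all[[name]] <<- round(proc.time()[3] - t0, 3)
    val
  }
  out <- list()

  dat <- stage("simulate", {
    if (!is.null(config$sim)) {
      simulate_hybrid_zone(config$sim)
    } else {
      gm <- read_vcf(config$vcf_path)
      list(genotypes = gm,
           samples = read_samples(config$samples_path, gm), truth = NULL)
    }
  })
  out$truth <- dat$truth
  samples <- validate_samples(dat$samples, dat$genotypes)

  gm <- stage("filter", {
    g <- dat$genotypes
    if (config$one_snp_per_locus)
      g <- suppressMessages(select_one_snp_per_locus(g))
    if (config$drop_singletons) g <- suppressMessages(filter_singletons(g))
    suppressMessages(filter_by_presence(g, config$presence))
  })
  out$genotypes <- gm
  out$samples <- samples

  anc <- stage("ancestry", {
    panel0 <- samples$individual[samples$panel %in% "ref0"]
    panel1 <- samples$individual[samples$panel %in% "ref1"]
    if (!length(panel0) || !length(panel1))
      stop("ancestry stage requires ref0/ref1 panel labels in the samples")
    freqs <- parental_allele_frequencies(gm, panel0, panel1)
    keep <- freqs$defined
    gmk <- subset_loci(gm, keep)
    freqs_k <- freqs[keep, ]
    class(freqs_k) <- class(freqs)
    est <- hybrid_index_ml(gmk, freqs_k)
    est <- classify_individuals(est, config$pure_threshold,
                                config$hybrid_threshold)
    dp <- suppressWarnings(diagnostic_panel(gmk, panel0, panel1))
    est$H <- if (nrow(dp)) interspecific_heterozygosity(gmk, dp) else NA_real_
    list(estimates = est, freqs = freqs_k, gm = gmk, panel = dp,
         panel0 = panel0, panel1 = panel1)
  })
  out$ancestry <- anc$estimates

  geo <- stage("geocline", {
    x <- project_to_transect(samples, config$baseline)
    periods <- if (!is.null(dat$truth)) dat$truth$clines$period else
      unique(samples$period[is.na(samples$panel)])
    iv <- config$interval_years
    if (is.null(iv) && !is.null(dat$truth))
      iv <- diff(dat$truth$clines$year)
    if (is.null(iv)) stop("interval_years must be set for file inputs")
    sseed <- .stage_seed(config$seed, "geocline")
    fits <- list(); boots <- list()
    for (pd in periods) {
      sel <- samples$period == pd & is.na(samples$panel)
      fits[[pd]] <- fit_geographic_cline(x[sel], anc$estimates$q[sel],
                                         seed = sseed, period = pd)
      boots[[pd]] <- bootstrap_cline(x[sel], anc$estimates$q[sel],
                                     n_boot = config$n_boot, seed = sseed,
                                     fit = fits[[pd]])
    }
    mv <- estimate_movement(fits[[1]], fits[[2]], iv,
                            boots[[1]], boots[[2]], seed = sseed)
    list(x = x, fits = fits, boots = boots, movement = mv)
  })
  out$clines <- geo$fits
  out$movement <- geo$movement
  out$transect <- data.frame(individual = samples$individual,
                             x_km = geo$x, q = anc$estimates$q,
                             period = samples$period)

  fit <- stage("genomcline", {
    fit_genomic_clines_mcmc(anc$gm, anc$estimates$q, anc$freqs,
                            iterations = config$mcmc$iterations,
                            burnin = config$mcmc$burnin,
                            thin = config$mcmc$thin,
                            prior_sd = config$mcmc$prior_sd,
                            seed = .stage_seed(config$seed, "genomcline"))
  })
  out$genomic_fit <- fit
  out$outliers <- suppressWarnings(classify_outliers(fit))

  out <- c(out, stage("scan", {
    gt <- chromosome_composition_test(out$outliers)
    runs <- find_outlier_runs(out$outliers, min_run = config$min_run)
    perm <- if (any(out$outliers$beta_pos)) {
      run_permutation_test(out$outliers$beta_pos,
                           out$outliers[, c("chrom", "pos")],
                           min_run = config$min_run,
                           n_perm = config$n_perm,
                           seed = .stage_seed(config$seed, "scan"))
    } else NULL
    list(gtests = gt, runs = runs, run_perm = perm)
  }))

  out$climate <- stage("climate", {
    if (is.null(config$climate_sim)) NULL else {
      cs <- simulate_climate_stack(config$climate_sim)
      yrs <- cs$config$years
      m_start <- window_mean(cs$stack, c(yrs[1], yrs[1] + 4))
      m_end <- window_mean(cs$stack, c(yrs[2] - 4, yrs[2]))
      rate <- rate_of_change(m_start, m_end, yrs[2] - (yrs[1] + 4))
      ctr <- regional_contrast(rate, cs$masks[[1]], rate, cs$masks[[2]])
      list(stack = cs, rate = rate, contrast = ctr)
    }
  })

  out$manifest <- list(
    package_version = as.character(utils::packageVersion("hzshift")),
    seed = config$seed,
    config_hash = sprintf("%08x",
                          sum(as.integer(serialize(unclass(config), NULL))) %%
                            2^31),
    stages = t_all)
  class(out) <- "pipeline_result"

  if (!is.null(config$outdir)) .write_pipeline_artifacts(out, config$outdir)
  out
}

.write_pipeline_artifacts <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) write.csv(df, file.path(outdir, name),
                                    row.names = FALSE)
  w(out$ancestry, "ancestry.csv")
  w(out$transect, "transect.csv")
  cl <- do.call(rbind, lapply(out$clines, function(f)
    data.frame(period = f$period, pmin = f$pmin, pmax = f$pmax,
               centre = f$centre, width = f$width, resid_sd = f$resid_sd,
               n = f$n)))
  w(cl, "cline_fit.csv")
  w(data.frame(delta_c_km = out$movement$delta_c_km,
               rate_km_per_yr = out$movement$rate_km_per_yr,
               interval_years = out$movement$interval_years,
               ci_lo = out$movement$ci[1], ci_hi = out$movement$ci[2]),
    "movement.csv")
  w(as.data.frame(out$outliers), "genomic_clines.csv")
  w(out$gtests, "chrom_gtest.csv")
  w(out$runs, "outlier_runs.csv")
  if (nrow(out$runs)) write_runs_bed(out$runs, file.path(outdir, "runs.bed"))
  mf <- out$manifest
  writeLines(c(paste("package_version:", mf$package_version),
               paste("seed:", mf$seed),
               paste("config_hash:", mf$config_hash),
               paste0("stage_seconds: ",
                      paste(names(mf$stages), unlist(mf$stages), sep = "=",
                            collapse = " "))),
             file.path(outdir, "manifest.txt"))
  invisible(outdir)
}

#' Summarise a pipeline run
#'
#' Collects the quantities the analysis reports: cline shift and per-year
#' rate with CI, hybrid proportions per period, outlier counts per category,
#' positive-beta runs with the permutation p, and the regional climate
#' contrast. Missing artifacts are listed and the rest still summarised.
#'
#' @param result a [run_pipeline()] result (or a partial list of its
#'   artifacts).
#' @return list with `summary` (named values), `text` (human-readable
#'   lines), `missing` (artifact names absent from the input).
#' @export
make_report <- function(result) {
  s <- list()
  missing <- character(0)
  txt <- character(0)
  if (!is.null(result$movement)) {
    s$delta_c_km <- result$movement$delta_c_km
    s$rate_km_per_yr <- result$movement$rate_km_per_yr
    if (!is.null(result$movement$ci)) {
      s$delta_c_ci_lo <- result$movement$ci[1]
      s$delta_c_ci_hi <- result$movement$ci[2]
    }
    txt <- c(txt, sprintf(
      "Cline centre shift: %.2f km over %g years (%.3f km/yr)%s",
      s$delta_c_km, result$movement$interval_years, s$rate_km_per_yr,
      if (!is.null(result$movement$ci))
        sprintf(", 95%% CI [%.2f, %.2f] km", s$delta_c_ci_lo,
                s$delta_c_ci_hi) else ""))
  } else missing <- c(missing, "movement")
  if (!is.null(result$ancestry) && "class" %in% names(result$ancestry) &&
      !is.null(result$samples)) {
    sm <- result$samples
    for (pd in unique(sm$period[is.na(sm$panel)])) {
      sel <- sm$period == pd & is.na(sm$panel)
      prop <- mean(result$ancestry$class[sel] == "hybrid", na.rm = TRUE)
      s[[paste0("hybrid_prop_", pd)]] <- prop
      txt <- c(txt, sprintf("Hybrid proportion (%s): %.1f%%", pd, 100 * prop))
    }
  } else missing <- c(missing, "ancestry")
  if (!is.null(result$outliers)) {
    o <- result$outliers
    n <- nrow(o)
    s$n_loci <- n
    s$n_outliers <- sum(o$outlier)
    s$outlier_pct <- 100 * s$n_outliers / n
    for (cc in c("alpha_pos", "alpha_neg", "beta_pos", "beta_neg"))
      s[[paste0("n_", cc)]] <- sum(o[[cc]])
    txt <- c(txt, sprintf(
      "Outliers: %d of %d loci (%.1f%%) [+a %d, -a %d, +b %d, -b %d]",
      s$n_outliers, n, s$outlier_pct, s$n_alpha_pos, s$n_alpha_neg,
      s$n_beta_pos, s$n_beta_neg))
  } else missing <- c(missing, "outliers")
  if (!is.null(result$runs)) {
    s$n_runs <- nrow(result$runs)
    if (!is.null(result$run_perm)) s$run_perm_p <- result$run_perm$p
    txt <- c(txt, sprintf(
      "Consecutive +beta runs (>= cutoff): %d%s", s$n_runs,
      if (!is.null(result$run_perm))
        sprintf(" (max-run permutation p = %.4g)", s$run_perm_p) else ""))
  } else missing <- c(missing, "runs")
  if (!is.null(result$climate)) {
    s$climate_contrast_pct <- result$climate$contrast$contrast_pct
    txt <- c(txt, sprintf(
      "Regional warming contrast: %.1f%% (A vs B)", s$climate_contrast_pct))
  } else missing <- c(missing, "climate")
  if (length(missing))
    txt <- c(txt, paste("Missing artifacts:", paste(missing, collapse = ", ")))
  list(summary = s, text = txt, missing = missing)
}
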