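# Synthetic two-species contact-zone datasets: the generative model the
# inference modules assume, inverted. Every downstream stage gets a
# parameter-recovery test from these draws.

#' Configure a hybrid-zone simulation
#'
#' Defines a transect of sites crossing a sigmoid ancestry cline sampled in
#' two periods whose cline centres may differ (the planted movement), two
#' parental gene pools with a chosen fraction of strongly divergent loci,
#' per-locus genomic-cline deviations (alpha, beta), RAD-style missingness,
#' and parental reference panels.
#'
#' An individual at transect distance `x` in period `t` draws its true hybrid
#' index `h ~ Beta(nu * p(x), nu * (1 - p(x)))` with `p(x)` the period's
#' sigmoid; each of its two allele copies at a locus is of species-1 ancestry
#' with probability `Phi(h, alpha, beta)` and the allele is then drawn from
#' that species' frequency. Copies are independent across loci (free
#' recombination between RAD loci).
#'
#' @param n_loci number of RAD loci (one variable site each unless
#'   `sites_per_locus_max > 1`).
#' @param chrom_plan named integer vector of loci per chromosome (must include
#'   `"Z"` when outliers are planted there); sums to `n_loci`.
#' @param site_x transect distances of the sampling sites (km, perpendicular
#'   to the interface, positive NW).
#' @param n_per_site_per_period individuals sampled per site per period.
#' @param periods data frame with columns `label`, `year` (two rows).
#' @param cline_truth named vector `pmin`, `pmax`, `c1`, `c2`, `w`: true
#'   sigmoid tails, the two period centres (km) and the width (km).
#' @param divergence fraction of loci with parental frequency difference
#'   >= 0.9 (divergent loci draw `p1 ~ U(0.95, 1)`, `p0 ~ U(0, 0.05)`; the
#'   rest share `p1 = p0 ~ U(0.05, 0.95)`).
#' @param outlier_truth data frame `locus`, `alpha`, `beta` of planted
#'   genomic-cline deviations (default: none).
#' @param outliers_divergent when `TRUE` (default), planted outlier loci are
#'   assigned to the divergent class: barrier loci are strongly
#'   differentiated between the parental species, which is what makes their
#'   introgression deviations observable.
#' @param h_concentration Beta concentration `nu` of individual hybrid-index
#'   noise around the site expectation.
#' @param missing_rate per-call missingness probability in `[0, 1)`.
#' @param n_ref reference-panel individuals per species (true `h` exactly 0
#'   or 1), labelled `ref0` / `ref1`.
#' @param sites_per_locus_max when > 1, each RAD locus emits 1..max variable
#'   sites (for exercising the one-SNP-per-locus filter).
#' @param baseline [transect_baseline()] used to invert the projection so the
#'   written lon/lat have exact transect distances.
#' @param seed integer seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_loci = 1000,
                       chrom_plan = NULL,
                       site_x = seq(-25, 25, length.out = 15),
                       n_per_site_per_period = 4,
                       periods = data.frame(label = c("historic", "modern"),
                                            year = c(1980, 2016)),
                       cline_truth = c(pmin = 0, pmax = 1, c1 = 0, c2 = 0,
                                       w = 10),
                       divergence = 1,
                       outlier_truth = NULL,
                       outliers_divergent = TRUE,
                       h_concentration = 50,
                       missing_rate = 0,
                       n_ref = 10,
                       sites_per_locus_max = 1,
                       baseline = transect_baseline(-94.0, 38.2, 45),
                       seed = 1) {
  if (is.null(chrom_plan)) {
    base <- c(chr1 = 0.3, chr2 = 0.25, chr3 = 0.2, chr4 = 0.15, Z = 0.1)
    chrom_plan <- floor(base * n_loci)
    chrom_plan[1] <- chrom_plan[1] + n_loci - sum(chrom_plan)
  }
  if (sum(chrom_plan) != n_loci)
    stop("chrom_plan locus counts must sum to n_loci")
  ct <- cline_truth
  req <- c("pmin", "pmax", "c1", "c2", "w")
  if (!all(req %in% names(ct)))
    stop("cline_truth must name ", paste(req, collapse = ", "))
  if (!(ct["pmin"] >= 0 && ct["pmin"] < ct["pmax"] && ct["pmax"] <= 1))
    stop("cline_truth requires 0 <= pmin < pmax <= 1")
  if (ct["w"] <= 0) stop("cline_truth width w must be > 0")
  if (h_concentration <= 0) stop("h_concentration must be > 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (divergence < 0 || divergence > 1)
    stop("divergence must be in [0, 1]")
  if (nrow(periods) != 2) stop("exactly two periods required")
  if (!is.null(outlier_truth)) {
    if (any(outlier_truth$locus < 1 | outlier_truth$locus > n_loci))
      stop("outlier_truth locus index out of range")
  }
  structure(list(n_loci = n_loci, chrom_plan = chrom_plan, site_x = site_x,
                 n_per_site_per_period = n_per_site_per_period,
                 periods = periods, cline_truth = ct, divergence = divergence,
                 outlier_truth = outlier_truth,
                 outliers_divergent = outliers_divergent,
                 h_concentration = h_concentration,
                 missing_rate = missing_rate, n_ref = n_ref,
                 sites_per_locus_max = sites_per_locus_max,
                 baseline = baseline, seed = seed),
            class = "sim_config")
}

# draw diploid genotypes for individuals with hybrid indices h at loci with
# ancestry probabilities phi (n_ind x n_loci) and parental frequencies p0, p1
.draw_genotypes <- function(phi, p0, p1) {
  n_ind <- nrow(phi); n_loci <- ncol(phi)
  g <- matrix(0L, n_ind, n_loci)
  for (copy in 1:2) {
    src1 <- matrix(runif(n_ind * n_loci), n_ind) < phi
    pr <- matrix(rep(p0, each = n_ind), n_ind)
    pr[src1] <- matrix(rep(p1, each = n_ind), n_ind)[src1]
    g <- g + (matrix(runif(n_ind * n_loci), n_ind) < pr)
  }
  g
}

#' Simulate a hybrid-zone dataset
#'
#' Draws a complete dataset (genotypes, sample metadata with coordinates,
#' full truth tables) under the model in [sim_config()]. Identical config and
#' seed give identical output.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_dataset`: `genotypes`
#'   ([genotype_matrix()]), `samples` (metadata data frame), and `truth`
#'   (lists `individuals`, `loci`, `clines`).
#' @export
simulate_hybrid_zone <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  n_loci <- config$n_loci
  ct <- config$cline_truth

  # parental allele frequencies
  n_div <- round(config$divergence * n_loci)
  div <- rep(FALSE, n_loci)
  div[sample.int(n_loci, n_div)] <- TRUE
  if (isTRUE(config$outliers_divergent) && !is.null(config$outlier_truth) &&
      n_div >= length(unique(config$outlier_truth$locus))) {
    pl <- unique(config$outlier_truth$locus)
    short <- sum(!div[pl])
    if (short > 0) { # keep the divergent count fixed while covering outliers
      swap <- sample(which(div & !(seq_len(n_loci) %in% pl)), short)
      div[swap] <- FALSE
      div[pl] <- TRUE
    }
  }
  p1 <- p0 <- numeric(n_loci)
  p1[div] <- runif(n_div, 0.95, 1)
  p0[div] <- runif(n_div, 0, 0.05)
  shared <- runif(n_loci - n_div, 0.05, 0.95)
  p1[!div] <- shared
  p0[!div] <- shared

  # locus metadata
  chrom <- rep(names(config$chrom_plan), config$chrom_plan)
  pos <- unlist(lapply(config$chrom_plan, function(k) seq_len(k) * 1000L),
                use.names = FALSE)
  loci <- data.frame(chrom = chrom, pos = pos,
                     rad_locus = sprintf("L%05d", seq_len(n_loci)),
                     stringsAsFactors = FALSE)

  alpha <- beta <- numeric(n_loci)
  if (!is.null(config$outlier_truth)) {
    alpha[config$outlier_truth$locus] <- config$outlier_truth$alpha
    beta[config$outlier_truth$locus] <- config$outlier_truth$beta
  }

  # individuals: transect samples per period plus reference panels
  nu <- config$h_concentration
  rows <- list()
  for (pi in 1:2) {
    cc <- ct[[if (pi == 1) "c1" else "c2"]]
    for (si in seq_along(config$site_x)) {
      x <- config$site_x[si]
      p <- cline_p(x, ct[["pmin"]], ct[["pmax"]], cc, ct[["w"]])
      p <- min(max(p, 1e-6), 1 - 1e-6)
      h <- rbeta(config$n_per_site_per_period, nu * p, nu * (1 - p))
      rows[[length(rows) + 1]] <- data.frame(
        site = sprintf("S%02d", si), x = x,
        period = config$periods$label[pi], h = h,
        panel = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (config$n_ref > 0) {
    xr <- max(abs(config$site_x)) + 30
    rows[[length(rows) + 1]] <- data.frame(
      site = "REF0", x = -xr, period = config$periods$label[2],
      h = rep(0, config$n_ref), panel = "ref0", stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      site = "REF1", x = xr, period = config$periods$label[2],
      h = rep(1, config$n_ref), panel = "ref1", stringsAsFactors = FALSE)
  }
  ind <- do.call(rbind, rows)
  ind$individual <- sprintf("I%04d", seq_len(nrow(ind)))
  ll <- transect_to_lonlat(s = 0, x = ind$x, baseline = config$baseline)
  ind$lon <- ll$lon
  ind$lat <- ll$lat

  # genotypes: ancestry probability per individual x locus, then alleles
  h <- ind$h
  hh <- matrix(h, nrow(ind), n_loci)
  am <- matrix(alpha, nrow(ind), n_loci, byrow = TRUE)
  bm <- matrix(beta, nrow(ind), n_loci, byrow = TRUE)
  phi <- pmin(pmax(hh + 2 * hh * (1 - hh) * (am + bm * (2 * hh - 1)), 0), 1)
  g <- .draw_genotypes(phi, p0, p1)

  # optionally expand RAD loci to 1..k variable sites
  if (config$sites_per_locus_max > 1) {
    n_sites <- sample.int(config$sites_per_locus_max, n_loci, replace = TRUE)
    expand <- rep(seq_len(n_loci), n_sites)
    g2 <- matrix(0L, nrow(ind), length(expand))
    loci2 <- loci[expand, , drop = FALSE]
    off <- unlist(lapply(n_sites, seq_len)) - 1L
    loci2$pos <- loci2$pos + off * 7L
    for (j in seq_along(expand)) {
      l <- expand[j]
      g2[, j] <- if (off[j] == 0L) g[, l] else
        .draw_genotypes(phi[, l, drop = FALSE], p0[l], p1[l])
    }
    g <- g2
    loci <- loci2
    rownames(loci) <- NULL
  }

  if (config$missing_rate > 0) {
    miss <- matrix(runif(length(g)) < config$missing_rate, nrow(g))
    g[miss] <- NA_integer_
  }

  gm <- genotype_matrix(g, loci, ind$individual)
  samples <- ind[, c("individual", "site", "lon", "lat", "period", "panel")]
  rownames(samples) <- NULL
  truth <- list(
    individuals = data.frame(individual = ind$individual, h = ind$h,
                             x = ind$x, period = ind$period,
                             stringsAsFactors = FALSE),
    loci = data.frame(locus = seq_len(n_loci), chrom = chrom, pos = pos,
                      rad_locus = sprintf("L%05d", seq_len(n_loci)),
                      p0 = p0, p1 = p1, alpha = alpha, beta = beta,
                      divergent = div, stringsAsFactors = FALSE),
    clines = data.frame(period = config$periods$label,
                        year = config$periods$year,
                        pmin = ct[["pmin"]], pmax = ct[["pmax"]],
                        centre = c(ct[["c1"]], ct[["c2"]]), width = ct[["w"]],
                        stringsAsFactors = FALSE))
  structure(list(genotypes = gm, samples = samples, truth = truth,
                 config = config),
            class = "sim_dataset")
}

#' Configure a synthetic climate raster stack
#'
#' Two disjoint rectangular regions warm (or wet) at different planted
#' per-year rates on a shared grid; cells outside both regions hold the base
#' value. Spatial noise is i.i.d. Gaussian per cell per year.
#'
#' @param nrows,ncols grid shape.
#' @param cellsize cell size (degrees).
#' @param xll,yll lower-left corner (degrees).
#' @param regions list of two `list(name, lon = c(min, max),
#'   lat = c(min, max), rate)` rectangles with per-year trend rates.
#' @param base base value of the variable in the first year.
#' @param noise_sd i.i.d. cell noise standard deviation.
#' @param years inclusive year range `c(first, last)`.
#' @param variable variable name (e.g. `"tmean"`).
#' @param seed integer seed.
#' @return a validated `climate_sim_config` list.
#' @export
climate_sim_config <- function(nrows = 20, ncols = 40, cellsize = 0.1,
                               xll = -95, yll = 37,
                               regions = list(
                                 list(name = "east", lon = c(-93, -91.5),
                                      lat = c(37.5, 38.5), rate = 0.03),
                                 list(name = "west", lon = c(-95, -93.5),
                                      lat = c(37.5, 38.5), rate = 0.02)),
                               base = 12, noise_sd = 0.05,
                               years = c(1976, 2016), variable = "tmean",
                               seed = 1) {
  if (length(regions) != 2) stop("exactly two regions required")
  g0 <- climate_grid(matrix(0, nrows, ncols), xll, yll, cellsize)
  masks <- lapply(regions, function(r) {
    cc <- .cell_centres(g0)
    outer(cc$lat >= r$lat[1] & cc$lat <= r$lat[2],
          cc$lon >= r$lon[1] & cc$lon <= r$lon[2], `&`)
  })
  if (any(masks[[1]] & masks[[2]]))
    stop("region masks overlap")
  structure(list(nrows = nrows, ncols = ncols, cellsize = cellsize,
                 xll = xll, yll = yll, regions = regions, masks = masks,
                 base = base, noise_sd = noise_sd, years = years,
                 variable = variable, seed = seed),
            class = "climate_sim_config")
}

#' Simulate a yearly climate raster stack
#'
#' @param config a [climate_sim_config()].
#' @return list with `stack` (named list of [climate_grid()], names = years),
#'   `masks` (the two region cell masks), and `config`.
#' @export
simulate_climate_stack <- function(config) {
  stopifnot(inherits(config, "climate_sim_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  yrs <- seq(config$years[1], config$years[2])
  rate_map <- matrix(0, config$nrows, config$ncols)
  for (k in 1:2) rate_map[config$masks[[k]]] <- config$regions[[k]]$rate
  stack <- setNames(vector("list", length(yrs)), yrs)
  for (i in seq_along(yrs)) {
    v <- config$base + rate_map * (yrs[i] - yrs[1])
    if (config$noise_sd > 0)
      v <- v + matrix(rnorm(length(v), 0, config$noise_sd), nrow(v))
    stack[[i]] <- climate_grid(v, config$xll, config$yll, config$cellsize,
                               variable = config$variable,
                               label = as.character(yrs[i]))
  }
  list(stack = stack, masks = config$masks, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits `genotypes.vcf` (VCF 4.2), `samples.csv`, the truth tables
#' (`truth_individuals.csv`, `truth_loci.csv`, `truth_clines.csv`), and any
#' climate stacks attached as `dataset$climate` (one
#' `<var>_<year>.asc` ASCII grid per year). [read_dataset()] round-trips the
#' genotypes and samples exactly.
#'
#' @param dataset a `sim_dataset` (optionally with a `climate` element:
#'   named list variable -> stack list).
#' @param directory output directory (created if absent).
#' @return `directory`, invisibly.
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  write_vcf(dataset$genotypes, file.path(directory, "genotypes.vcf"))
  write.csv(dataset$samples, file.path(directory, "samples.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(dataset$truth$individuals,
            file.path(directory, "truth_individuals.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(dataset$truth$loci, file.path(directory, "truth_loci.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(dataset$truth$clines, file.path(directory, "truth_clines.csv"),
            row.names = FALSE, quote = FALSE)
  if (!is.null(dataset$climate)) {
    for (var in names(dataset$climate)) {
      st <- dataset$climate[[var]]
      for (yr in names(st$stack))
        write_ascii_grid(st$stack[[yr]],
                         file.path(directory, paste0(var, "_", yr, ".asc")))
    }
  }
  invisible(directory)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param directory directory holding `genotypes.vcf` and `samples.csv`.
#' @return list with `genotypes`, `samples`, and (when present) `truth`
#'   tables.
#' @export
read_dataset <- function(directory) {
  gm <- read_vcf(file.path(directory, "genotypes.vcf"))
  samples <- read_samples(file.path(directory, "samples.csv"), gm)
  out <- list(genotypes = gm, samples = samples)
  tf <- file.path(directory, c("truth_individuals.csv", "truth_loci.csv",
                               "truth_clines.csv"))
  if (all(file.exists(tf)))
    out$truth <- list(individuals = read.csv(tf[1]), loci = read.csv(tf[2]),
                      clines = read.csv(tf[3]))
  out
}
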