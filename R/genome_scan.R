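# Chromosome-level outlier composition (G-tests) and consecutive
# positive-beta run detection with a permutation null.

# mutually exclusive category per locus for the composition test
.outlier_category <- function(outliers) {
  flags <- cbind(outliers$alpha_pos, outliers$alpha_neg,
                 outliers$beta_pos, outliers$beta_neg)
  nm <- c("alpha_pos", "alpha_neg", "beta_pos", "beta_neg")
  nflag <- rowSums(flags)
  cat <- rep("non_outlier", nrow(outliers))
  single <- nflag == 1
  cat[single] <- nm[apply(flags[single, , drop = FALSE], 1, which.max)]
  cat[nflag > 1] <- "multi"
  factor(cat, levels = c(nm, "multi", "non_outlier"))
}

#' Per-chromosome outlier composition G-tests
#'
#' For each chromosome, compares the observed counts of outlier categories
#' (`+alpha` only, `-alpha` only, `+beta` only, `-beta` only, multi-category,
#' non-outlier) against expected counts from the genome-wide category
#' proportions, with the log-likelihood-ratio statistic
#' `G = 2 sum O ln(O / E)` (terms with `O = 0` contribute 0) referred to a
#' chi-square with `df = (categories with E > 0) - 1`.
#'
#' @param outliers an [classify_outliers()] table (columns `chrom` and the
#'   four directional flags).
#' @param williams apply the Williams small-sample correction (default
#'   `FALSE`).
#' @param alpha significance level for the `significant` column.
#' @return data frame, one row per chromosome, sorted by `G` descending:
#'   `chrom`, `n_loci`, `G`, `df`, `p`, `significant`, plus observed category
#'   counts.
#' @export
chromosome_composition_test <- function(outliers, williams = FALSE,
                                        alpha = 0.05) {
  stopifnot(inherits(outliers, "outlier_table"))
  chroms <- unique(outliers$chrom)
  if (length(chroms) < 2) stop("need >= 2 chromosomes")
  cat <- .outlier_category(outliers)
  genome_prop <- table(cat) / length(cat)
  res <- lapply(chroms, function(ch) {
    idx <- outliers$chrom == ch
    n <- sum(idx)
    if (n == 0) {
      warning("chromosome ", ch, " has 0 loci; skipped")
      return(NULL)
    }
    O <- table(cat[idx])
    E <- genome_prop * n
    keep <- E > 0
    terms <- ifelse(O[keep] > 0, O[keep] * log(O[keep] / E[keep]), 0)
    G <- 2 * sum(terms)
    k <- sum(keep)
    if (williams && k > 1) G <- G / (1 + (k^2 - 1) / (6 * n * (k - 1)))
    df <- k - 1
    p <- pchisq(G, df, lower.tail = FALSE)
    counts <- as.data.frame(t(as.numeric(O)))
    names(counts) <- paste0("n_", names(O))
    cbind(data.frame(chrom = ch, n_loci = n, G = G, df = df, p = p,
                     significant = p < alpha, stringsAsFactors = FALSE),
          counts)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$G), ]
  rownames(out) <- NULL
  out
}

#' Find runs of consecutive outlier loci
#'
#' Maximal runs of at least `min_run` loci flagged in `category`, consecutive
#' in the position-sorted locus list of a single chromosome (runs never span
#' chromosome boundaries). "Consecutive" means adjacent markers in the
#' filtered locus list, not a base-pair distance.
#'
#' @param outliers an [classify_outliers()] table.
#' @param min_run minimum run length (default 3).
#' @param category flag column to scan (default `"beta_pos"`).
#' @return data frame, one row per run: `chrom`, `start_locus`, `end_locus`
#'   (locus ids), `start_pos`, `end_pos`, `length`.
#' @export
find_outlier_runs <- function(outliers, min_run = 3, category = "beta_pos") {
  stopifnot(inherits(outliers, "outlier_table"))
  if (!category %in% names(outliers)) stop("unknown category: ", category)
  ord <- order(outliers$chrom, outliers$pos)
  o <- outliers[ord, ]
  runs <- list()
  for (ch in unique(o$chrom)) {
    oc <- o[o$chrom == ch, ]
    r <- rle(as.logical(oc[[category]]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hit <- which(r$values & r$lengths >= min_run)
    for (k in hit) {
      runs[[length(runs) + 1]] <- data.frame(
        chrom = ch,
        start_locus = oc$locus[starts[k]], end_locus = oc$locus[ends[k]],
        start_pos = oc$pos[starts[k]], end_pos = oc$pos[ends[k]],
        length = r$lengths[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(runs))
    return(data.frame(chrom = character(0), start_locus = integer(0),
                      end_locus = integer(0), start_pos = integer(0),
                      end_pos = integer(0), length = integer(0)))
  do.call(rbind, runs)
}

# maximum within-chromosome run length of TRUE in a flag vector ordered by
# (chrom, pos); `chrom` must be ordered accordingly
.max_run <- function(flags, chrom) {
  mx <- 0L
  for (ch in unique(chrom)) {
    r <- rle(flags[chrom == ch])
    m <- r$lengths[r$values]
    if (length(m)) mx <- max(mx, max(m))
  }
  mx
}

#' Permutation test for consecutive-outlier runs
#'
#' Null hypothesis: flagged loci are randomly distributed across the data
#' set. Flags are permuted genome-wide over the position-sorted locus list
#' (each chromosome keeps its locus count) and the maximum within-chromosome
#' run length is recorded; `p = (1 + #{permutations with max run >=
#' min_run}) / (1 + n_perm)`. When fewer than `min_run` loci are flagged no
#' arrangement can produce a run, and `p = 1`.
#'
#' @param flags logical flag per locus.
#' @param loci data frame with `chrom`, `pos` aligned with `flags`.
#' @param min_run minimum run length (default 3).
#' @param n_perm number of permutations (default 10000; < 100 warns).
#' @param seed integer seed.
#' @return list with `p`, `observed_max_run`, `n_perm`.
#' @export
run_permutation_test <- function(flags, loci, min_run = 3, n_perm = 10000,
                                 seed = 1) {
  if (!any(flags)) stop("no flagged loci")
  if (n_perm < 100) warning("n_perm < 100: permutation p is very coarse")
  ord <- order(loci$chrom, loci$pos)
  flags <- as.logical(flags)[ord]
  chrom <- loci$chrom[ord]
  obs <- .max_run(flags, chrom)
  if (sum(flags) < min_run)
    return(list(p = 1.0, observed_max_run = obs, n_perm = n_perm))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  # insert a permanent FALSE between chromosomes so one rle call per
  # permutation respects boundaries
  n <- length(flags)
  breaks <- which(chrom[-1] != chrom[-n])
  aug_idx <- seq_len(n) + findInterval(seq_len(n) - 1, breaks)
  aug <- rep(FALSE, n + length(breaks))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    aug[aug_idx] <- flags[sample.int(n)]
    r <- rle(aug)
    m <- r$lengths[r$values]
    if (length(m) && max(m) >= min_run) hits <- hits + 1L
  }
  list(p = (1 + hits) / (1 + n_perm), observed_max_run = obs,
       n_perm = n_perm)
}

#' Export outlier runs as BED
#'
#' Writes run regions as 0-based half-open BED intervals.
#'
#' @param runs a [find_outlier_runs()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_runs_bed <- function(runs, path) {
  lines <- if (nrow(runs)) {
    paste(runs$chrom, runs$start_pos - 1L, runs$end_pos,
          paste0("run", seq_len(nrow(runs))), sep = "\t")
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}
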