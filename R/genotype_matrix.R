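#' Construct a genotype matrix
#'
#' The central genotype container: an individuals-by-loci matrix of diploid
#' counts of the species-1-associated allele (0, 1 or 2; `NA` = missing call),
#' with per-locus metadata (chromosome, 1-based position, RAD locus id).
#'
#' @param values integer matrix, individuals in rows, loci in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param loci data frame with one row per locus and columns `chrom`,
#'   `pos` (1-based), `rad_locus`.
#' @param individuals character vector of individual ids (unique).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `values`, `loci`, `individuals`.
#' @export
genotype_matrix <- function(values, loci, individuals) {
  values <- as.matrix(values)
  if (!is.numeric(values) && !all(is.na(values)))
    stop("`values` must be a numeric matrix")
  storage.mode(values) <- "integer"
  bad <- !is.na(values) & !(values %in% 0:2)
  if (any(bad))
    stop("genotype values must be 0, 1, 2 or NA; found ",
         values[which(bad)[1]])
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "rad_locus")
  if (!all(req %in% names(loci)))
    stop("`loci` must have columns: ", paste(req, collapse = ", "))
  if (nrow(loci) != ncol(values))
    stop("nrow(loci) [", nrow(loci), "] != ncol(values) [", ncol(values), "]")
  individuals <- as.character(individuals)
  if (length(individuals) != nrow(values))
    stop("length(individuals) != nrow(values)")
  if (anyDuplicated(individuals))
    stop("duplicated individual ids")
  rownames(values) <- individuals
  structure(list(values = values, loci = loci, individuals = individuals),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nm <- sum(is.na(x$values))
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * nm / max(1L, length(x$values))))
  cat("chromosomes:", paste(unique(x$loci$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Subset loci of a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param keep logical or integer index over loci.
#' @return a `genotype_matrix` with the selected loci.
#' @export
subset_loci <- function(gm, keep) {
  stopifnot(inherits(gm, "genotype_matrix"))
  genotype_matrix(gm$values[, keep, drop = FALSE],
                  gm$loci[keep, , drop = FALSE],
                  gm$individuals)
}

#' Validate a sample metadata table
#'
#' Checks the per-individual metadata table against a genotype matrix: one row
#' per genotyped individual, valid coordinates, and an optional reference-panel
#' label (`"ref0"` = species-0/Carolina panel, `"ref1"` = species-1/black-capped
#' panel, `NA` = unlabelled).
#'
#' @param samples data frame with columns `individual`, `site`, `lon`, `lat`,
#'   `period` and optionally `panel`.
#' @param gm optional [genotype_matrix()] to cross-check individual ids against.
#' @return the validated data frame (invisibly usable), with a `panel` column
#'   guaranteed present.
#' @export
validate_samples <- function(samples, gm = NULL) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("individual", "site", "lon", "lat", "period")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!"panel" %in% names(samples)) samples$panel <- NA_character_
  if (anyDuplicated(samples$individual))
    stop("duplicated individuals in sample table")
  if (any(samples$lat < -90 | samples$lat > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]")
  if (any(samples$lon < -180 | samples$lon > 180, na.rm = TRUE))
    stop("longitude outside [-180, 180]")
  if (!is.null(gm)) {
    if (!setequal(samples$individual, gm$individuals))
      stop("sample table individuals do not match genotype matrix")
    samples <- samples[match(gm$individuals, samples$individual), ]
    rownames(samples) <- NULL
  }
  samples
}
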