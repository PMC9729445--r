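# Genotype file I/O and the SNP filters applied before ancestry analysis.

#' Read a VCF into a genotype matrix
#'
#' Parses diploid `GT` fields of a VCF 4.x file into counts of the ALT allele
#' per individual (the species-1 orientation is resolved downstream from the
#' reference panels). Multiallelic records are rejected and counted. The
#' per-record `INFO` key `LOCUS` (RAD locus id), when present, populates the
#' `rad_locus` metadata column; otherwise each record is its own locus.
#'
#' @param path path to a VCF (plain or gzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    message(sum(multi), " multiallelic record(s) dropped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no biallelic records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  # allele counts from unphased or phased diploid calls
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
            "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  vals <- matrix(code[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  unknown <- !is.na(gt) & !(gt %in% c(names(code), "./.", ".|.", "."))
  if (any(unknown))
    stop("unparseable GT value(s), e.g. '", gt[which(unknown)[1]],
         "' at record ", which(unknown, arr.ind = TRUE)[1, 1])
  info <- vcf@fix[, "INFO"]
  rad <- sub(".*LOCUS=([^;]+).*", "\\1", info)
  no_tag <- !grepl("LOCUS=", info)
  ids <- fix[, "ID"]
  rad[no_tag] <- ifelse(is.na(ids[no_tag]) | ids[no_tag] == ".",
                        paste0("rec", which(no_tag)), ids[no_tag])
  loci <- data.frame(chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     rad_locus = rad,
                     stringsAsFactors = FALSE)
  genotype_matrix(t(vals), loci, colnames(gt))
}

#' Write a genotype matrix as a VCF
#'
#' Emits a minimal plain-text VCF 4.2 with one biallelic record per locus,
#' `GT`-only genotypes, contig lines per chromosome, and the RAD locus id in
#' `INFO` as `LOCUS=<id>`. The counted allele is written as ALT so that
#' [read_vcf()] round-trips the matrix exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=hzshift",
               paste0("##contig=<ID=", unique(gm$loci$chrom), ">"),
               "##INFO=<ID=LOCUS,Number=1,Type=String,Description=\"RAD locus id\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", gm$individuals), collapse = "\t")
  writeLines(header, con)
  if (ncol(gm$values) > 0L) {
    gt_code <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow = ncol(gm$values), ncol = nrow(gm$values))
    ok <- !is.na(t(gm$values))
    gt[ok] <- gt_code[t(gm$values)[ok] + 1L]
    recs <- paste(gm$loci$chrom, gm$loci$pos,
                  paste0("snp", seq_len(nrow(gm$loci))),
                  "A", "T", ".", "PASS",
                  paste0("LOCUS=", gm$loci$rad_locus), "GT",
                  sep = "\t")
    if (nrow(gm$values) > 0L)
      recs <- paste(recs, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(recs, con)
  }
  invisible(path)
}

#' Keep one variable site per RAD locus
#'
#' Collapses multi-SNP RAD loci to a single representative SNP: the
#' lowest-position site on each locus, ties broken by input order.
#'
#' @param gm a [genotype_matrix()] with `rad_locus` metadata populated.
#' @return a `genotype_matrix` with exactly one site per RAD locus, in input
#'   order of the retained sites.
#' @export
select_one_snp_per_locus <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (any(is.na(gm$loci$rad_locus)))
    stop("rad_locus annotation missing for some loci")
  n0 <- ncol(gm$values)
  # stable order by position keeps input order among position ties
  ord <- order(gm$loci$pos)
  first <- ord[!duplicated(gm$loci$rad_locus[ord])]
  keep <- sort(first)
  out <- subset_loci(gm, keep)
  message("select_one_snp_per_locus: ", n0 - length(keep), " site(s) removed, ",
          length(keep), " retained")
  out
}

#' Remove singleton SNPs
#'
#' Drops loci whose minor allele occurs exactly once across all non-missing
#' calls, counting allele copies (a single heterozygote carries the minor
#' allele once; a single homozygote carries it twice and is retained).
#'
#' @param gm a [genotype_matrix()].
#' @return the filtered `genotype_matrix`.
#' @export
filter_singletons <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  alt <- colSums(gm$values, na.rm = TRUE)
  tot <- 2L * colSums(!is.na(gm$values))
  mac <- pmin(alt, tot - alt)
  keep <- mac != 1L
  message("filter_singletons: ", sum(!keep), " singleton(s) removed")
  subset_loci(gm, keep)
}

#' Filter loci by call presence
#'
#' Keeps loci genotyped in at least `min_fraction` of individuals.
#'
#' @param gm a [genotype_matrix()].
#' @param min_fraction minimum non-missing call fraction, in (0, 1].
#' @return the filtered `genotype_matrix`.
#' @export
filter_by_presence <- function(gm, min_fraction = 0.9) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.numeric(min_fraction) || length(min_fraction) != 1 ||
      min_fraction < 0 || min_fraction > 1)
    stop("`min_fraction` must be a single value in [0, 1]")
  pres <- colMeans(!is.na(gm$values))
  keep <- pres >= min_fraction
  message("filter_by_presence: ", sum(!keep), " locus/loci below ",
          min_fraction, " presence removed")
  subset_loci(gm, keep)
}

#' Read a sample metadata CSV
#'
#' @param path CSV with header `individual,site,lon,lat,period,panel`.
#' @param gm optional genotype matrix to validate against (reorders rows to
#'   match its individuals).
#' @return validated sample data frame.
#' @export
read_samples <- function(path, gm = NULL) {
  samples <- read.csv(path, stringsAsFactors = FALSE)
  if ("panel" %in% names(samples))
    samples$panel[samples$panel %in% c("", "NA")] <- NA_character_
  validate_samples(samples, gm)
}
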