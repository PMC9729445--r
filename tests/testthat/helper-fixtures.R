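# shared fixtures built in code

# small two-period transect dataset
small_sim <- function(seed = 1, n_loci = 60, missing_rate = 0, ...) {
  simulate_hybrid_zone(sim_config(
    n_loci = n_loci, seed = seed, missing_rate = missing_rate,
    site_x = seq(-12, 12, length.out = 6), n_per_site_per_period = 4,
    n_ref = 5, ...))
}

# hand-built genotype matrix
toy_gm <- function(values, chrom = NULL, pos = NULL, rad = NULL) {
  values <- as.matrix(values)
  L <- ncol(values)
  genotype_matrix(
    values,
    data.frame(chrom = chrom %||% rep("chr1", L),
               pos = pos %||% (seq_len(L) * 100L),
               rad_locus = rad %||% sprintf("L%03d", seq_len(L))),
    sprintf("ind%02d", seq_len(nrow(values))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-written VCF text fixture: 3 samples x 2 biallelic records (+ 1
# multiallelic that must be dropped)
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=LOCUS,Number=1,Type=String,Description=\"RAD locus id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("chr1", "100", ".", "A", "T", ".", "PASS", "LOCUS=L1", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("chr1", "200", ".", "G", "C", ".", "PASS", "LOCUS=L2", "GT",
          "./.", "1/0", "0/0", sep = "\t"),
    paste("chr1", "300", ".", "G", "C,A", ".", "PASS", "LOCUS=L3", "GT",
          "0/0", "0/2", "0/0", sep = "\t")), path)
  path
}

# synthetic outlier table for scan tests
toy_outlier_table <- function(chrom, beta_pos,
                              alpha_pos = rep(FALSE, length(chrom)),
                              alpha_neg = rep(FALSE, length(chrom)),
                              beta_neg = rep(FALSE, length(chrom))) {
  n <- length(chrom)
  out <- data.frame(locus = seq_len(n), chrom = chrom, pos = seq_len(n),
                    alpha_med = 0, alpha_lo = -1, alpha_hi = 1,
                    beta_med = 0, beta_lo = -1, beta_hi = 1, accept = 0.3,
                    alpha_pos = alpha_pos, alpha_neg = alpha_neg,
                    beta_pos = beta_pos, beta_neg = beta_neg)
  out$outlier <- out$alpha_pos | out$alpha_neg | out$beta_pos | out$beta_neg
  class(out) <- c("outlier_table", "data.frame")
  out
}
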