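# hzshift

Temporal hybrid-zone analysis from biallelic SNPs: how far has a contact
zone moved between two sampling periods, which loci resist introgression,
and how does the movement relate to regional climate change?

The package grew out of the black-capped (*Poecile atricapillus*) /
Carolina (*P. carolinensis*) chickadee contact zone, where a transect
sampled decades apart lets the interface position be compared through time,
but every stage is generic: it applies to any two-taxon hybrid zone sampled
as diploid biallelic genotypes along a transect in two periods.

## What it computes

**Ancestry.** Per-individual admixture proportion `q` (species-1 ancestry),
three ways: a maximum-likelihood hybrid index given parental-panel allele
frequencies (`hybrid_index_ml()`, with profile-likelihood CIs), a K = 2 EM
admixture estimator that needs no panels (`admixture_em()`), and a
verification PCA (`genotype_pca()`). Individuals are classified pure /
hybrid / backcross-like (`classify_individuals()`), and interspecific
heterozygosity on fixed-difference loci (`diagnostic_panel()`,
`interspecific_heterozygosity()`) supports triangle-plot style checks.

**Geographic clines and movement.** Samples are projected onto the axis
perpendicular to the interface (`project_to_transect()`), and ancestry is
fitted per period to the sigmoid

```
p(x) = pmin + (pmax - pmin) / (1 + exp(-4 (x - c) / w))
```

so `c` is the cline centre (km) and `w` the width (inverse of the maximum
slope). The movement estimate is `Δc = c₂ − c₁` with a bootstrap CI and a
per-year rate (`fit_geographic_cline()`, `bootstrap_cline()`,
`estimate_movement()`).

**Genomic clines.** Per-locus Bayesian genomic cline parameters `(α, β)`
with the ancestry-probability function

```
Φ(h) = h + 2 h (1 - h) (α + β (2 h - 1)),  clamped to [0, 1]
```

fitted by random-walk Metropolis with the hybrid indices held fixed
(`fit_genomic_clines_mcmc()`; the kernel is C++). Outliers follow the joint
rule — 95% posterior interval excludes 0 *and* the median sits in the 1%
tail of all loci (`classify_outliers()`). Positive-β loci are candidate
barrier loci; chromosome-level composition is tested with G-tests
(`chromosome_composition_test()`), and runs of ≥ 3 consecutive positive-β
loci are detected and tested against a genome-wide permutation null
(`find_outlier_runs()`, `run_permutation_test()`).

**Climate context.** Yearly rasters (ESRI ASCII grid) are reduced to 5-year
window means, per-year rates of change, site-buffered regional summaries,
and a between-region contrast such as "region A warmed 50% more than
region B" (`window_mean()`, `rate_of_change()`, `buffer_cells()`,
`regional_contrast()`).

**Synthetic data.** `simulate_hybrid_zone()` and `simulate_climate_stack()`
generate complete datasets under exactly the generative model the inference
assumes — two parental gene pools, a sigmoid transect with a planted
centre shift, planted (α, β) outliers including a consecutive run on the Z
chromosome, RAD-style missingness, and two-region climate trends — so every
stage has a parameter-recovery test with no external data.

## Worked example

```r
library(hzshift)

cfg <- sim_config(
  n_loci = 300, seed = 7, missing_rate = 0.05,
  cline_truth = c(pmin = 0, pmax = 1, c1 = 0, c2 = 5.66, w = 10))
d <- simulate_hybrid_zone(cfg)

gm <- filter_by_presence(filter_singletons(select_one_snp_per_locus(d$genotypes)), 0.9)
panel0 <- d$samples$individual[d$samples$panel %in% "ref0"]
panel1 <- d$samples$individual[d$samples$panel %in% "ref1"]
freqs  <- parental_allele_frequencies(gm, panel0, panel1)
est    <- hybrid_index_ml(gm, freqs)

x  <- project_to_transect(d$samples, cfg$baseline)
h1 <- d$samples$period == "historic" & is.na(d$samples$panel)
h2 <- d$samples$period == "modern"   & is.na(d$samples$panel)
f1 <- fit_geographic_cline(x[h1], est$q[h1], seed = 1, period = "historic")
f2 <- fit_geographic_cline(x[h2], est$q[h2], seed = 1, period = "modern")
f1; f2
estimate_movement(f1, f2, interval_years = 36)
```

prints

```
geographic cline (n = 60, period historic): pmin = 0.000, pmax = 1.000, centre = 0.09 km, width = 9.86 km
geographic cline (n = 60, period modern): pmin = 0.004, pmax = 1.000, centre = 6.08 km, width = 8.21 km
cline shift: 6.00 km over 36 years (0.167 km/yr)
```

— the fitted centres bracket the planted 5.66 km shift (60 individuals per
period at 15 sites; sampling noise of roughly half a kilometre is expected
at this size), and the rate is the shift divided by the 36-year interval.
`run_pipeline()` chains all stages (filtering, ancestry, clines, genomic
clines, genome scan, climate) behind one seeded config and writes CSV
artifacts plus a run manifest; `make_report()` condenses a run into the
headline numbers.

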