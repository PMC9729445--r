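---
title: "Models and methods in hzshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hzshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hzshift quantifies the movement of a two-taxon hybrid zone between two
sampling periods and the per-locus heterogeneity of introgression across
it. This vignette is the package's account of the models it fits, the
assumptions behind them, the tunable parameters that matter, and the
numerical and design choices that were genuinely open.

## The generative model

Everything in the package is organised around one generative picture,
which the synthetic-data module implements literally and the inference
modules invert.

Two parental gene pools (species 0 = the southern taxon, species 1 = the
northern taxon; in the chickadee system, Carolina and black-capped) have
per-locus allele frequencies $p_{0\ell}, p_{1\ell}$. A *divergent* locus
has a large frequency difference ($p_1 \sim U(0.95, 1)$,
$p_0 \sim U(0, 0.05)$ in the simulator); the remaining loci are shared
($p_0 = p_1 \sim U(0.05, 0.95)$) and carry no ancestry information.

Sampling sites sit on a transect crossing the zone. The site's expected
ancestry follows the sigmoid geographic cline

$$p(x) = p_{\min} + \frac{p_{\max} - p_{\min}}{1 + e^{-4 (x - c)/w}},$$

where $x$ is the signed perpendicular distance (km) from a baseline laid
along the interface, $c$ is the cline centre and $w$ the width. The factor
4 makes $w$ the conventional width — the inverse of the maximum slope of
the scaled sigmoid. Each period has its own centre; the planted difference
$\Delta c = c_2 - c_1$ is the movement the pipeline must recover.

An individual at distance $x$ draws its true hybrid index
$h \sim \mathrm{Beta}(\nu p(x), \nu (1 - p(x)))$. The concentration $\nu$
(default 50) gives cline fitting realistic within-site scatter instead of
deterministic site values. At each locus, each of the two allele copies is
of species-1 ancestry with probability

$$\Phi(h; \alpha, \beta) = h + 2h(1 - h)\left(\alpha + \beta(2h - 1)\right),$$

clamped to $[0, 1]$, and the allele is then drawn from that species'
frequency. $\alpha$ shifts a locus's ancestry towards one species
relative to the genomic background; positive $\beta$ steepens the
locus-specific cline (ancestry tracking the genomic background more
tightly than typical — restricted introgression, the signature of barrier
loci), negative $\beta$ flattens it. $\Phi(0) = 0$ and $\Phi(1) = 1$ for
any $(\alpha, \beta)$: pure individuals are pure at every locus. Copies
are independent across loci (free recombination between RAD markers),
matching the independence assumption of the genomic-cline likelihood.
Calls go missing independently with a fixed per-call rate.

Planted outlier loci default to the divergent class
(`outliers_divergent = TRUE`): loci that resist introgression are the
strongly differentiated ones, and a locus with $p_0 = p_1$ has a flat
genomic-cline likelihood, so nothing could be learned from it anyway.

## Ancestry estimation

`hybrid_index_ml()` maximises, per individual, the binomial likelihood
$g_\ell \sim \mathrm{Bin}(2,\; h\,p_{1\ell} + (1-h)\,p_{0\ell})$ over
$h \in [0, 1]$, using parental frequencies smoothed with a pseudocount
(default 0.5) so boundary frequencies cannot produce infinite
log-likelihoods. The likelihood is concave in $h$; the optimum is located
from a coarse grid refined by bounded 1-D optimisation, and the 95%
interval is the profile-likelihood region at a drop of 1.92 log units
(the asymptotic $\chi^2_1$ cutoff; no standard interval convention exists
for the hybrid index, so this is the package's choice). Missing
genotypes drop out of the likelihood (missing-at-random); no imputation is
done anywhere except PCA.

`admixture_em()` is the panel-free alternative: K = 2 maximum-likelihood
admixture alternating (i) an exact per-individual maximisation of $q$
given the component frequencies — implemented as vectorised bisection on
the score of the concave 1-D likelihood — and (ii) an EM update of the
component frequencies given $q$. Both half-steps are ascent steps, so the
log-likelihood is non-decreasing; this is asserted every iteration.
Label switching is resolved after fitting, by anchor panels when given and
otherwise by requiring the individual with the highest PC1 score to have
$q > 0.5$; the run itself is never constrained. Five random restarts are
the default; the test suite and experiments use two to three, which on
simulated transects reach the same optimum.

Orientation convention: $q$ is species-1 (northern/black-capped) ancestry
everywhere inside the package. A southern-referenced hybrid index is
$1 - q$ at reporting time. Classification uses two rules: pure if
$q \ge 0.99$ (or $\le 0.01$), hybrid if neither cluster exceeds 0.95
(boundary inclusive), and the remainder — caught by neither rule — is
labelled backcross-like.

`genotype_pca()` is verification-only: column-mean centring, column-mean
imputation of missing calls, optional binomial scaling, scores from the
eigendecomposition of the individual-by-individual covariance. Its only
analytical role is the sanity check that PC1 correlates with the
model-based ancestry estimates.

## Geographic clines and movement

Cline fitting is box-constrained least squares of $q$ on $p(x)$ with
seeded multi-start (20 random restarts around data-driven starting
points). Least squares rather than a trait-model MCMC is a deliberate
simplification: the response is a bounded mean over hundreds to thousands
of loci, its residuals are near-Gaussian, and uncertainty is delegated to
a nonparametric bootstrap over individuals (percentile CIs; degenerate
resample fits are dropped and counted). A fit with
$p_{\max} - p_{\min} < 10^{-3}$ or constant $q$ is flagged degenerate
($w$ unidentifiable) and refuses downstream use.

The transect projection is a local equirectangular approximation about the
baseline anchor (east km $= \Delta\mathrm{lon} \cdot 111.320
\cos(\mathrm{lat}_0)$, north km $= \Delta\mathrm{lat} \cdot 110.574$),
adequate within the $\sim$100 km extent of a typical transect (the test
suite checks pairwise distances against the haversine within 1%).
Movement is reported along the perpendicular axis only — the analysis
assumes the interface translates without rotating — as
$\Delta c = c_2 - c_1$ with rate $\Delta c / \Delta t$, $\Delta t$
defaulting to the difference of the period anchor years. The CI for
$\Delta c$ differences independently resampled draws from the two
periods' bootstrap centre distributions.

Period comparisons expose Welch's t (Satterthwaite df), the Mann-Whitney
U (exact for small tie-free samples, otherwise the normal approximation
with tie correction — the `stats::wilcox.test` policy), and a
two-proportion z test without continuity correction.

The inverse-distance-weighted ancestry surface exists for visual QC of the
interface only; grid nodes coincident with a sample take that sample's
value, and values are clipped to $[0, 1]$. Movement is never quantified
from the surface.

## Genomic clines

Per-locus $(\alpha, \beta)$ are sampled by componentwise random-walk
Metropolis with independent $N(0, \sigma_p^2)$ priors (default
$\sigma_p = 1$; the hierarchical prior of the original genomic-cline
software is not reproduced). The likelihood uses called genotypes,
$g_i \sim \mathrm{Bin}(2, \pi_i)$ with
$\pi_i = \Phi(h_i)\,p_1 + (1 - \Phi(h_i))\,p_0$, smoothed frequencies
strictly inside $(0,1)$, and an optional symmetric genotype-error rate
$\epsilon$ (default 0). Two design decisions matter:

* **Hybrid indices are fixed** at the ancestry module's estimates rather
  than jointly sampled. With hundreds to thousands of loci, $\hat h$ is
  precise; fixing it makes loci conditionally independent, so each locus
  gets its own chain and the sampler parallelises trivially (the kernel is
  C++). The cost — ignoring $\hat h$ uncertainty — is measured directly by
  the truth-table recovery tests.
* **Proposal scales are tuned during burnin only** (towards 0.2–0.5
  acceptance, in blocks of 100 iterations), keeping the post-burnin chain
  a valid fixed-kernel Metropolis sampler.

Chain defaults mirror the study scale (50,000 states after 25,000 burnin,
thinned by 5); the test suite and acceptance experiments run 5,000 + 2,500
— the vignette-scale choice that keeps the full suite in minutes while the
diagnostics (acceptance rates 0.2–0.5, convergence cross-checks between
independent chains) stay clean. `check_convergence()` compares posterior
medians between a long and a short chain and flags loci moving more than
0.1.

Outlier classification follows the joint rule: a locus is a $+\beta$
outlier (say) only if its 95% equal-tail interval excludes 0 *and* its
median is at or above the 99% quantile of all loci's $\beta$ medians.
Quantiles are computed across all loci genome-wide, per parameter, per
side — so each of the four directional categories is capped near the tail
fraction (1%) by construction. A consequence worth stating: when
posteriors are informative (shrinkage factor near 1), essentially every
quantile-tail locus also passes the interval rule, so the *union* of the
four categories approaches 3–4% of null loci even though no single
category exceeds ~1%. Calibration statements in the tests are therefore
per category.

## Genome scan

The chromosome composition test compares each chromosome's outlier
category counts ($+\alpha$ only, $-\alpha$ only, $+\beta$ only, $-\beta$
only, multi-category, non-outlier) against expectations from genome-wide
proportions with $G = 2\sum O \ln(O/E)$, df = (categories with $E > 0$)
$- 1$, no small-sample correction by default (a Williams correction is
exposed). "Consecutive" positive-β loci means adjacent in the
position-sorted, filtered marker list of one chromosome — marker adjacency,
not base-pair distance, which is the natural unit for RAD data. The
permutation null shuffles flags genome-wide while each chromosome keeps
its marker count, and

$$p = \frac{1 + \#\{\text{permutations with max run} \ge \text{cutoff}\}}
          {1 + n_{\text{perm}}}.$$

This $p$ is the null probability of seeing any qualifying run by chance;
it *increases* with the number of flagged loci (more flags make chance
runs easier), and when fewer loci are flagged than the cutoff no
arrangement qualifies and $p = 1$ by convention.

## Climate trends

Rasters travel as ESRI ASCII grids (plain text, bit-exactly testable; the
reader/writer is in-package because no installed raster package was
available, and the format is a six-line header plus a matrix). Window
means are cellwise over an inclusive 5-year range, a cell going to nodata
if any contributing year is nodata. The rate convention divides the
difference of window means by (end-window final year − start-window final
year), e.g. 2016 − 1980 = 36. Buffers are Euclidean in degrees (0.5° by
default, ~55 km at these latitudes) — deliberately not geodesic, matching
how such buffers are usually specified. Regional means are unweighted
over cells; over ≤ 1° of latitude the area distortion is below other error
sources. The contrast is $100 (\bar r_A - \bar r_B)/\bar r_B$: "+50%"
reads "region A warmed 50% more per year than region B".

## What the simulator does and does not emulate

Emulated: divergent parental pools with reference panels, a two-period
transect with a planted centre shift, Beta-distributed individual ancestry
around the site cline, per-locus $(\alpha, \beta)$ deviations including a
consecutive positive-β run on the Z chromosome, multi-SNP RAD loci (for
exercising the one-SNP-per-locus filter), uniform RAD-style missingness,
and two-region climate trends with i.i.d. cell noise.

Not emulated: linkage within and between RAD loci, genotyping error and
allele dropout, uneven missingness across individuals or loci, selection
changing $(\alpha, \beta)$ through time, drift between the sampling
periods, spatially autocorrelated climate noise, and read-level data.
Passing recovery tests therefore demonstrates correctness of the
estimators under their own assumptions — not robustness to these
violations, which on real data must be judged with the usual diagnostics
(PCA cross-check, convergence cross-chains, bootstrap spread).

## Numerical choices and degenerate inputs

* Parental-frequency smoothing (pseudocount 0.5) guards every likelihood
  against $\log 0$; the diagnostic-locus panel deliberately uses *raw*
  frequencies, since fixed differences are a statement about observed
  panels.
* $\Phi$ is clamped to $[0,1]$ before the binomial likelihood; genotype
  probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$.
* Sites with equal lowest positions on a RAD locus tie-break by input
  order; the singleton filter counts allele copies (minor-allele count
  exactly 1), so a lone homozygote (two copies) is retained.
* Individuals with all genotypes missing get flagged, undefined estimates;
  loci with an empty panel are flagged undefined and excluded from
  likelihood-based stages.
* Experiment scales: 20 replicates × 1,000 loci × ~130 individuals for
  shift recovery (bootstrap 200 per period inside the replicate loop);
  2,000 loci × ~180 individuals × 5,000 + 2,500 states for the
  genomic-cline calibration; 500 loci for ancestry accuracy; a 20 × 40
  cell, 41-year stack for the climate contrast. These are the package's
  test-scale choices; function defaults keep the study-scale values.

## Known limitations

The movement estimate assumes pure translation of a one-dimensional
interface; rotating or locally deforming zones need 2-D cline surfaces,
which are out of scope. Cline *width* change between periods is
deliberately not compared — with transect ends sampled differently across
periods, width is the first casualty of design imbalance. The genomic
cline model treats loci as exchangeable and independent given $h$;
physically linked markers violate this and inflate run lengths, which is
precisely why run significance is judged against a permutation null
rather than an analytic one. The K = 2 admixture estimator does not
explore K, and the package takes two-cluster structure as given.
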