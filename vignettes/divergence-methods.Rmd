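---
title: "Comparing phenotypic and neutral genetic divergence with pstfst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing phenotypic and neutral genetic divergence with pstfst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pstfst)
library(dplyr)
```

## The scientific question

When wild populations of one species differ in a quantitative trait — body
mass, limb length, skull dimensions — the difference may reflect random
genetic drift or directional natural selection. The classical way to
separate the two is to compare divergence in the trait with divergence at
neutral molecular markers. Neutral divergence is measured by the fixation
index $F_{ST}$; divergence in additive genetic values of a trait is
measured by $Q_{ST}$. Under drift alone the two have the same expectation,
so traits with $Q_{ST} \gg F_{ST}$ point to divergent selection.

$Q_{ST}$ requires breeding designs that are impossible for most wild (and
all protected) mammals, so field studies substitute $P_{ST}$, computed
directly from wild phenotypes:

$$
P_{ST} \;=\; \frac{c\,\sigma^2_B}{c\,\sigma^2_B + 2 h^2 \sigma^2_W},
$$

where $\sigma^2_B$ and $\sigma^2_W$ are the between- and within-population
variance components of the trait, $h^2$ is the narrow-sense heritability
within populations, and $c$ is the proportion of the between-population
variance assumed to be additive genetic. `pstfst` implements this
comparison end to end — genotype input and filtering, diversity indices,
Weir–Cockerham $F_{ST}$, ANOVA variance components and $P_{ST}$,
environmental distance matrices and Mantel tests — together with a
simulator that generates studies with known ground truth, so every stage
can be validated without access to any particular field data set.

The package ships one worked example: the published site covariates and
per-population diversity indices of a five-population study of the
Hengduan-Mountain vole *Eothenomys miletus*, used to validate the
diversity–environment correlation stage against printed values.

## Data model and conventions

Genotypes are held as an individuals × SNPs matrix of alternate-allele
dosages (0/1/2, `NA` for a missing call) plus a population label per
individual (`genotype_matrix()`). All estimators are pairwise-complete:
missing calls are skipped, never imputed. SNP filtering
(`filter_snps()`) keeps a SNP when its call rate is at least 0.8 **and**
its pooled minor-allele frequency is at least 0.05; both boundaries are
inclusive, matching the usual reading of "exclude SNPs present in fewer
than 80% of individuals or with MAF below 5%". MAF is pooled over all
populations (a panel-level filter, as PLINK applies it), not
per-population.

Coordinates in the packaged site table are printed as `D°MM′SS″` strings
whose minute/second fields exceed 59 at four of five sites; they are
therefore parsed as decimal fractions written in digit pairs
(`28°35′14″ → 28.3514`). This dialect reproduces the published
latitude correlations to three decimals; a sexagesimal reading does not.

## Genetic diversity indices

Per population (over SNPs polymorphic in the whole panel, not
re-ascertained per population):

* $H_o$: fraction of heterozygous calls;
* $H_e = 2pq$ from within-population frequencies;
* Nei unbiased gene diversity $\frac{2n}{2n-1} 2pq$;
* PIC (Botstein): $1 - p^2 - q^2 - 2p^2q^2$;
* $\theta_\pi$: summed unbiased per-site heterozygosity divided by an
  explicit surveyed length `surveyed_bp`. Reduced-representation data
  survey a genome fraction that is not recoverable from the SNP table, so
  a per-site value is only defined once the surveyed length is supplied;
  the published per-site magnitudes (~$3\times10^{-5}$) imply such a
  normalization without printing the length, which is why the worked
  example validates correlations (scale-invariant), never the raw
  $\theta_\pi$ row.
* Tajima's $D$ with the standard 1989 constants. Dosage data are
  unphased and per-SNP call counts vary, but the constants require one
  chromosome count, so $n_{chr}$ is twice the floored median per-SNP call
  count, and SNPs called in fewer than 80% of that median are excluded
  from the segregating-site count.

## Weir–Cockerham $F_{ST}$

`wc_fst_pair()` implements the 1984 moment estimator $\theta$ from the
per-locus components $a$ (among populations), $b$ (among individuals
within populations) and $c$ (within individuals), combined across loci by
ratio of sums — the standard small-sample choice. Each pair of
populations uses only its own two samples. Monomorphic-in-pair loci are
skipped; slightly negative estimates are reported as computed (clamping
would distort the estimator's distribution, which the tests rely on).
`linearize_fst()` applies Rousset's $F_{ST}/(1-F_{ST})$ for
isolation-by-distance regressions, and `nm_from_fst()` the island-model
migrant estimate $(1-F_{ST})/(4F_{ST})$ — an equilibrium idealization
reported for comparability, not a demographic inference.

## $P_{ST}$ and its sensitivity analysis

Variance components come from the classical Sokal–Rohlf one-way
random-effects ANOVA (`anova_components()`), with
$n_0 = (N - \sum n_i^2/N)/(k-1)$ for unequal group sizes and negative
between-component estimates truncated to zero so $P_{ST}$ stays in
$[0,1]$. Pairwise $P_{ST}$ (`pairwise_pst()`) uses a two-group ANOVA per
population pair, mirroring pairwise $F_{ST}$; a global all-population
$P_{ST}$ (`global_pst()`) is available for reference. Defaults are
$c = 1$ (no environmental variance difference between samples) and
$h^2 = 0.5$, the convention for wild small-mammal morphometrics; both are
arguments everywhere. Because $c$ is the least defensible constant, two
sensitivity tools are provided:

* `h2_sensitivity()` re-evaluates all $P_{ST}$ cells over
  $h^2 \in \{0.25, 0.5, 0.75, 1\}$ at $c=1$ and reports the fraction of
  trait × pair cells exceeding $F_{ST}$ (nonincreasing in $h^2$; the
  $h^2=1$ value is the conservative end).
* `critical_c()` solves $P_{ST}(c) = F_{ST}$ in closed form,
  $c_{crit} = 2h^2\sigma^2_W F_{ST} / (\sigma^2_B (1-F_{ST}))$: a trait
  whose plausible $c$ is far above $c_{crit}$ supports selection robustly.

`pst_vs_fst_test()` runs Welch two-sample t-tests of a trait's pairwise
$P_{ST}$ values against the pairwise $F_{ST}$ values (one-sided
"greater" is the divergent-selection alternative). `pooled = TRUE`
performs a single study-level test of all trait × pair values — the
comparison a violin plot of $P_{ST}$ with $F_{ST}$ overlaid
(`plot_pst_fst()`) shows. No multiple-testing correction is applied
across traits, matching field practice for this design; readers should
treat per-trait p-values accordingly.

### Estimator attenuation — a caveat the simulator exposes

With $k$ populations the between mean square has only $k-1$ degrees of
freedom, and for pairwise $P_{ST}$, $k = 2$. The ratio
$\hat\sigma^2_B/(\hat\sigma^2_B + \hat\sigma^2_W)$ is therefore a concave
function of a 1-df chi-square-like draw, and its expectation sits well
below the plug-in truth: with a true between proportion of 0.5, the mean
pairwise estimate is about 0.33 (about 0.43 for a five-group ANOVA) — no
amount of per-group sample size removes this, because the noise lives in
the number of populations. The test suite checks the estimator against an
exact sampling-distribution oracle rather than against the naive plug-in
value, and users should read individual pairwise $P_{ST}$ cells as noisy:
the study-level comparison against $F_{ST}$, not any single cell, is the
supported inference.

## Distances and matrix tests

Geographic distances are haversine great-circle distances (radius
6371 km) via `geosphere`. Altitude and temperature distances are absolute
differences. Climate distances use the Pearson-distance convention
$d = 1 - r$ between sites' bioclim profiles after z-scoring each variable
across sites (so variables with large units do not dominate); the
temperature subset is BIO1–BIO11 and the precipitation subset BIO12–BIO19,
the standard WorldClim partition.

`mantel()` correlates lower triangles and permutes rows and columns of
the second matrix jointly; `p = (\#\{r_{perm} \ge r_{obs}\} + 1)/(n_{perm}+1)`
so p is never zero, with `exact = TRUE` enumerating all $n!$
permutations for small $n$ (the tests verify the sampled p against this
enumeration). The default tail is one-sided "greater" because
isolation hypotheses are directional; the default `n_perm = 9999`.
`partial_mantel()` residualizes both matrices on a control matrix over
the triangles and permutes the residualized second matrix. A matrix
explained exactly by the control leaves only floating-point noise, which
is treated as zero association rather than correlated garbage.
`matrix_regression()` is the descriptive OLS companion; its nominal
p-values are not reported because distance pairs are not independent.

Per-trait group differences use one-way ANOVA with Fisher's LSD post-hoc
letters (`trait_anova_lsd()`): pairwise t-tests on the pooled within mean
square with $N-k$ df, deliberately uncorrected (that is the definition of
LSD), summarised as a compact letter display at $\alpha = 0.05$.

## The synthetic-study generator

`simulate_study()` emulates the motivating field design: 5 montane
populations × 32 diploids, 10^4 unlinked biallelic SNPs, 22 traits, a
site gradient spanning altitudes 2183–3459 m against annual mean
temperatures 19.7–4.7 °C, 5% missing genotype calls, default
differentiation $F = 0.124$.

* **Genotypes** follow the Balding–Nichols model: ancestral frequency
  uniform on [0.05, 0.95], population frequencies
  $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ (variance $Fp(1-p)$), dosages
  Binomial(2, $p_i$) — Hardy–Weinberg within populations, differentiation
  $F$ between. This directly parameterizes the quantity the estimators
  target; linkage, ascertainment and demographic history are deliberately
  not modeled, so passing recovery tests demonstrates estimator
  correctness, not robustness to real SLAF-seq artifacts.
* **Traits** are population effect + Normal residual. The drawn
  population effects are centred and rescaled so their realized sample
  variance equals `sigma2_b` exactly. With only five populations, raw
  Normal draws would leave chi-square noise of the same order as the
  target in the realized between-population variance, and the recorded
  "true $P_{ST}$" would describe no particular data set; rescaling makes
  the truth record exact while keeping the relative configuration of
  populations random. Trait values are Gaussian and independent across
  traits — real morphometrics are correlated and right-skewed, so tests
  passing here say nothing about trait-correlation structure.
* **Sites** place populations on a line with equally spaced altitudes and
  temperature linear in altitude (optional noise), mimicking a montane
  sampling transect.

All randomness flows from one seed through fixed per-component offsets,
so genotypes, traits and sites can be regenerated independently.

## Numerical and design choices

* Filter boundaries inclusive; missing sentinel is `NA`, never imputed.
* $F_{ST}$: ratio-of-sums across loci; negative values passed through.
* $\sigma^2_B$ truncated at zero; `pst_value()` returns 0 when
  $\sigma^2_B = 0$.
* Population labels are sorted lexicographically wherever matrices are
  built, so all distance matrices align by construction.
* Mantel p-values use +1 smoothing; permutations are seeded and
  reproducible bit-for-bit.
* The worked example compares r² after rounding to 3 decimals with a
  ±0.002 band: the published diversity indices are printed to 3 decimals
  themselves, which limits reproduction accuracy; the
  nucleotide-diversity row (3 significant figures) and one Tajima-D cell
  cannot round-trip and are flagged `reproducible = FALSE` / reported but
  not counted.

## Problem sizes used in validation

The shipped tests and the acceptance script use 10^4 SNPs for single-run
estimator recovery, 2 × 10^3 SNPs inside replicated scenarios
(100 replicates for detection, 10 for drift calibration, 200 for
variance-component recovery and Mantel size), and 200-draw permutation
nulls. These sizes give Monte-Carlo error comfortably below the asserted
tolerances while keeping a full run to a few minutes on one CPU; they are
the package's chosen validation conditions, and nothing in the code
depends on them.

## Known limitations

* $P_{ST}$ inference inherits all caveats of substituting phenotypic for
  additive genetic variance; $c$ and $h^2$ are assumptions, not
  estimates. The sensitivity tools quantify, but cannot remove, this.
* The external reproduction of a full published SNP data set (archived
  on a public repository) is out of scope here: the pipeline starts at a
  genotype matrix, and the validation strategy rests on the worked
  example plus simulations with known truth.
* No haplotype statistics, no linked loci, no selection scans, no
  demographic inference.

## A complete synthetic analysis

```{r pipeline, eval = FALSE}
sim <- simulate_study(sim_config(sigma2_b = 1.5, sigma2_w = 1, seed = 7))
report <- run_divergence_pipeline(
  sim$genotypes, sim$traits, sim$sites,
  config = divergence_config(n_perm = 999)
)
report$fst_summary
report$pst_fst_test
autoplot(report$fst)
plot_pst_fst(report$pst, report$fst)
```
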