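---
title: "Models and methods behind divscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind divscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

divscan implements the statistical machinery of a short-term two-line
divergent selection experiment genotyped on a medium-density SNP chip: the
motivating setting is a pair of broiler lines selected up and down for
breast-muscle ultimate pH over five generations, with the founder cohort
(G0) genotyped and available as an ancestral reference, and a sixth
generation measured for two correlated muscle-pH traits. This vignette
describes the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## The drift null and the kinship matrix

All selection-signature scans compare observed population differentiation
with the expectation under pure genetic drift. Drift is summarised by a
kinship matrix `F`: `F[i, i]` is the inbreeding coefficient accumulated by
population `i` since the common ancestral population, and `F[i, j]` the
drift shared by `i` and `j`. The matrix is built in three steps:

1. **Reynolds distances** between all genotyped cohorts (G0, low line, high
   line). We use a bias-corrected ratio-of-sums coancestry estimator: per
   locus, `num = (p_i - p_j)^2 - vhat_i - vhat_j` (the `vhat` terms remove
   finite-sample noise using the observed allele counts) and
   `den = pbar(1 - pbar) + num/4`; the distance is `sum(num)/sum(den)` over
   loci. The estimator is deliberately calibrated on the drift scale: under
   pure drift `d(i, j)` estimates `F_i + F_j`, so that tree branch lengths
   below can be read directly in drift units. The classical pair-coancestry
   normalisation differs by a factor two; with our calibration the
   pure-drift identity `F = 1 - (1 - 1/(2N))^g` is recovered without any
   rescaling, which is what the effective-size conversions assume.
2. **Neighbour joining** (via ape) on the distance matrix, rooted at the
   midpoint of the outgroup's terminal branch. The outgroup *is* the
   ancestral reference, so its own drift is set to zero; negative NJ branch
   lengths (sampling noise) are clamped to zero with a warning.
3. `F[i, j]` = summed length of the branches shared by the root-to-i and
   root-to-j paths; the tree-metric bound `F[i, j] <= min(F[i, i], F[j, j])`
   is enforced.

`ne_from_inbreeding()` inverts `F = 1 - (1 - 1/(2N))^g`. For the study's
printed inbreeding values (0.08 and 0.068 over five generations) this gives
effective sizes of ~30 and ~36 diploid reproducers; note that converting a
rounded F moves the second value slightly above the printed 35.

## FLK

At a biallelic SNP with ancestral (outgroup) frequency `p0` and line
frequencies `p`, the FLK statistic is the quadratic form
`(p - p0)' V^{-1} (p - p0)` with `V = p0 (1 - p0) F` restricted to the
selected lines. Under neutral drift it is approximately chi-squared with
degrees of freedom equal to the number of selected lines (2 here, because
the ancestral frequency is taken from the genotyped outgroup rather than
estimated jointly). Numerical choices: SNPs whose outgroup frequency is
within 1e-6 of 0 or 1 are skipped (the statistic is undefined there and the
normal approximation to drift is poorest); `V` is inverted through an
SVD-based pseudo-inverse so near-singular kinship matrices degrade
gracefully.

The chi-squared null is asymptotic in population size. At `Ne ~ 30` and five
generations the exact Wright-Fisher distribution has slightly less mass in
the upper tail, so the realised type-I error at nominal 0.05 is ~0.046.
A green calibration test therefore establishes agreement at the
per-scan scale (binomial noise of a 2,000-SNP panel), not exactness to the
third decimal.

## The haplotype-cluster HMM and hapFLK

Local haplotype diversity is modelled with a Scheet-Stephens style cluster
HMM fitted directly to unphased genotypes: at each SNP every haplotype
belongs to one of `K` clusters; along the chromosome a haplotype either
keeps its cluster or, with per-interval probability `rho[l]`, jumps to a
cluster drawn from locus-specific weights `alpha[l, ]`. A diploid individual
is an unordered pair of cluster paths; we implement the equivalent ordered
pair chain (`K^2` states) whose factorised transitions allow O(K^2)
forward-backward updates. Emission probabilities combine the per-cluster
allele frequencies `theta[l, k]` binomially; missing genotypes emit
probability 1. EM maximises the likelihood; every accepted iteration
increases it (this is asserted in the tests), and convergence is declared at
a relative change below 1e-6. Multiple random restarts are kept: the hapFLK
statistic is averaged across runs (it is invariant to cluster relabelling),
while cluster-frequency displays use the best run, because averaging
frequencies across runs would mix arbitrary label permutations.

Defaults: `n_em_runs = 3` for pipeline use and tests — trajectory-style fits
with 3 runs are reported to lead to the same interpretation as full-scale
fits — with 50 runs available via configuration for production scans.
`K` defaults to 12 in the pipeline (the value selected by masking
cross-validation on chip data of this density); `select_K()` implements the
masking cross-validation for other panels. EM initialisation draws `theta`
uniformly in [0.05, 0.95] with uniform weights, seeded for reproducibility.

hapFLK applies the FLK quadratic form to each cluster frequency in turn
(outgroup cluster frequency playing the role of `p0`) and sums over
clusters; clusters absent from the outgroup are skipped. Because cluster
frequencies are model outputs, no closed-form null is available: following
standard practice the genome-wide statistic distribution is summarised by a
normal whose location and scale are estimated by regressing the order
statistics of the lower body of the distribution (5th-65th percentile ranks)
on standard normal quantiles. Excluding the entire upper tail — not merely
the extreme 5% — keeps the fit stable when a few percent of loci carry real
signal: with 1% of values replaced by extreme outliers the fitted location
and scale move by less than 1%.

Regions are built from SNPs at q-value <= 0.05 (Storey q-values with a
lambda = 0.5 null-proportion estimate, falling back to Benjamini-Hochberg
when the estimate is unstable), merged when closer than 1 Mb. Regions found
at different generations are unioned when they overlap or when the gap
between them contains no genotyped SNP; the merged region records the sorted
generations of detection.

## Trajectory tests

For FLK outliers outside hapFLK regions, a Monte-Carlo test asks how likely
drift alone is to move a frequency from `p0` (observed in G0) at least as
far as observed at G5. Two neutral simulators are provided: a haploid
Wright-Fisher binomial chain of size `N` (from the FLK effective-size
estimate, haploid `N = 2 Ne`), and a sex-structured chain tracking male and
female reproducer counts per generation with the four-binomial transition.
The p-value is the proportion of simulated endpoints `pj` with
`(pj - p0)^2 >= (pf - p0)^2`, reported with its binomial standard error, and
the two lines are combined by multiplying their p-values. Starting
frequencies that fall off the copy-count grid are snapped to the nearest
count with a warning. Tests default to 1e5 simulations (the study scale of
1e7 is configurable); for one generation the Monte-Carlo estimate is checked
against exact binomial enumeration.

## Bayes C-pi QTL mapping

Phenotypes are first pre-corrected by OLS for sex and hatch (optionally
line: the "within-line" variant fits line as an additional covariate, which
is equivalent to a fixed line effect in the mean model). The marker model is
a point-mass/normal mixture: each SNP is in the model with probability `pi`
(Beta(0.5e4, 99.5e4) prior, pinning `pi` near 0.005) and then carries a
`N(0, sigma2_a)` additive effect. Variances have scaled inverse chi-squared
priors with 4.2 degrees of freedom and scale `S2 = sigma2_hat (nu - 2)/nu`.
Gibbs updates sample (indicator, effect) jointly per SNP from the exact
marginal odds, then the mean, the variances and `pi`.

The prior point value `sigma2_hat` for the marker-effect variance is the
package's main elicitation choice: half the phenotypic variance treated as
genetic and divided over *all* markers (`Vg / (M * mean 2pq)`). The
alternative convention that divides by the expected number of *included*
markers makes the slab so diffuse that pure-noise traits reach Bayes factors
in the hundreds; with the per-marker convention noise panels stay below
BF 20 while planted QTL of 5% variance rank at the top of the scan, which is
the regime the evidence thresholds (BF 20-150 strong, >150 very strong)
assume. Both conventions are available through `prior_spec()`.

The default MCMC schedule for tests is 40,000 iterations, 8,000 burn-in,
thinning 40 — a 10x scaled-down version of the production schedule
(400,000/80,000/400), which is available via configuration. Posterior
inclusion probabilities are smoothed as `(count + 0.5)/(S + 1)` so Bayes
factors stay finite; missing dosages are mean-imputed per SNP. QTL regions
merge SNPs with BF >= 20 closer than 1 Mb and are extended by 1 Mb flanks.

## Post-hoc summaries

LD is the squared dosage correlation (composite LD, the standard unphased
chip estimator) for same-chromosome pairs under 500 kb with MAF > 0.1.
Region-category means report spread both across pairs and across per-region
means (both conventions exist in the literature; outputs carry both). The
enrichment of QTL evidence inside selection signatures is a two-sided Welch
t-test on Bayes factors inside versus outside candidate regions; Welch
rather than the pooled-variance variant because the two groups differ
greatly in size and variance.

## The synthetic study

No genotype data are deposited for the motivating experiment, so the package
ships a generator that emulates its design at desk scale and provides ground
truth for every stage: founders whose haplotypes are recombinant mosaics of
a small ancestral pool (blockwise LD, 2,000 SNPs on 5 chromosomes at 60 kb
spacing by default); two traits with heritabilities ~0.4, genetic
correlation 0.54, residual correlation 0.2 and pH-like means (5.9, 6.35);
and six generations of two-line divergent sib selection — the best 19% of
sires and 50% of dams chosen on the mean phenotype of their full sibs
excluding themselves (the measured sibs are "slaughtered"), with ~27
reproducing sires and ~70 dams per line, 51 genotyped G0 sires, ~20
genotyped sires per line per generation and a phenotyped G6 cohort of 558
birds (253 males, 305 females). G0 selection uses own phenotype since
founders have no sib structure. An optional single large QTL (10% of
phenotypic variance by default in the pipeline configuration) provides a
known target for the end-to-end enrichment check.

What the generator does *not* emulate: coalescent-exact founder LD spectra,
mutation, genotyping error, BLUP-based selection indices (a sib mean stands
in for the breeding value), overlapping generations, or the real chip's
ascertainment. A green end-to-end test therefore establishes that the
machinery detects the signals this stated world produces — not that it
reproduces the study's region counts, which would require the undeposited
data.

## Known limitations

- The FLK chi-squared null is asymptotic; its tail is slightly conservative
  at effective sizes around 30 (see above).
- The hapFLK normal null is an empirical approximation; p-values far in the
  tail inherit its error.
- Reynolds/NJ kinship assumes pure drift; migration or admixture between
  lines would bias the tree.
- The Gibbs sampler is single-chain; convergence is addressed by the long
  default schedule and seeded reproducibility rather than formal
  diagnostics.
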