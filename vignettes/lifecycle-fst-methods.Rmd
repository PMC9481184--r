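---
title: "Detecting sex-differential selection with life-cycle between-sex F_ST"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-differential selection with life-cycle between-sex F_ST}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexfst)
```

## The problem

Sexually antagonistic (SA) alleles benefit one sex and harm the other;
sexually concordant (SC) alleles help or hurt both, possibly unequally.
Because Mendelian inheritance equalises autosomal allele frequencies between
the sexes at every fertilisation, sex-differential selection leaves only
faint, within-generation frequency signals, and naive between-sex comparisons
are riddled with confounders: mis-mapped reads from the sex chromosomes,
sex-biased population structure, and non-random sampling.

`sexfst` implements a life-cycle framework for extracting these signals from
a genotyped cohort with offspring counts (lifetime reproductive success,
LRS). The generation is split into two episodes:

* **zygote to adult** (viability): sex-differential survival shows up as a
  difference between adult female and male allele frequencies
  $\hat p_f, \hat p_m$;
* **adult to gamete** (reproduction): sex-differential LRS shows up as a
  difference between each sex's *projected gametic* frequency and its adult
  frequency. The projection weighs each adult's alleles by their realised
  LRS:
  $$\hat p_s' = \frac{S_{11} + \tfrac12 S_{12}}{S_{11}+S_{12}+S_{22}},$$
  with $S_{ij}$ the cumulative LRS of sex-$s$ adults of genotype $ij$.

Four per-site statistics summarise the episodes ($\bar p = (\hat p_f + \hat
p_m)/2$, likewise $\bar p'$):

| metric | definition | signal |
|---|---|---|
| adult $F_{ST}$ | $(\hat p_f-\hat p_m)^2 / 4\bar p(1-\bar p)$ | sex-differential survival (and participation bias) |
| reproductive $F_{ST}$ | $((\hat p_f'-\hat p_f)-(\hat p_m'-\hat p_m))^2 / 4\bar p(1-\bar p)$ | sex-differential LRS; immune to participation bias |
| gametic $F_{ST}$ | $(\hat p_f'-\hat p_m')^2 / 4\bar p'(1-\bar p')$ | total fitness |
| unfolded reproductive $F_{ST}$ | $z_m z_f$ with $z_s = (\hat p_s'-\hat p_s)\big/\sqrt{\tfrac{\hat p_s(1-\hat p_s)}{2N_s}\tfrac{\sigma_s^2}{\mu_s^2}(1-\hat F_{IS}^s)}$ | sign: negative = SA-like, positive = SC-like |

Here $\mu_s,\sigma_s^2$ are the sex's mean and variance of LRS, $N_s$ its
genotyped adult count, and $\hat F_{IS} = P_{het}/2p(1-p) - 1$ with the
*heterozygote-excess-positive* sign convention (the reverse of Wright's).
All of these are computed per site over the individuals genotyped at that
site, so missingness propagates into the per-site null.

## Null distributions and scaling

With no sex-differential selection, each squared metric divided by a per-site
multiplier is $\chi^2_1$:

* adult: $1/8N_f + 1/8N_m$;
* reproductive: $\sum_s \hat p_s(1-\hat p_s)\,\sigma_s^2 (1-\hat
  F_{IS}^s)/2N_s\mu_s^2$, applied to $4\bar p(1-\bar p)\,\hat F_{ST}$;
* gametic: $\sum_s (1+\sigma_s^2/\mu_s^2)/8N_s$.

The unfolded metric needs no scaling: it is already a product of two
(asymptotically) standard normal deviates, so its null is the product-normal
distribution, with density $K_0(|x|)/\pi$ and conditional tail means
$\pm 2/\pi \approx \pm 0.637$. `per_site_pvalues()` integrates the Bessel
density for two-tailed per-site p-values; `draw_theoretical_null()` samples
either null.

Empirical nulls come from single-permutation schemes chosen per metric:
permuting *sex labels* (adult, gametic — destroys all between-sex structure
while fixing pooled frequencies) or permuting *LRS within sex* (reproductive,
unfolded — keeps any adult frequency differences, e.g. from viability
selection or participation bias, while destroying genotype–LRS
associations). The permutation count defaults to one, which is all a
genome-wide cumulative test needs; tests in this package that quantify
calibration precisely use larger simulated panels instead.

The comparison battery (`compare_to_null()`) mirrors standard practice:
two-sample Wilcoxon and Kolmogorov–Smirnov tests on LD-pruned sites, a
top-percentile enrichment chi-square (cut at the null draws' empirical 99th
percentile by default; the analytic $\chi^2_1$ quantile behind a flag), and a
1,000-replicate bootstrap over sites for the mean difference, its percentile
95% CI and a two-sided empirical p-value (floored at $1/n_{boot}$).

## Site quality control

Biobank-standard thresholds (defaults): MAF $\ge$ 0.01, missing rate $\le$
0.05, exact Hardy–Weinberg p $\ge 10^{-6}$, imputation INFO $>$ 0.8. The HWE
test is the exact (Wigginton-style) enumeration, the conservative biobank
default; the text sources for this pipeline do not pin the HWE test variant,
and we filter on the combined sample.

Three artefact tests target read mis-mapping from the sex chromosomes, each
BH-FDR-corrected across sites at $q < 0.05$:

1. **Bounded excess heterozygosity.** Under SA selection at a polymorphic
   equilibrium the expected $\hat F_{IS}$ is at most
   $1/2n + \tfrac{p(1-p)}{4}\left(\frac{s_{max}}{1-p\,s_{max}}\right)^2$ with
   variance $1/n$. With $s_{max} = 0.2$ — selection stronger than any
   plausible polygenic SA effect — a one-tailed Z-test flags sites whose
   heterozygosity not even strong SA selection could explain.
2. **Minor-homozygote deficit**: one-tailed binomial test of the observed
   minor-homozygote count against the $p^2$ Hardy–Weinberg expectation.
3. **Sex-differential missingness**: 2×2 chi-square (no continuity
   correction by default; a flag enables Yates for small panels).

Tests 1–2 run on the combined sample and on each sex; a site fails if
flagged in any group. Note that a minor-homozygote deficit at fixed allele
frequency mechanically implies a heterozygote excess, so those two flags
co-occur on genuinely artefactual sites — the families are still corrected
and reported separately because their sensitivities differ at the margins.

## Structure-corrected analogues

Sex-biased sampling from genetically distinct subpopulations inflates adult
(and gametic) $F_{ST}$ with no selection at all. The package re-derives the
metrics from regression GWAS with principal-component adjustment:

* `gwas_of_sex()`: per-site logistic regression of sex (1 = female, so the
  sign of the log-odds $\hat L$ matches $\hat p_f - \hat p_m$) on dosage,
  covariates and the top $k = 20$ PCs; $L_{ST} = (\bar p(1-\bar p)\hat L)^2$
  is the adult-$F_{ST}$ analogue. The printed standardiser is used verbatim;
  a `sqrt_standardiser` flag offers $(\sqrt{\bar p(1-\bar p)}\,\hat L)^2$
  because the typography of the source formula is ambiguous.
* `gwas_of_lrs_by_sex()`: per-site OLS of LRS on dosage within each sex
  (exact via Frisch–Waugh residualisation), feeding
  $t = (\beta_F-\beta_M)/\sqrt{SE_F^2+SE_M^2-2\rho\,SE_F SE_M}$ and
  $\text{unfolded } t = \beta_F\beta_M/(SE_F SE_M)$, with $\rho$ the
  between-sex Spearman correlation of effects over LD-pruned loci.

A deliberate design deviation: the original analyses used BOLT-LMM
mixed-model kinship correction, which is out of scope here; fixed-effect PC
adjustment replaces it. At the simulated scales used for validation
(two-subpopulation Balding–Nichols structure), PC adjustment removes the
confound essentially completely; on real data with fine-scale structure a
mixed model remains preferable.

A second, subtler point: when sex and ancestry are *strongly* associated, a
global sex-label permutation changes the logistic regression's information
content (fitted probabilities move from 0.8/0.2 towards 0.5), so the permuted
$L_{ST}$ null is on a slightly wrong scale even though confounding has been
removed. For such designs `permute_sex_labels(strata =
sex_propensity_strata(...))` permutes within sex-propensity strata — a
conditional randomisation that preserves each individual's structure profile.
The global permutation remains the default, matching standard usage; the
stratified variant is used in this package's own structure-confound
validation, where the simulated sex–ancestry association is deliberately
extreme (80/20 vs 20/80 sampling).

## Modes-of-evolution tests

Given user-supplied annotations (the package computes none of them):
Spearman metric–MAF correlations with a 1,000-replicate bootstrap contrast
against null data; between-population $F_{ST}$ (the same kernel as adult
$F_{ST}$); allele-age associations adjusted for the age–frequency confound
(default: centring age within 20 ALT-frequency quantile bins, mirroring the
quantile-averaging display convention; rank-residual adjustment as an
option); OLS of log between-population $F_{ST}$ or 10-kb-windowed Tajima's D
on a metric with MAF as covariate (windows are half-open
$[10000k, 10000(k+1))$ per chromosome; zero $F_{ST}$ values are dropped
before the natural log, with a count logged); and logistic regression of
balancing-selection candidate status on a metric with MAF covariate.

## The cohort simulator

`simulate_cohort()` is the package's test harness and defines its reference
study conditions. Defaults: 20,000 adults per sex, 5,000 unlinked diallelic
sites, ancestral ALT frequencies uniform on (0.05, 0.95) — comfortably inside
the MAF filter so every simulated site carries signal about calibration
rather than about thresholds — and Poisson LRS with mean 1.8 in both sexes
(a post-reproductive human cohort value). A negative-binomial option
($\sigma^2/\mu^2 = 1.5$ by default) covers human-like overdispersion.

The life cycle is generative, not metric-based: zygotes are drawn at
Hardy–Weinberg equilibrium with equal frequencies in the sexes; viability
selection thins a 3× oversampled zygote pool by weighted sampling without
replacement (Efraimidis–Spirakis keys, keeping realised adult counts exact)
with weight $\prod_j (1 + s^{viab}_{j,sex}\, g_j/2)$; LRS is drawn with mean
$\mu_{sex} \prod_j (1 + s^{repr}_{j,sex}\, g_j/2)$, *normalised to mean 1
within each sex* — relative fitness — so polygenic presets with hundreds of
selected loci keep the cohort's mean LRS at $\mu$ instead of drifting
exponentially. Selection presets place $s = 0.1$ at 10% of sites (SA:
$+s/-s$ on LRS; SC equal/unequal; viability-SA). Population structure is a
two-deme Balding–Nichols model ($F = 0.05$) with sex-biased sampling
fractions (80/20 vs 20/80 by default); LD is emulated by a Gaussian-copula
block model on haplotypes, sufficient for pruning and hitchhiking checks but
not a recombination simulation. Artefact injection (genotype masking,
optionally sex-biased; conversion of minor homozygotes to heterozygotes)
runs last, emulating the mis-mapping signatures the QC module hunts.

What the simulator does *not* emulate: participation bias, realistic human
demography or LD decay, X-linked variation, assortative mating, and
fine-scale (continuous) structure. Passing calibration and power tests on
simulated cohorts therefore demonstrates internal consistency of the
estimators and filters, not robustness to every real-data pathology.

## Numerical choices and degenerate inputs

* Frequencies and metrics return `NA` (never an error) at monomorphic sites,
  zero per-sex LRS totals, zero LRS variance, or $(1-\hat F_{IS}) \le 0$;
  downstream comparisons drop NAs and log counts.
* LRS variance uses the unbiased $n-1$ estimator (the sources are silent).
* The reproductive-scaling normaliser uses $\bar p$ (consistent with the
  metric's own denominator); the alternative pooled-frequency reading
  differs only at $O(\Delta p^2)$.
* Half-called genotypes are treated as missing (conservative).
* Repeat LRS assessments: the monotonicity check (no later report smaller
  than an earlier one) runs first, then the maximum is taken.
* LD pruning removes the lower-MAF member of an offending pair, ties broken
  by removing the later genomic position; r² is estimated on a capped,
  evenly spaced subset of individuals (default 5,000), ample precision for a
  0.2 threshold.
* PCA caps the site panel (default 2,000, evenly spaced) and fixes component
  signs by the largest-loading-positive rule.
* Bootstrap empirical p-values are two-sided, floored at $1/n_{boot}$.

## Validation problem sizes

The shipped test-suite checks run at sizes chosen to make Monte-Carlo error
small relative to each assertion: neutral calibration at the reference
conditions (5,000 sites × 20,000/sex; scaled-metric means within $1 \pm
0.06 \approx 3$ SE, tail shares within $1\% \pm 0.5\%$, KS p > 0.01);
orthogonality and SA/SC sign recovery at 3,000 sites × 6,000–8,000/sex; the
structure confound at 1,500 sites × 3,000/sex; artefact sensitivity at
40,000 genotyped adults. `scripts/acceptance.R` recomputes the same
quantities from scratch at the same sizes.

## Known limitations

* Fixed-effect PCs, not a mixed model, correct structure (see above).
* The per-site theoretical nulls are asymptotic; at very small $N$ or
  extreme MAF the chi-square calibration degrades before the MAF filter
  would admit such sites.
* Only diallelic autosomal SNPs; no phasing, imputation or dosage
  uncertainty (hard GT calls only).
* Candidate-gene mapping, allele ages, Tajima's D and external-population
  frequencies are consumed as user tables, never computed.
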