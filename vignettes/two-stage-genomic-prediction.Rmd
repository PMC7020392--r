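---
title: "Two-stage GWAS-informed Bayesian genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage GWAS-informed Bayesian genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genomic selection in non-model tree species often has to work with
low-density marker panels: a SNP array designed for commercially important
relatives may yield only a few thousand informative markers once
cross-species genotyping, call-rate and minor-allele-frequency filters have
taken their toll. With ~4k SNPs on a genome of several hundred Mb, much of
the genome is far from any marker, and a whole-genome regression alone
leaves predictive signal on the table. `gsqpred` implements and evaluates a
two-stage response to this situation, for open-pollinated progeny trials —
the workhorse design of forest-tree breeding, in which each family shares a
known mother and an unknown mixture of pollen parents.

## The two competing models

Both models work on pre-corrected records $y^\*$: the trait is first
regressed on block indicators (and population-structure covariates when
available) by ordinary least squares, and $y^\*$ are the residuals
(`adjust_phenotypes()`). Ordinal ratings (stem straightness, flowering
intensity, bifurcation height) are treated on their numeric scale
throughout, matching common practice of fitting linear Gaussian models to
field ratings.

**Traditional model (GS).** All informative markers plus a pedigree
polygenic effect:

$$y^\* = 1\mu + \textstyle\sum_{i=1}^{m} x_i m_i + Za + \varepsilon, \qquad
a \sim N(0, \sigma^2_a A), \quad \varepsilon \sim N(0, \sigma^2_e I)$$

where $x_i \in \{0,1,2\}$ counts copies of one allele, $m_i$ is the marker
effect under one of four priors (below), and $A$ is the numerator
relationship matrix from the pedigree.

**Two-stage model (GSq).** Stage 1 is a mixed-model association scan
(`scan_markers()`): each marker is tested as a fixed effect alongside
structure covariates, with a random polygenic effect whose covariance is
proportional to the marker kinship and with variance components estimated
once on the null model and reused for every marker (the P3D/EMMAX scheme —
the per-marker REML alternative is computationally heavier and changes
little at this scale). Markers passing both a raw threshold $p < 0.001$ and
a Benjamini–Hochberg FDR $< 10\%$ (both strict) are the marker–trait
associations (MTAs). Stage 2 adds a QTL-genotype random effect whose
covariance $Q$ is the realized (VanRaden) relationship computed over the
significant markers only, while the regression term keeps the
*non-significant* markers:

$$y^\* = 1\mu + \textstyle\sum_{i \notin \text{MTA}} x_i m_i + Za + Zq +
\varepsilon, \qquad q \sim N(0, \sigma^2_q Q).$$

The published description of $Q$ is a matrix of IBD probabilities from
significant SNPs; with unphased SNP data the realized genomic relationship
over that subset is the standard estimator of exactly that quantity, so
`qtl_Q()` delegates to the same estimator as the full-panel kinship.

## Marker priors and the Gibbs sampler

Four classic whole-genome-regression priors are implemented in one
single-site Gibbs sampler (`fit_wgr()`, Rcpp core):

* **BRR** — one common variance $\sigma^2_{SNP}$ for all marker effects;
* **Bayes A** — a per-marker variance with a scaled-inverse-$\chi^2$ prior;
* **Bayes B** — a point mass at zero with probability $\pi$ (fixed, default
  0.95) plus a Bayes-A-type slab;
* **Bayes C$\pi$** — a point mass plus a common slab variance, with $\pi$
  sampled from its Beta(1,1) posterior.

Kernel effects ($a$, and $q$ for GSq) are sampled in the eigenbasis of
their covariance matrix: after the one-off eigendecomposition, each
coordinate has an independent scalar full conditional, which turns the
otherwise $O(n^3)$ correlated-effect update into $O(n^2)$ per sweep — the
decision that makes 490-tree kernels cheap. Eigenvalues below $10^{-10}$
are pinned to zero-effect coordinates. All variance components have
scaled-inverse-$\chi^2$ full conditionals.

**Hyperpriors.** Degrees of freedom 4.2 everywhere; scales are solved so
that the prior expectation of each variance component splits half the
phenotypic variance equally among the genetic terms, leaving half to the
residual (the familiar $R^2 = 0.5$ heuristic of whole-genome-regression
software). For Bayes B the slab scale is inflated by $1/(1-\pi)$ so the
implied genomic variance is comparable across priors. These defaults
matter little for prediction at $n \approx 500$ but keep variance
partitions stable on weak traits.

**Deviance and DIC.** Each retained sample contributes the Gaussian
residual deviance $-2 \log f(y^\*\mid\theta)$ conditional on all sampled
effects; `dic()` combines the posterior mean deviance $\bar D$ with
$p_D = \bar D - D(\bar\theta)$, the deviance at the posterior means of all
parameters. Model comparison uses $\Delta DIC = DIC_{GS} - DIC_{GSq}$
(positive favours the two-stage model) with the conventional bands:
$|\Delta| > 10$ strong, $5\text{–}10$ substantial, $< 5$ not significant.

**MCMC sizes.** The package default is 30,000 iterations with 5,000
burn-in and thinning 10. These conjugate samplers mix quickly (effective
sample sizes for variance components are typically in the hundreds at
these settings), and production-length chains (e.g. $10^6$ with $10^5$
burn-in) are a configuration change, not a code change. The analysis
drivers and the acceptance computations use 2,500–12,000 iterations, sizes
chosen so the whole suite turns around in minutes while leaving Monte
Carlo error well inside the tolerances being tested.

## Heritability partition

Per retained draw, with a common denominator:

$$\hat h^2_a = \frac{\sigma^2_a}{\sigma^2_a+\sigma^2_m+\sigma^2_q+\sigma^2_e},
\qquad \hat h^2_m, \hat h^2_q \text{ analogous},$$

averaging the per-draw ratios (the proper posterior of a ratio) rather
than taking a ratio of posterior means. The genomic variance $\sigma^2_m$
is derived from the SNP-effect variances with allele-frequency weighting:
$\sigma^2_m = 2\sigma^2_{SNP}\sum_i p_i(1-p_i)$ for the common-variance
priors and $\sigma^2_m = 2\sum_i p_i(1-p_i)\sigma^2_{SNP_i}$ for the
per-marker priors, with Bayes-B markers currently at zero contributing
nothing (`marker_variance()`).

## Predictive ability

`cross_validate()` partitions individuals into $k$ near-equal random folds
(default 20), refits the model without the held-out fold, and predicts
$\hat y^\* = \sum_i x_i \hat m_i + Z\hat u$ (plus $Z\hat q$ for GSq),
where kernel effects at held-out individuals are the joint-normal
conditional means $K_{\text{new,train}}K_{\text{train}}^{-1}\hat u$.
Predictive ability is the Pearson correlation between $\hat y^\*$ and the
held-out records, averaged over folds. Two deliberate choices:

* MTA selection is done once on the full data and held fixed across folds.
  This mirrors the two-stage procedure as published (cross-validation of
  the *prediction* models); re-selecting within folds would measure a
  different, more pessimistic quantity.
* Folds are simple random, not family-stratified; a stratified option
  would be a small extension but the trials analysed here have families
  spread across all folds by construction.

## The synthetic trial generator

No genotype or phenotype data accompany the study system this package
targets, so `sim_config()`/`sim_trial()` generate trials with the same
statistical structure, plus a truth record for parameter-recovery grading:

* **Design.** 49 open-pollinated families × 10 genotyped offspring
  (490 trees) in 30 randomized complete blocks with single-tree plots;
  each offspring occupies a distinct block within its family.
* **Markers.** 3,879 biallelic SNPs spread evenly over 11 chromosomes with
  sorted uniform positions; ancestral minor allele frequencies uniform on
  (0.1, 0.5) so the simulated panel survives the MAF filter largely
  intact. No linkage disequilibrium beyond that induced by family and
  subpopulation structure is simulated: LD enters the analysis only
  descriptively, and the composite-r² estimator is exercised by the
  structure-induced correlation itself.
* **Structure.** Founders come from three subpopulations diverged from the
  ancestral pool by Balding–Nichols beta sampling. A subpopulation with
  divergence $F_s$ has allele frequencies
  $p_s \sim \text{Beta}(p(1-F_s)/F_s,\,(1-p)(1-F_s)/F_s)$, and the expected
  pairwise Weir–Cockerham $F_{ST}$ between subpopulations $i, j$ is
  approximately $(F_i+F_j)/2$. The default divergences (0.056, 0.116,
  0.444) were solved from the three pairwise values reported for the
  target population (0.086, 0.25, 0.28); the published values are not
  labelled by pair, so the assignment of values to pairs is the package's
  own.
* **Mating.** Each offspring draws one Mendelian allele from its dam and
  one from either the dam again (selfing, probability `selfing_rate`) or a
  pollen-pool draw from the dam's subpopulation frequencies. The default
  selfing rate is 0 — pure half-sib families, consistent with the default
  maternal-sib relationship of 0.25 in `pedigree_A()`. Eucalypt trials
  often show partial selfing; both the selfing rate and the
  open-pollinated sib coefficient are exposed so a mixed pollen cloud and
  its matching relationship adjustment can be simulated and fitted
  together.
* **Traits.** Each trait is a sum of block effects, a few QTLs (marker
  columns with fixed effects scaled so each explains its stated fraction
  of the unit non-block phenotypic variance), an $A$-structured polygenic
  value, a diffuse marker background ($X w$ with i.i.d. normal $w$ — the
  BRR generative model), and Gaussian residual. Ordinal traits threshold
  the latent value at equiprobable quantiles by default (the published
  rating scales give levels but not category frequencies); explicit
  thresholds can be supplied.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: ascertainment-skewed (L-shaped) allele
frequency spectra, within-chromosome LD and recombination, genotyping
error, dominance and epistasis, genotype-by-environment interaction, and
spatial field trends beyond the block structure. In particular the
simulated panel's expected heterozygosity (~0.37) is higher than is
typical of a cross-species array panel, because the MAF spectrum is
uniform rather than L-shaped.

## Recovery experiments: design choices

Two evaluation experiments deserve explanation because their conditions
were fixed by design:

* **Variance-partition recovery** (GSq/BRR on 490 trees, 1,000 markers,
  15 QTLs jointly at 20%, polygenic 20%, marker background 30%) uses a
  *panmictic* founder pool and builds $Q$ from the truth record's QTL
  indices rather than from a fresh scan. Both choices isolate the quantity
  being tested — the sampler's ability to separate $\sigma^2_a$,
  $\sigma^2_m$ and $\sigma^2_q$. With strong structure, the structure
  correction removes part of the marker-background variance (markers are
  differentiated between subpopulations), shifting the estimand itself;
  and 15 QTLs at 1.3% each are underpowered at $p<0.001$, so re-detection
  would grade stage-1 power, which is measured separately.
* **The headline comparison** (GSq beats GS when the planted QTLs carry
  substantial variance) simulates 12 QTLs jointly explaining 36%, runs the
  full two-stage pipeline including detection, and compares 5-fold
  cross-validated predictive ability over 10 seeds. With no planted QTLs
  the scan almost always returns an empty MTA set, in which case the
  two-stage model collapses onto the traditional one by construction.

## Numerical details worth knowing

* Marker columns are centered inside `fit_wgr()`; the stored column means
  are reapplied at prediction time, so reported effects stay on the
  allele-count scale.
* All relationship matrices get an $\epsilon I$ ridge ($\epsilon=10^{-6}$)
  after construction; a $Q$ built from very few markers is rank-deficient
  and this keeps its eigendecomposition and the conditional-mean solve
  stable.
* The REML profile in the scan is optimized on $\log\delta$,
  $\delta = \sigma^2_e/\sigma^2_g \in [e^{-12}, e^{12}]$, after rotating
  into the kinship eigenbasis; Wald p-values use the normal approximation.
* Ties in the LD-kNN imputation vote resolve to the lower genotype code;
  distances are $\ell_1$ on shared non-missing calls over the `l_sites`
  most-correlated markers, and vote weights are inverse distances.
* Same seed, same spec → bit-identical chains: the Rcpp sampler draws from
  R's own RNG stream.

## Known limitations

Ordinal traits are modelled on their numeric scale (no threshold model);
the sampler is single-chain (convergence is monitored by effective sample
size, not split-$\hat R$); DIC at short chain lengths carries visible
Monte Carlo noise, so decision-band verdicts near a boundary deserve a
longer run; and the pipeline estimates no dominance or epistatic
components. The open-pollinated relationship adjustment is a single
coefficient applied to maternal-sib blocks — a pragmatic stand-in for a
full selfing-aware pedigree model.
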