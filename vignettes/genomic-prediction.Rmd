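---
title: "Genomic prediction with dense marker panels: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with dense marker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgsblup)
```

# The problem

Breeding programs increasingly impute chip-genotyped animals up to
sequence-level ("WGS") marker density in the hope of capturing causal
variants directly. Whether that pays off depends on imputation error, on the
linkage-disequilibrium (LD) structure of the dense panel, and on whether the
extra markers are pruned or pre-selected sensibly. **wgsblup** implements the
full analysis loop used to study this question in a pedigreed broiler
population — GBLUP with a genomic relationship matrix, REML variance
components, mixed-model GWAS, LD pruning, GWAS-based variant pre-selection
and repeated cross-validation — together with a population simulator that
provides ground truth for every stage.

# Models

## Genomic relationship matrix

`computeGrm()` builds VanRaden's method-1 matrix

$$G = \frac{MM'}{2\sum_i p_i(1-p_i)}$$

where $M$ is the dosage matrix with $2p_i$ subtracted from column $i$ and
$p_i$ is the observed counted-allele frequency. We center by the *counted*
allele's frequency rather than the minor allele's: centering by the minor
allele is ill-defined when the counted allele happens to be the major one,
and the denominator is identical either way. Missing dosages are replaced by
the column mean ($0$ after centering), which preserves $E[M] = 0$;
monomorphic markers are dropped from numerator and denominator alike.

## REML and GBLUP

The prediction model is $y = Xb + g + e$ with
$g \sim N(0, \sigma_g^2 G)$ and $e \sim N(0, \sigma_e^2 I)$. `fitReml()`
estimates the two variance components by restricted maximum likelihood.
After one symmetric eigendecomposition $G = UDU'$ the rotated covariance is
diagonal, so each iteration costs $O(np^2)$. Iterations are
average-information (AI) steps with step-halving; whenever no AI step
improves the restricted likelihood the solver falls back to a profile step —
a one-dimensional search over the heritability with the total variance
concentrated out in closed form — and a final profile polish is always
applied. Two consequences we rely on in tests: the recorded log-likelihood
trajectory is non-decreasing by construction, and because the profile is
one-dimensional the solver does not stall in local AI failures. Variances
are floored at $10^{-10}\,\mathrm{var}(y)$; convergence is declared when the
log-likelihood or relative parameter change falls below $10^{-8}$. With an
identity relationship matrix only $\sigma_g^2 + \sigma_e^2$ is identifiable;
the solver returns a finite flagged solution rather than failing.

`solveGblup()` computes GLS fixed effects under
$V = \sigma_g^2 G + \sigma_e^2 I$ on the phenotyped samples and genetic
values $\hat g = \sigma_g^2 G[\cdot,\mathrm{train}] V^{-1}(y - X\hat b)$ for
*every* sample in $G$. Validation animals are simply rows of $G$ without
phenotypes — exactly how a cross-validation fold is predicted. On panels
without missing genotypes this is algebraically identical to
ridge-regression SNP-BLUP with marker-effect variance $\sigma_g^2$ divided
by the GRM scale, an identity the test suite checks to $10^{-8}$.

## Mixed-model association

`runMlma()` tests each marker in $y = Xb + sa + g + e$. Variance components
are estimated once under the null model and reused for every marker (the
behavior of the standard MLMA implementations, and orders of magnitude
faster); each marker is then a GLS coefficient with a Wald $\chi^2_1$
p-value. The tested marker stays in the background relationship matrix — no
leave-one-chromosome-out — so a marker's own contribution to $G$ causes mild
proximal contamination; with thousands of background markers the effect is
conservative and small, and the calibration test (genomic-control
$\lambda \in [0.9, 1.1]$ on a structured polygenic null, while naive OLS
inflates past 1.1) shows the polygenic term absorbs family structure as
intended. Monomorphic markers are flagged `tested = FALSE`, never silently
dropped.

## LD pruning and variant pre-selection

`pruneByLd()` follows the PLINK kb-mode convention: windows span 50 kb (by
default) from an anchor marker, the anchor advances by 10 retained markers,
and inside a window the first violating pair in position order loses its
lower-MAF member (ties: the later position). Anchored windows alone cannot
guarantee that *no* retained within-span pair exceeds the cutoff — pairs
straddling skipped anchors can slip through, as they can in PLINK — so a
deterministic cleanup sweep over all within-span pairs runs until the strong
guarantee holds; `verifyPruning()` re-checks it exhaustively. Windows never
cross chromosome boundaries. Retained counts are monotone non-decreasing in
the cutoff over the conventional grid $0.1$–$0.99$.

`selectSignificantRegions()` takes markers with $-\log_{10}p$ above a cutoff
(conventional grid 2–5), expands each seed by $\pm 50$ kb, merges
overlapping intervals (IRanges), and partitions the panel into selected and
remaining variants — always disjoint and exhaustive. Merging before
extraction is required for the partition to be well defined. Two composite
schemes are provided: `s3MarkerSet()` prunes the selected set at
$r^2 = 0.99$ to strip near-duplicates, and `s4MergedSet()` prunes one side
of the partition at a fixed $r^2 = 0.1$ and the other at a varying cutoff
before merging.

## Cross-validated predictive ability

`makeCvPlan()` draws 10 replicates of 5-fold random partitions (fold sizes
within one of each other). Per fold, `runCv()` estimates variance components
on the training samples only, predicts the validation fold through the
relationship matrix, and scores

- accuracy $r(\hat g, p)$: Pearson correlation between predictions and
  phenotypes corrected for fixed effects, and
- bias $b(\hat g, p) = \mathrm{cov}(y_c, \hat g)/\mathrm{var}(\hat g)$, the
  slope of corrected phenotype on prediction, with $b = 1$ meaning
  unbiased. The wording "regression of the predictions and the corrected
  phenotypes" is ambiguous about direction; we adopt the animal-breeding
  convention (phenotype on prediction), under which shrinkage-consistent
  predictions give slope 1.

Fixed-effect correction of the validation fold uses *training* estimates
only; an unseen factor level is an error naming the level. When GWAS-based
selection is requested, the scan itself is re-run inside each training fold
(`gwasPerFold()`), so validation phenotypes never influence marker
selection. Summaries report the mean with both the SD of replicate means
(the conventional parenthesized spread) and the SD over all fold values.

# The simulator

`simulatePopulation()` emulates the statistical structure the analysis
assumes, not a particular genome:

- **Pedigree.** 30 sires each mated to 12 of 360 dams by default — a
  single-generation half/full-sib broiler design; offspring counts per dam
  are configurable.
- **Founder LD.** Haplotypes come from a latent first-order autoregressive
  Gaussian thresholded at per-marker allele frequencies
  ($\mathrm{Unif}(0.05, 0.95)$). The AR parameter (`founderLdDecay`,
  default 0.9 — strong local LD as in closed livestock populations) is the
  only LD dial; adjacent-marker $r^2$ is monotone in it. This is a Markov
  haplotype process, not a coalescent: it gives tunable pairwise LD and
  family structure, which is all the pipeline consumes, but no deep
  population history or distance-dependent decay.
- **Meiosis.** Haldane crossovers (Poisson in map length at 1 cM/Mb,
  uniform positions), so offspring are exact gene-drops of founder
  haplotypes — Mendelian consistency is checkable and checked.
- **Trait.** $y = \mathrm{pen} + \sum_q s_q a_q + e$. QTL effects are
  standard normal (optionally gamma for few-large-effect architectures) and
  rescaled so the realized breeding-value variance equals the target
  heritability with residual variance $1 - h^2$; pen effects
  ($N(0, 0.5^2)$ across six pens by default) sit on top of that unit
  phenotypic scale. Default $h^2 = 0.3$, typical for feed-efficiency traits.
- **Chip vs WGS.** The chip is an evenly spaced fraction (default 10%) of
  the dense panel; by default QTL are drawn from *non-chip* markers, so the
  chip tags causal variants through LD but never contains them — the exact
  contrast between chip and sequence panels the pipeline is built to
  expose.
- **Imputation error and masking.** `corruptGenotypes()` resamples
  genotypes from per-marker Hardy–Weinberg frequencies with a configurable
  error rate (default 3%) — a frequency proxy for real, haplotype-structured
  imputation error, and documented as such; `maskGenotypes()` hides 2% of
  markers entirely for `scoreImputation()`'s per-sample and per-marker
  correlations. Reference panels of different quality are emulated as
  different corruption intensities.

What passing tests show, and do not show: recovery of simulated
heritability, calibration of the association scan, the pruning guarantee
and the chip-vs-causal contrast are all demonstrated *under this
generator*, i.e. under additive architecture, random mating, homogeneous
error and first-order LD. Real data add strand flips, haplotype-correlated
imputation error, selection and non-additive variation that the simulator
deliberately omits.

# Numerical choices and degenerate inputs

- Missing genotypes are a single sentinel (`NA`); every module treats it
  explicitly (mean imputation in GRM and MLMA, pairwise-complete LD,
  call-rate filters in QC).
- QC order is fixed and logged — SNP call rate, sample call rate, MAF, HWE —
  because the later filters depend on which samples survive. The HWE test
  is the Wigginton exact test with a plain (not mid-) p-value, the variant
  conventional with the $10^{-6}$ threshold.
- `hweExactTest` sums probabilities $\le p_{obs}(1 + 10^{-12})$ to absorb
  floating-point ties; monomorphic sites return 1.
- GRM positive semidefiniteness is tolerated to $-10^{-8}$ in eigenvalue;
  singular mixed-model systems raise an error suggesting diagonal
  stabilization rather than silently regularizing.
- Pair-removal ties in pruning (equal MAF) drop the later position, making
  output deterministic.
- Eigendecompositions are computed per training fold; the rotated-space
  REML is identical to dense solves within $10^{-8}$ (tested against a
  dense-algebra oracle).

# Problem sizes used in the shipped checks

The test suite and the acceptance script run the pipeline at desk scale,
chosen so every stage is exercised with meaningful statistics: populations
of 150–900 offspring, panels of 200–3,000 markers over 1–5 chromosomes,
heritabilities 0.3–0.5, 10 replicates of 5-fold cross-validation, 20
replicates for recovery checks, and a 2,000-marker polygenic null for
calibration. The simulator scales linearly in samples times markers, and
REML cubically in training-set size, so production-scale panels are a
matter of compute, not code paths.

# Known limitations

- No dominance or epistatic relationship matrices, and no LD-weighted GRM.
- No actual phasing/imputation engine: the package evaluates and corrupts
  genotypes; running an imputation tool is out of scope.
- The MLMA scan has no leave-one-chromosome-out mode.
- Sex chromosomes are treated like autosomes by the dosage code.
- The corruption model is genotype-frequency resampling; real imputation
  error is correlated along haplotypes and between relatives.
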