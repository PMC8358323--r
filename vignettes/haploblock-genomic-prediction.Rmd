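---
title: "Haplotype-based genomic prediction with LD-threshold haploblocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based genomic prediction with LD-threshold haploblocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Genomic prediction regresses a quantitative trait on genome-wide markers
through a relationship matrix, ranking selection candidates by their
genomic estimated breeding values (GEBVs). Single-SNP models treat every
marker as an independent predictor; when causal variants are poorly
tagged by any single SNP but well tagged by a short local haplotype, a
model whose predictors are *haplotype alleles* — distinct combinations
of alleles at adjacent SNPs transmitted as a unit — can capture more of
the signal. `hapblup` implements that comparison end to end for phased
diploid panels: LD-threshold haploblock construction, haplotype dosage
coding, SNP- and haplotype-based relationship matrices, REML/GBLUP with
one or two genetic components, repeated cross-validation, and a
dependent-correlation test between the competing models' accuracies.

# Models and procedure

## Haploblock construction

For two bi-allelic loci with alleles $A_1/A_2$ and $B_1/B_2$, linkage
disequilibrium is measured from phased haplotype frequencies:

$$D = p_{A_1B_1}\,p_{A_2B_2} - p_{A_1B_2}\,p_{A_2B_1}, \qquad
  r^2 = \frac{D^2}{p_{A_1}\,p_{A_2}\,p_{B_1}\,p_{B_2}}.$$

Because the input is phased, the frequencies are counted directly over
the $2n$ chromosomes — no genotype-based EM approximation is needed.
A haploblock at threshold $t$ is a run of *consecutive* markers in which
**every** pair satisfies $r^2 \ge t$. Construction is a single greedy
left-to-right pass per chromosome: the current block absorbs the next
marker while that marker clears the threshold against every member; on
the first failure the block is closed (emitted if it holds $\ge 2$
SNPs) and a new candidate block starts at the failing marker.

Three design points here were genuinely open and are fixed as follows:

* **Contiguity.** Blocks never skip markers. Non-contiguous cliques
  would make the "non-blocked SNP" set ambiguous, and the downstream
  partition (blocked vs non-blocked) must be a partition.
* **Direction and ties.** One deterministic left-to-right pass, no
  backtracking, no merging across a failed candidate. Any alternative
  (e.g. optimal interval cover) changes counts but not the model class;
  determinism and reproducibility were weighted over optimality.
* **Minimum size 2.** A single-SNP "block" is indistinguishable from
  the SNP itself, so singletons stay in the non-blocked set. No maximum
  span or size is imposed, and no physical gap rule is applied.

The default threshold grid is $t \in \{0.2, 0.3, \ldots, 0.8\}$, the
range over which LD decays in dense bovine panels; the package computes
an LD-decay profile (mean $r^2$ per 1-kb distance bin up to 100 kb,
half-open bins) so users can judge the informative range on their data.

## Dosage coding

Within each block, every haplotype allele *observed* in the panel
becomes a pseudo-marker column; an individual's entry is how many of its
two phased haplotypes carry that allele (0/1/2). Each individual's row
segment within a block sums to exactly 2 — diploidy conservation — which
the tests assert. For a two-SNP block with alleles $AB, Ab, aB, ab$ the
ten possible diplotypes produce the canonical coding (e.g. $AB/AB \to
(2,0,0,0)$, $Ab/aB \to (0,1,1,0)$). Columns are ordered
lexicographically on the internal 0/1 allele string within a block,
blocks in genome order, so the matrix is identical across runs and
platforms. Rare haplotype alleles are retained: a frequency-pruning
floor exists in principle but defaults to keeping everything, since
rare-allele columns cost little and discarding them changes $Q_H$.

## Relationship matrices

The SNP-based matrix follows VanRaden:

$$\mathbf G = \frac{(\mathbf M - \mathbf P)(\mathbf M - \mathbf P)'}
  {2\sum_i p_i (1 - p_i)},$$

with $\mathbf M$ the 0/1/2 counted-allele dosages and $\mathbf P$ the
matrix of column means $2p_i$. One deliberate reading: $p_i$ is the
**counted (ALT) allele frequency**, not the minor allele frequency,
even though the two are sometimes conflated in writing. With MAF in
$\mathbf P$ the centering would break ($E[\mathbf M - \mathbf P] \ne 0$
wherever $p_i > 0.5$) and $\mathbf G$ would be biased; MAF is used only
for the QC filter. Frequencies are fixed once from the full analysis
panel rather than re-estimated per training fold, so a single $\mathbf
G$ serves the whole cross-validation.

The haplotype-based matrix is the uncentred, unscaled product

$$\mathbf G_H = \frac{\mathbf M_H \mathbf M_H'}{Q_H},$$

where $Q_H$ is the total haplotype-allele count. The definition is
implemented exactly as printed — no centring, no frequency scaling — so
its entries are nonnegative and its scale differs from $\mathbf G$'s;
REML absorbs the scale into the variance component, and prediction
accuracy is invariant to it. A centred variant is available
(`haplotype_grm(..., center = TRUE)`) for sensitivity analysis only.

## Variance components and prediction

The single-component animal model is $y = \mathbf 1\mu + a + e$ with
$a \sim N(0, \sigma^2_a \mathbf K)$, $e \sim N(0, \sigma^2_e \mathbf I)$
and heritability $h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)$;
phenotypes are pre-adjusted for fixed effects (sex and year as factors,
entry body weight and fattening days as covariates, via OLS; the
adjusted value is residual plus overall mean), so the mixed model
carries only an intercept. REML uses the eigendecomposition of
$\mathbf K$: the restricted likelihood is profiled down to a 1-D search
over the variance ratio, which cannot fail to converge and is exact to
optimiser tolerance ($10^{-10}$ on the log-ratio).

The two-component model $y = \mathbf 1\mu + a + a_u + e$ puts the
haploblock effects behind $\mathbf G_H$ and the non-blocked SNP effects
behind a $\mathbf G$ built only from non-blocked markers; the two
effects are uncorrelated. Estimation is average-information REML with a
safeguard: the AI step is step-halved until it stays in the parameter
space and does not decrease the restricted likelihood, and if no such
step exists an EM-REML update
($\sigma^2_i \leftarrow \sigma^2_i + (\sigma^4_i/n)(y'PK_iPy -
\mathrm{tr}(PK_i))$) is taken instead. Convergence requires both
$|\Delta \ell_R| < 10^{-6}$ and relative parameter change $< 10^{-6}$,
capped at 200 iterations; variances are floored at
$10^{-10}\,\mathrm{var}(y)$.

Validation GEBVs propagate through the relationship covariance,
$\hat g_{val} = \Sigma_{vt}\,(\Sigma_{tt} + \sigma^2_e \mathbf I)^{-1}
(y_t - \hat\mu)$ with $\Sigma$ the fitted genetic covariance; for
$\mathbf K = \mathbf W \mathbf W'/c$ this reproduces marker-ridge
(SNP-BLUP) predictions to numerical precision, which the test suite
asserts at $10^{-8}$.

## Evaluation

Fivefold cross-validation with 10 random repeats; fold sizes differ by
at most one. Per repeat and model, validation predictions are pooled
over the five folds, then: correlation $r = \mathrm{cor}(y^*,
\mathrm{gebv})$, accuracy $r/\sqrt{h^2}$ (with $h^2$ the whole-data
single-component SNP-GBLUP estimate — computed once, before any model
comparison), and dispersion bias $b = \mathrm{Cov}(\mathrm{gebv},
y^*)/\mathrm{Var}(\mathrm{gebv})$.

Two models' accuracies share the phenotype, so their difference is
tested with the Hotelling–Williams statistic for dependent
correlations,

$$t = (r_{jk} - r_{jh})
  \sqrt{\frac{(n-3)(1 + r_{kh})}{2|R|}}, \qquad
  |R| = 1 + 2 r_{jk} r_{jh} r_{kh} - r_{jk}^2 - r_{jh}^2 - r_{kh}^2,$$

on $n - 3$ degrees of freedom. Three open choices, all flagged in the
output metadata:

* **Pooling level.** The test is applied per repeat on the pooled
  validation predictions (so $n$ = number of individuals), and the
  reported p is the mean over repeats. Per-fold testing would cut $n$
  fivefold; grand-pooling across repeats would pretend the repeats are
  independent observations.
* **Sidedness.** Two-sided by default — the direction of a difference
  is not pre-specified per comparison — with a one-sided option.
* **Re-estimation.** Variance components are re-estimated on every
  training fold (no leakage from validation individuals); a
  whole-data-reuse flag exists for speed.

Its type-I error is verified by simulation: under a trivariate-normal
null with equal population correlations, the empirical rejection rate
at $\alpha = 0.05$ over 5,000 replicates must fall within $\pm 0.01$ of
nominal.

# Quality control

Variant filters in fixed order — call rate $< 0.90$, MAF $< 0.01$,
exact Hardy–Weinberg $p < 10^{-6}$ — each variant counted once under
its first failing filter, then samples with call rate $< 0.90$ over the
retained variants. The HWE test is the exact conditional test
(enumeration of heterozygote counts given allele totals, two-sided by
probability ordering): the chi-square approximation is anti-conservative
exactly where chip QC needs power, at rare alleles. A flag to switch is
deliberately *not* offered; the exact test is strictly preferable at
these sample sizes. Missing genotypes are tolerated only up to QC; all
downstream operations require complete phased data, since phasing and
imputation are upstream concerns for this package.

# The synthetic-data generator

Every claim the test suite and the reproduction script make is computed
on simulated data with known truth, generated by a founder-mosaic model:

* Each block carries a small pool of founder haplotypes (default 4),
  themselves Markov mosaics of two ancestral haplotypes with per-site
  switch probability 0.08 — this makes within-block $r^2$ high on
  average and decaying with distance, the structure LD-threshold
  blocking is built for, with auditable true block boundaries.
* Each gamete picks one founder per block, redrawing its lineage
  between adjacent blocks with probability 0.5 (1 would make blocks
  fully independent); a per-site leakage flip (default 0.02) erodes
  within-block LD, and raising it provably lowers realized $r^2$
  (asserted as a monotonicity test).
* Loose SNPs drawn independently per haplotype sit between blocks, so
  between-block and block-to-loose LD is at $1/(2n)$ sampling noise.
* The trait is additive: effects of the default 100 QTL are i.i.d.
  normal; the residual vector is rescaled so the *realized*
  $\mathrm{var}(g)/(\mathrm{var}(g)+\mathrm{var}(e))$ equals the target
  heritability exactly, rather than in expectation. Sex (2 levels),
  year (8 levels) and two covariates with fixed true coefficients are
  added on top.

The desk-scale preset — 600 individuals, 40 blocks × 8 SNPs plus 80
loose SNPs, 100 QTL, $h^2 = 0.5$ — keeps a full pipeline run around a
minute; the REML recovery study uses 1,000 individuals × 50 replicates.
These sizes were chosen so the whole validation suite completes in a
few minutes while Monte-Carlo error stays well inside the asserted
tolerances (e.g. mean recovered $h^2$ within $\pm 0.03$ of a 0.25
target over 50 replicates).

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: demographic history (bottlenecks,
selection, admixture) and the long-range LD it induces; pedigree
structure and cryptic relatedness; imputation error in the phased input;
allele-frequency spectra skewed toward rare variants; QTL outside the
genotyped marker set. In this simulator every causal variant is
genotyped, which favours the single-SNP model; on real data with
ungenotyped causal variants the haplotype models' relative standing can
differ. The package measures the comparison; it does not prejudge its
winner.

# Numerical choices

* Symmetry/PSD tolerance on relationship matrices: $10^{-8}$ relative;
  matrices are symmetrised as $(\mathbf G + \mathbf G')/2$ after the
  product to absorb floating-point drift.
* Monomorphic markers are an error in LD and GRM construction (zero
  variance, zero denominator contribution) rather than being silently
  dropped: after QC they should not exist, and silence would mask an
  upstream mistake.
* A constant phenotype returns boundary components with an explicit
  warning and $h^2 = 0$ instead of failing.
* Degenerate Hotelling triples ($|R| \le 0$) error, except the exact
  self-comparison limit ($r_{jk} = r_{jh}$), which returns $t = 0$,
  $p = 1$.
* All randomness (simulation, fold assignment) flows from explicit
  integer seeds; fold assignment restores the caller's RNG state.

# Limitations

* Unphased or multi-allelic input is rejected, not handled; phasing
  quality is assumed, and phase errors masquerade as recombination.
* The greedy block scan is order-dependent by design; a different scan
  direction can yield a different (equally valid) partition.
* The two-component REML solves dense $n \times n$ systems per
  iteration; beyond a few thousand individuals a sparse or
  preconditioned implementation would be needed.
* Accuracy scaling by $1/\sqrt{h^2}$ inherits the error of the $h^2$
  estimate; comparisons between models are unaffected (the scaling is
  common to all).
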