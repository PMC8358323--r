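# hapblup

Haplotype-based genomic prediction with LD-threshold haploblocks, for
quantitative geneticists and breeders working with phased SNP panels
(livestock chips or sequence-level data). The package answers one
question end to end: **does modelling short local haplotypes as
pseudo-markers predict breeding values better than modelling the same
SNPs individually?**

## What it computes

Starting from a phased VCF and a phenotype/covariate table:

1. **QC** — variant call rate, MAF, exact Hardy–Weinberg and sample
   call-rate filters.
2. **Haploblocks** — maximal runs of consecutive SNPs in which every
   pair satisfies `r² ≥ t`, with

   `r² = D² / (p_A1 · p_A2 · p_B1 · p_B2)`,  `D = p_A1B1·p_A2B2 − p_A1B2·p_A2B1`,

   counted directly from the phased haplotypes; thresholds sweep
   0.2–0.8 by default. Plus an LD-decay profile (mean r² per 1-kb
   distance bin).
3. **Dosage coding** — each observed haplotype allele in a block
   becomes a pseudo-marker; individuals carry 0/1/2 copies
   (`AB/AB → (2,0,0,0)`, `Ab/aB → (0,1,1,0)`, …); block segments always
   sum to 2.
4. **Relationship matrices** — VanRaden SNP matrix
   `G = (M − P)(M − P)′ / 2Σpᵢ(1−pᵢ)` and the haplotype matrix
   `G_H = M_H M_H′ / Q_H` on the uncentred dosages.
5. **REML / GBLUP** — profile REML (eigendecomposition) for
   single-component models; AI-REML with EM fallback for the
   two-component model `y = 1μ + a + a_u + e` (haploblock effects via
   `G_H` plus non-blocked SNP effects via `G`); heritability
   `h² = σ²ₐ/(σ²ₐ+σ²ₑ)`; GEBV prediction through the relationship
   covariance.
6. **Evaluation** — fivefold cross-validation × 10 random repeats with
   shared folds across models; accuracy `cor(y*, gebv)/√h²`, dispersion
   bias `b = Cov(gebv, y*)/Var(gebv)`, and the Hotelling–Williams
   t-test for the difference of two dependent accuracy correlations.

A founder-mosaic simulator generates phased panels with controllable
block-LD structure and traits of exactly realized heritability, so the
whole pipeline is verifiable against ground truth without any external
data.

## Worked example

```r
library(hapblup)

cfg <- sim_config(n_individuals = 300, n_blocks = 12, n_loose_snps = 24,
                  h2_target = 0.5, n_qtl = 60, seed = 42)
sim <- simulate_haplotype_panel(cfg)
ph  <- simulate_phenotypes(sim$panel, sim$truth, cfg)

res <- run_pipeline(sim$panel, ph$pheno,
                    run_config(r2_thresholds = c(0.2, 0.5),
                               models = c("GBLUP", "GBLUP_In_Block",
                                          "G_H_BLUP", "G_H_BLUP+GBLUP"),
                               k = 5, repeats = 5, seed = 7))
print(res)
```

```
pipeline_result: h2 = 0.434 
block summary:
 r2_threshold haplotype_alleles n_blocks n_blocked_snps snps_per_block
          0.2               309       19             96       5.052632
          0.5               228       24             88       3.666667
 n_non_blocked
            24
            32
cross-validation (means over repeats):
          model r2_threshold    cor accuracy   bias
       G_H_BLUP          0.2 0.6185   0.9389 0.9814
 G_H_BLUP+GBLUP          0.2 0.6204   0.9417 0.9614
          GBLUP          0.2 0.6481   0.9838 0.9906
 GBLUP_In_Block          0.2 0.6380   0.9685 0.9982
       G_H_BLUP          0.5 0.6246   0.9481 0.9805
 G_H_BLUP+GBLUP          0.5 0.6296   0.9557 0.9686
          GBLUP          0.5 0.6481   0.9838 0.9906
 GBLUP_In_Block          0.5 0.6404   0.9722 0.9972
model comparisons (Hotelling-Williams, mean over repeats):
 r2_threshold      model_ref      model_alt t_mean p_mean   n
          0.2 GBLUP_In_Block       G_H_BLUP 1.3927 0.2100 300
          0.2 GBLUP_In_Block G_H_BLUP+GBLUP 1.0560 0.3119 300
          0.5 GBLUP_In_Block       G_H_BLUP 1.3404 0.2446 300
          0.5 GBLUP_In_Block G_H_BLUP+GBLUP 0.7554 0.4649 300
```

Reading the output: the REML heritability estimate on this simulated
trait (true realized h² = 0.5) is 0.434; at `r² ≥ 0.2` the panel
partitions into 19 haploblocks holding 96 of 120 SNPs and 309 haplotype
alleles. Mean cross-validated accuracy (correlation over √h²) is
highest for all-SNP GBLUP here — as expected, since in this simulation
every causal variant is itself genotyped — the dispersion bias of every
model is near 1 (no inflation), and no haplotype-vs-SNP accuracy
difference is significant on these 300 individuals (all mean p > 0.2).

## Analysis workflow

`analysis/` holds the numbered drivers that run the full study on the
simulated population, each writing delimited tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # panel + phenotypes + truth
Rscript analysis/02_qc_and_ld.R         # QC report, LD decay profile
Rscript analysis/03_blocks_and_coding.R # block summary across 0.2..0.8
Rscript analysis/04_heritability.R      # whole-data REML fit and GRM
Rscript analysis/05_cross_validation.R  # 5-fold x 10 CV, four models
Rscript analysis/06_model_comparison.R  # Hotelling-Williams tests
```

## Vignette

`vignettes/haploblock-genomic-prediction.Rmd` documents the models and
their assumptions, the block-construction and coding conventions, the
REML algorithms and their tolerances, the evaluation design (fold
sharing, pooling level for the dependent-correlation test), what the
synthetic-data generator does and does not emulate, and known
limitations.
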