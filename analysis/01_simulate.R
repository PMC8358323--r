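#!/usr/bin/env Rscript
# Simulate the study population: a phased panel with block-LD structure
# (40 blocks x 8 SNPs + 80 loose SNPs, n = 600) and a trait of realized
# heritability 0.5 with sex/year/weight/days fixed effects. Writes the
# phased VCF, the phenotype table and the ground truth under results/data.

library(hapblup)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20240601L)
sim <- simulate_haplotype_panel(cfg)
ph <- simulate_phenotypes(sim$panel, sim$truth, cfg)

write_phased_vcf(sim$panel, file.path(out, "panel.vcf.gz"))
write.table(ph$pheno, file.path(out, "phenotypes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_sim_truth(ph$truth, sim$panel, out)

message("panel: ", n_samples(sim$panel), " individuals x ",
        n_variants(sim$panel), " variants")
message("realized h2: ", round(ph$truth$realized_h2, 4),
        " (target ", cfg$h2_target, ")")
message("written to ", out)
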