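#!/usr/bin/env Rscript
# Step 1: generate the synthetic multi-line pig population.
#
# The study population this emulates is proprietary, so every downstream
# step runs on simulated data: six closed lines, discrete generations,
# litters nested in dams, a tested subset of each litter housed in pens of
# 6-16 animals that mix litters, herd-year-season groups and 23 scorers.
# Bivariate ear/tail damage scores (0-3) arise by thresholding Gaussian
# liabilities with additive-genetic, litter, pen, herd-year-season and
# residual components (h2 = 0.05 per trait, genetic correlation 0.45).

library(pigdamage)

out_dir <- "results/data"
cfg <- sim_config(mode = "ordinal", seed = 111L)
ds <- simulate_dataset(cfg)
write_dataset(ds, out_dir)

tab <- ds$phenotypes
cat("phenotyped animals: ", nrow(tab), "\n")
cat("pedigree animals:   ", length(ds$pedigree$id), "\n")
cat("litters/pens/HYS:   ", length(unique(tab$litter)), "/",
    length(unique(tab$pen)), "/", length(unique(tab$hys_scoring)), "\n")
cat("score distribution (ED03 / TD03):\n")
print(rbind(ED03 = table(factor(tab$ED03, 0:3)),
            TD03 = table(factor(tab$TD03, 0:3))))
cat("true breeding-value variance (ear, tail): ",
    round(diag(var(ds$truth$bv)), 4), "\n")
cat("wrote pedigree/phenotypes/truth/config to ", out_dir, "\n")
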