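#!/usr/bin/env Rscript
# Step 2: variance components, heritabilities and genetic correlations.
#
# Fits the linear animal model (fixed: sex, line, sex x line, scorer, age at
# scoring; random: animal with pedigree covariance, litter, pen group,
# herd-year-season of scoring) by AI-REML to each of the seven damage trait
# definitions, then bivariate models for key trait pairs starting from the
# univariate estimates. Heritabilities are reported with both phenotypic-
# variance conventions (including and excluding the herd-year-season term).

library(pigdamage)

ds <- read_dataset("results/data")
tab <- derive_traits(ds$phenotypes)
ped <- ds$pedigree

uni <- list()
rows <- list()
for (tr in damage_traits()) {
  spec <- model_spec(tr)
  fit <- reml_fit(tab, spec, ped)
  uni[[tr]] <- fit
  h_in <- heritability(fit, include_hys = TRUE)
  h_ex <- heritability(fit, include_hys = FALSE)
  rows[[tr]] <- data.frame(
    trait = tr,
    sigma2_a = fit$vc$variance[1], se_a = fit$vc$se[1],
    sigma2_l = fit$vc$variance[2], sigma2_g = fit$vc$variance[3],
    sigma2_hys = fit$vc$variance[4], sigma2_e = fit$vc$variance[5],
    h2 = h_in$h2, h2_se = h_in$se, h2_no_hys = h_ex$h2,
    logLik = fit$logLik, converged = fit$converged)
  cat(sprintf("%-5s h2 = %.3f (se %.3f)  logL = %.1f\n",
              tr, h_in$h2, h_in$se, fit$logLik))
}
write.csv(do.call(rbind, rows), "results/genetic_parameters.csv",
          row.names = FALSE)

pairs <- list(c("ED03", "TD03"), c("ED03", "ED01"),
              c("TD03", "TD01"), c("TD03", "SD06"), c("ED03", "SD06"))
bres <- list()
for (pr in pairs) {
  spec2 <- model_spec(pr)
  bi <- reml_bivariate(tab, spec2, ped, start_uni = uni[pr])
  bres[[paste(pr, collapse = "_")]] <- data.frame(
    trait1 = pr[1], trait2 = pr[2], rg = bi$rg, rg_se = bi$rg_se,
    converged = bi$converged)
  cat(sprintf("%s-%s  rg = %.3f (se %.3f)\n", pr[1], pr[2], bi$rg, bi$rg_se))
}
write.csv(do.call(rbind, bres), "results/genetic_correlations.csv",
          row.names = FALSE)

# EBVs of the original-scale traits for the selection step, with their
# prediction error variances and model-derived accuracies
ebv <- data.frame(animal = unique(tab$animal))
for (tr in c("ED03", "TD03")) {
  fit <- uni[[tr]]
  ebv[[paste0("ebv_", tr)]] <- unname(fit$ebv[ebv$animal])
  ebv[[paste0("pev_", tr)]] <- unname(fit$pev_all[ebv$animal])
  ebv[[paste0("accuracy_", tr)]] <-
    unname(model_accuracy(fit, pev_values = fit$pev_all[ebv$animal]))
}
write.csv(ebv, "results/ebv.csv", row.names = FALSE)

# within-line analysis: the same model without the line terms, on the two
# largest lines (the across-line analysis above fits line as a fixed effect
# and assumes a common genetic variance)
win <- list()
for (ln in names(sort(table(tab$line), decreasing = TRUE))[1:2]) {
  sub <- tab[tab$line == ln, ]
  wspec <- model_spec("ED03", fixed = ~ sex + scorer + age_days)
  wfit <- reml_fit(sub, wspec, ped)
  h <- heritability(wfit)
  win[[ln]] <- data.frame(line = ln, n = nrow(sub), h2 = h$h2, h2_se = h$se)
  cat(sprintf("within-line %s (n=%d): h2 = %.3f (se %.3f)\n",
              ln, nrow(sub), h$h2, h$se))
}
write.csv(do.call(rbind, win), "results/within_line_h2.csv", row.names = FALSE)
cat("wrote results/genetic_parameters.csv, genetic_correlations.csv, ebv.csv, within_line_h2.csv\n")
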