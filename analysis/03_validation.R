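#!/usr/bin/env Rscript
# Step 3: how reliable are the EBVs? Three validation procedures per trait.
#
# (a) model-derived accuracy from the prediction error variances;
# (b) replicated five-fold cross-validation with phenotypes adjusted for all
#     non-animal effects (random, full-sib and half-sib maskings);
# (c) forward validation by the linear-regression (LR) method, splitting at
#     a birth-date cutoff so the validation set is the youngest generation.

library(pigdamage)

ds <- read_dataset("results/data")
tab <- derive_traits(ds$phenotypes)
ped <- ds$pedigree
cutoff <- "2021-08-01"

cv_rows <- list(); lr_rows <- list()
for (tr in damage_traits()) {
  spec <- model_spec(tr)
  fit <- reml_fit(tab, spec, ped)
  macc <- mean(model_accuracy(fit, pev_values = fit$pev_all[unique(tab$animal)]))
  for (grp in c("random", "full-sib", "half-sib")) {
    reps <- if (grp == "random") 10L else 5L
    cv <- run_cv(tab, ped, spec,
                 cv_scheme(k = 5, replicates = reps, grouping = grp, seed = 7),
                 fit = fit)
    cv_rows[[paste(tr, grp)]] <- cbind(cv$summary, model_accuracy = macc)
  }
  lr <- lr_validate(tab, ped, spec, cutoff, fit = fit)
  lr_rows[[tr]] <- data.frame(trait = tr, accuracy = lr$accuracy,
                              bias_sd_units = lr$bias,
                              dispersion = lr$dispersion, fbar = lr$fbar,
                              n_validation = lr$n_validation)
  cat(sprintf("%-5s model-acc %.3f | CV acc %.3f disp %.3f | LR acc %.3f bias %+.3f disp %.3f\n",
              tr, macc,
              cv_rows[[paste(tr, "random")]]$accuracy,
              cv_rows[[paste(tr, "random")]]$dispersion,
              lr$accuracy, lr$bias, lr$dispersion))
}
write.csv(do.call(rbind, cv_rows), "results/cv_report.csv", row.names = FALSE)
write.csv(do.call(rbind, lr_rows), "results/lr_report.csv", row.names = FALSE)
cat("wrote results/cv_report.csv and results/lr_report.csv\n")
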