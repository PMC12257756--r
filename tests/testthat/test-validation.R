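test_that("adjusted phenotypes keep the animal effect and residual", {
  ds <- small_dataset(seed = 15)
  tab <- ds$phenotypes
  spec <- model_spec("ED03", fixed = ~ sex + scorer + age_days)
  fit <- reml_fit(tab, spec, ds$pedigree)
  y_adj <- adjust_phenotypes(fit)

  # identity: y_adj = animal solution + residual of the full fit
  ia <- fit$ebv[tab$animal]
  resid_fit <- tab$ED03 - as.numeric(fit$design$X %*% fit$b) -
    Reduce(`+`, lapply(names(fit$u), function(tm)
      as.numeric(fit$design$Zlist[[tm]] %*% fit$u[[tm]][fit$design$levels[[tm]]])))
  expect_equal(y_adj, unname(ia) + resid_fit, tolerance = 1e-8)

  # adding a constant moves only the intercept
  tab2 <- tab
  tab2$ED03 <- tab2$ED03 + 5
  fit2 <- reml_fit(tab2, spec, ds$pedigree, start = fit$vc$variance)
  expect_equal(adjust_phenotypes(fit2), y_adj, tolerance = 1e-6)

  # adjusting with the true simulated effects leaves exactly a + e
  tr <- ds$truth
  y_true_adj <- tab$ED03 - tr$fixed_part -
    tr$litter_effects[tab$litter, 1] - tr$pen_effects[tab$pen, 1] -
    tr$hys_effects[tab$hys_scoring, 1]
  ia2 <- match(tab$animal, rownames(tr$bv))
  expect_equal(cor(y_true_adj, tr$bv[ia2, 1] + tr$residuals[, 1]), 1)
})

test_that("fold allocation balances records and respects sib constraints", {
  ped <- new_pedigree(sprintf("A%02d", 1:10), rep(NA, 10), rep(NA, 10))
  tab <- data.frame(animal = sprintf("A%02d", 1:10))
  f <- make_folds(tab, ped, cv_scheme(k = 5, replicates = 3, seed = 1))
  expect_true(all(apply(f, 2, function(x) all(table(x) == 2))))

  # full-sib families never split
  ds <- small_dataset(seed = 17)
  tab <- ds$phenotypes
  fs <- make_folds(tab, ds$pedigree,
                   cv_scheme(k = 5, replicates = 5, grouping = "full-sib",
                             seed = 2))
  ix <- match(tab$animal, ds$pedigree$id)
  fam <- paste(ds$pedigree$sire[ix], ds$pedigree$dam[ix])
  for (r in 1:5)
    expect_true(all(tapply(fs[, r], fam, function(x) length(unique(x))) == 1))

  # one sire over 40 dams: the whole half-sib block stays together
  sire <- "S1"
  dams <- sprintf("D%02d", 1:40)
  kids <- sprintf("K%02d", 1:40)
  ped1 <- new_pedigree(c(sire, dams, kids),
                       c(rep(NA, 41), rep(sire, 40)),
                       c(rep(NA, 41), dams))
  tab1 <- data.frame(animal = kids)
  expect_warning(
    hs <- make_folds(tab1, ped1,
                     cv_scheme(k = 5, replicates = 2, grouping = "half-sib",
                               seed = 3)),
    "larger than n/k")
  expect_true(all(apply(hs, 2, function(x) length(unique(x)) == 1)))
})

test_that("half-sib blocks are connected components of the sib graph", {
  # two sires sharing a dam chain into one component
  ped <- new_pedigree(c("S1", "S2", "D1", "D2", "K1", "K2", "K3"),
                      c(NA, NA, NA, NA, "S1", "S1", "S2"),
                      c(NA, NA, NA, NA, "D1", "D2", "D2"))
  tab <- data.frame(animal = c("K1", "K2", "K3"))
  blocks <- pigdamage:::.sib_blocks(tab, ped, "half-sib")
  expect_equal(length(blocks), 1L)
  # unrelated singletons stay separate
  tab2 <- data.frame(animal = c("S1", "S2"))
  expect_equal(length(pigdamage:::.sib_blocks(tab2, ped, "half-sib")), 2L)
})

test_that("cross-validation reports calibrated accuracy on simulated data", {
  cfg <- sim_config(n_lines = 2, generations = 3, sires_per_gen = 5,
                    dams_per_gen = 40, seed = 19)
  ds <- simulate_dataset(cfg)
  tab <- ds$phenotypes
  spec <- model_spec("ED03")
  fit <- reml_fit(tab, spec, ds$pedigree)
  cv <- run_cv(tab, ds$pedigree, spec, cv_scheme(k = 5, replicates = 3, seed = 5),
               fit = fit, keep_ebv = TRUE)
  expect_equal(nrow(cv$folds), 15L)
  expect_true(cv$summary$accuracy > 0 && cv$summary$accuracy < 1)
  expect_lt(abs(cv$summary$dispersion - 1), 0.5)
  # shuffled EBVs carry no signal
  set.seed(1)
  null_acc <- replicate(20, cor(cv$ebv$y_adj, sample(cv$ebv$ebv)) / cv$h)
  expect_lt(abs(mean(null_acc)), 3 * sd(null_acc) / sqrt(20) + 0.02)
})

test_that("forward split partitions records at the cutoff", {
  ds <- small_dataset(seed = 23)
  tab <- ds$phenotypes
  sp <- lr_split(tab, "2021-08-01")
  expect_equal(sort(c(sp$training, sp$validation)), seq_len(nrow(tab)))
  # generations are separated in time, so the cutoff recovers generation 2
  expect_setequal(tab$animal[sp$validation], tab$animal[tab$generation == 2])
  expect_error(lr_split(tab, "1990-01-01"), "training")
  expect_error(lr_split(tab, "2999-01-01"), "validation")
})

test_that("LR metrics follow their algebraic identities", {
  set.seed(3)
  va <- 0.04
  fbar <- 0.02
  ebv_c <- rnorm(400, 0, sqrt((1 - fbar) * va))
  m <- lr_metrics(ebv_c, ebv_c, va, fbar)
  expect_equal(m$bias, 0)
  expect_equal(m$dispersion, 1)
  expect_equal(m$accuracy, sqrt(var(ebv_c) / ((1 - fbar) * va)))

  ebv_p <- 0.8 * ebv_c + rnorm(400, 0, 0.05)
  m2 <- lr_metrics(ebv_p, ebv_c, va, fbar)
  # dispersion is the OLS slope of complete on partial EBVs
  expect_equal(m2$dispersion, unname(coef(lm(ebv_c ~ ebv_p))[2]),
               tolerance = 1e-10)
  expect_equal(m2$bias, (mean(ebv_p) - mean(ebv_c)) / sqrt(va))

  expect_warning(m3 <- lr_metrics(ebv_p, -ebv_c, va), "negative covariance")
  expect_true(is.nan(m3$accuracy))
  expect_true(m3$cov_negative)
  expect_false(is.nan(m3$dispersion))
})

test_that("forward validation tracks the truth-based accuracy", {
  cfg <- sim_config(n_lines = 2, generations = 3, sires_per_gen = 5,
                    dams_per_gen = 40, seed = 29)
  ds <- simulate_dataset(cfg)
  tab <- ds$phenotypes
  spec <- model_spec("ED03")
  fit <- reml_fit(tab, spec, ds$pedigree)
  lr <- lr_validate(tab, ds$pedigree, spec, "2021-08-01", fit = fit)
  expect_equal(lr$n_training + lr$n_validation, nrow(tab))
  iv <- match(lr$ebv$animal, rownames(ds$truth$bv))
  truth_acc <- cor(lr$ebv$ebv_p, ds$truth$bv[iv, 1])
  expect_lt(abs(lr$accuracy - truth_acc), 0.2)
  expect_lt(abs(lr$bias), 0.3)
})
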