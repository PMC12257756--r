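test_that("design construction checks rank, missing data and incidences", {
  ds <- small_dataset()
  tab <- ds$phenotypes
  spec <- model_spec("ED03", fixed = ~ sex + scorer + age_days)
  des <- build_design(tab, spec, ds$pedigree)
  expect_equal(qr(des$X)$rank, ncol(des$X))
  expect_true(all(Matrix::rowSums(des$Zlist$animal) == 1))
  expect_equal(ncol(des$Zlist$animal), length(ds$pedigree$id))

  # a factor duplicated under another name is fully confounded
  tab2 <- tab
  tab2$sex_copy <- tab2$sex
  expect_error(build_design(tab2, model_spec("ED03", fixed = ~ sex + sex_copy),
                            ds$pedigree), "rank deficient")
  tab3 <- tab
  tab3$age_days[1] <- NA
  expect_error(build_design(tab3, spec, ds$pedigree), "missing values")
  expect_error(build_design(tab[, -1], spec, ds$pedigree), "lacks column")
})

test_that("MME restricted likelihood equals the dense-V oracle", {
  ds <- small_dataset()
  spec <- model_spec("ED03", fixed = ~ sex + scorer + age_days)
  des <- build_design(ds$phenotypes, spec, ds$pedigree)
  prep <- pigdamage:::.mme_prep(des)
  set.seed(1)
  for (rep in 1:3) {
    v <- exp(runif(5, log(0.02), log(0.8)))
    mme <- pigdamage:::.n2ll_uni(v, prep, 1L, new.env())$value
    expect_equal(mme, dense_n2ll(v, des, ds$pedigree), tolerance = 1e-9)
  }
})

test_that("likelihood is invariant to age centering, record order and
           reference levels", {
  ds <- small_dataset(seed = 9)
  tab <- ds$phenotypes
  spec <- model_spec("ED03", fixed = ~ sex + scorer + age_days)
  v <- c(0.05, 0.1, 0.2, 0.1, 0.55)
  ll <- function(tb, sp = spec) {
    des <- build_design(tb, sp, ds$pedigree)
    pigdamage:::.n2ll_uni(v, pigdamage:::.mme_prep(des), 1L, new.env())$value
  }
  base <- ll(tab)
  tab_c <- tab
  tab_c$age_days <- tab_c$age_days - mean(tab_c$age_days)
  expect_equal(ll(tab_c), base, tolerance = 1e-8)
  set.seed(2)
  expect_equal(ll(tab[sample(nrow(tab)), ]), base, tolerance = 1e-8)
  tab_r <- tab
  tab_r$sex <- stats::relevel(factor(tab_r$sex), ref = "M")
  expect_equal(ll(tab_r), base, tolerance = 1e-8)
})

test_that("sparse MME solutions match dense GLS on small data", {
  ds <- small_dataset(seed = 13, dams = 8)
  spec <- model_spec("ED03", fixed = ~ sex + age_days)
  des <- build_design(ds$phenotypes, spec, ds$pedigree)
  expect_lte(des$n, 200)
  v <- c(0.06, 0.08, 0.18, 0.09, 0.5)
  gls <- dense_gls(v, des, ds$pedigree)
  bl <- blup_solve(des, v = v)
  expect_equal(unname(bl$b), gls$b, tolerance = 1e-6)
  expect_equal(unname(bl$ebv), gls$ebv, tolerance = 1e-6)
})

test_that("AI and quasi-Newton REML agree and satisfy the MME at the optimum", {
  ds <- small_dataset(seed = 21)
  spec <- model_spec("ED03", fixed = ~ sex + scorer + age_days)
  fa <- reml_fit(ds$phenotypes, spec, ds$pedigree, method = "ai")
  fl <- reml_fit(ds$phenotypes, spec, ds$pedigree, method = "lbfgs")
  # the AI path must reach at least the quasi-Newton optimum
  expect_gte(fa$logLik, fl$logLik - 1e-6)
  expect_lt(abs(fa$logLik - fl$logLik), 0.05)
  expect_lt(fa$mme_residual, 1e-6)
  expect_true(fa$converged)
  expect_true(fl$converged)
})

test_that("analytic REML gradient matches central finite differences", {
  ds <- small_dataset(seed = 3)
  spec <- model_spec("ED03", fixed = ~ sex + scorer + age_days)
  des <- build_design(ds$phenotypes, spec, ds$pedigree)
  prep <- pigdamage:::.mme_prep(des)
  v0 <- c(0.05, 0.08, 0.15, 0.1, 0.5)
  res <- pigdamage:::.reml_ai(prep, des, d = 1L, t_idx = 1L,
                              start_blocks = lapply(v0, matrix, 1, 1),
                              floor_ = 1e-10, maxit = 0L)  # evaluate at v0
  vf <- vapply(res$blocks, function(b) b[1, 1], 0)
  f <- function(v) pigdamage:::.n2ll_uni(v, prep, 1L, new.env())$value
  gfd <- vapply(1:5, function(k) {
    h <- vf[k] * 1e-6
    vp <- vf; vp[k] <- vf[k] + h
    vm <- vf; vm[k] <- vf[k] - h
    -0.5 * (f(vp) - f(vm)) / (2 * h)
  }, 0)
  expect_equal(res$gradient, gfd, tolerance = 1e-4)
})

test_that("null genetic variance is recovered at the floor", {
  cfg <- sim_config(n_lines = 2, generations = 3, sires_per_gen = 4,
                    dams_per_gen = 25, var_a = 0, seed = 77)
  ds <- simulate_dataset(cfg)
  fit <- reml_fit(ds$phenotypes, model_spec("ED03"), ds$pedigree)
  expect_lt(fit$vc$variance[1], 1e-3)
})

test_that("animal-model REML equals 4x the ANOVA sire component on a
           balanced paternal half-sib design", {
  set.seed(55)
  n_sires <- 100; n_off <- 20
  sires <- sprintf("S%03d", seq_len(n_sires))
  off <- sprintf("O%04d", seq_len(n_sires * n_off))
  ped <- new_pedigree(c(sires, off),
                      c(rep(NA, n_sires), rep(sires, each = n_off)),
                      rep(NA, n_sires + n_sires * n_off))
  sire_eff <- rnorm(n_sires, 0, sqrt(0.05))
  y <- rep(sire_eff, each = n_off) + rnorm(n_sires * n_off, 0, sqrt(0.8))
  tab <- data.frame(animal = off, y = y,
                    sire = rep(sires, each = n_off))
  fit <- reml_fit(tab, model_spec("y", fixed = ~ 1, random = "animal"), ped)
  msb <- n_off * var(tapply(y, tab$sire, mean))
  msw <- sum((y - ave(y, tab$sire))^2) / (n_sires * (n_off - 1))
  sigma2_s <- (msb - msw) / n_off
  expect_equal(fit$vc$variance[1], 4 * sigma2_s, tolerance = 0.02)
})

test_that("heritability follows both denominator conventions with delta SEs", {
  v <- c(animal = 0.05, litter = 0.05, pen = 0.20, hys_scoring = 0.10,
         residual = 0.60)
  h <- heritability(v, include_hys = TRUE)
  expect_equal(h$h2, 0.05)
  expect_true(is.na(h$se))
  h2 <- heritability(v, include_hys = FALSE)
  expect_equal(h2$h2, 0.05 / 0.90)
  expect_equal(heritability(c(animal = 1, residual = 0))$h2, 1)
  expect_error(heritability(c(animal = 0, residual = 0)), "zero")
  # delta-method SE positive when a covariance is supplied
  vc <- diag(c(1e-4, 1e-4, 1e-4, 1e-4, 1e-4))
  dimnames(vc) <- list(names(v), names(v))
  expect_gt(heritability(v, varcov = vc)$se, 0)
})

test_that("model-derived accuracy clamps PEV and decreases in PEV", {
  ds <- small_dataset(seed = 31)
  fit <- reml_fit(ds$phenotypes, model_spec("ED03", fixed = ~ sex + age_days),
                  ds$pedigree)
  va <- fit$vc$variance[1]
  pv <- setNames(c(va, 0, 0.75 * va, 1.2 * va, -0.01), letters[1:5])
  acc <- suppressMessages(model_accuracy(fit, pev_values = pv))
  expect_equal(unname(acc[1:3]), c(0, 1, 0.5))
  expect_equal(unname(acc[4]), 0)   # clamped to PEV = va
  expect_equal(unname(acc[5]), 1)   # clamped to PEV = 0
  expect_equal(attr(acc, "n_clamped"), 2L)
  grid <- seq(0, va, length.out = 11)
  accs <- suppressMessages(model_accuracy(fit, pev_values = setNames(grid, 1:11)))
  expect_true(all(diff(accs) <= 0))
})

test_that("prediction error variances match the dense inverse of the MME", {
  ds <- small_dataset(seed = 41, dams = 6)
  spec <- model_spec("ED03", fixed = ~ sex + age_days)
  fit <- reml_fit(ds$phenotypes, spec, ds$pedigree)
  v <- fit$vc$variance
  prep <- fit$prep
  Cd <- as.matrix(pigdamage:::.assemble_uni(prep, c(1 / v[5], 1 / v[1:4])))
  Ci <- solve(Cd)
  ids <- unique(fit$design$animal)
  cols <- prep$offsets[["animal"]] + match(ids, fit$design$levels$animal)
  expect_equal(unname(pev(fit, ids)), diag(Ci)[cols], tolerance = 1e-8)
  # the AI path stores the same PEVs from the selected inverse
  expect_equal(unname(fit$pev_all[ids]), diag(Ci)[cols], tolerance = 1e-8)
})
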