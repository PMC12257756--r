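test_that("a single generation yields founders only", {
  cfg <- sim_config(n_lines = 2, generations = 1, seed = 1)
  sp <- simulate_pedigree(cfg)
  expect_equal(nrow(sp$groups), 0L)
  expect_true(all(sp$pedigree$sire == 0L & sp$pedigree$dam == 0L))
})

test_that("lines are closed: no relationships across lines", {
  cfg <- sim_config(n_lines = 2, generations = 3, sires_per_gen = 3,
                    dams_per_gen = 12, seed = 2)
  sp <- simulate_pedigree(cfg)
  ped <- sp$pedigree
  line_of <- function(id) sub("^(L[0-9]+).*", "\\1", id)
  par_ok <- function(p, i) p == 0L | line_of(ped$id[pmax(p, 1L)]) == line_of(ped$id[i])
  i <- seq_along(ped$id)
  expect_true(all(par_ok(ped$sire, i)) && all(par_ok(ped$dam, i)))
})

test_that("litter sizes follow the truncated-Poisson oracle and pens mix
           litters", {
  cfg <- sim_config(n_lines = 6, generations = 2, sires_per_gen = 7,
                    dams_per_gen = 90, phenotyped_fraction = 1, seed = 3)
  sp <- simulate_pedigree(cfg)
  sizes <- as.numeric(table(sp$groups$litter))
  # exact mean/sd of a Poisson(12.5) clamped to [1, 30]
  k <- 0:200
  pk <- dpois(k, 12.5)
  ck <- pmin(pmax(k, 1), 30)
  mu <- sum(pk * ck)
  sdev <- sqrt(sum(pk * ck^2) - mu^2)
  expect_lt(abs(mean(sizes) - mu), 3 * sdev / sqrt(length(sizes)))
  mix <- tapply(sp$groups$litter, sp$groups$pen, function(x) length(unique(x)))
  expect_gt(mean(mix >= 2), 0.95)
  pen_sizes <- as.numeric(table(sp$groups$pen))
  expect_true(all(pen_sizes <= cfg$pen_size[2] + cfg$pen_size[1]))
})

test_that("infeasible pen constraints are rejected", {
  cfg <- sim_config(n_lines = 1, generations = 2, sires_per_gen = 1,
                    dams_per_gen = 1, litter_size = list(mean = 2, min = 1, max = 3),
                    phenotyped_fraction = 1, pen_size = c(6L, 16L), seed = 4)
  expect_error(simulate_dataset(cfg), "pen")
})

test_that("breeding values have the configured variance, correlation and
           mid-parent regression", {
  cfg <- sim_config(n_lines = 6, generations = 3, sires_per_gen = 10,
                    dams_per_gen = 110, seed = 5)
  ds <- simulate_dataset(cfg)
  bv <- ds$truth$bv
  n <- nrow(bv)
  expect_gt(n, 4000)
  # founder variance: sampling tolerance 3 SE (SE ~ sqrt(2/n) * var)
  expect_lt(abs(var(bv[, 1]) - 0.05), 3 * sqrt(2 / n) * 0.05 + 0.004)
  expect_lt(abs(cor(bv[, 1], bv[, 2]) - 0.45), 3 / sqrt(n) + 0.05)
  ped <- ds$pedigree
  off <- which(ped$sire > 0 & ped$dam > 0)
  mp <- 0.5 * (bv[ped$sire[off], 1] + bv[ped$dam[off], 1])
  fit <- lm(bv[off, 1] ~ mp)
  expect_lt(abs(coef(fit)[2] - 1), 3 * summary(fit)$coefficients[2, 2])
})

test_that("zero variances and zero fixed effects give identically zero
           phenotypes", {
  cfg <- sim_config(n_lines = 1, generations = 2, sires_per_gen = 2,
                    dams_per_gen = 6, phenotyped_fraction = 1,
                    var_a = 0, var_l = 0, var_g = 0, var_hys = 0, var_e = 0,
                    sex_effect = 0, line_effect_sd = 0, sexline_sd = 0,
                    scorer_sd = 0, age_slope = 0, seed = 6)
  ds <- simulate_dataset(cfg)
  expect_equal(ds$phenotypes$ED03, rep(0, nrow(ds$phenotypes)))
  expect_equal(ds$phenotypes$TD03, rep(0, nrow(ds$phenotypes)))
})

test_that("ordinal thresholds reproduce normal-CDF prevalences", {
  tot <- 0.05 + 0.10 + 0.20 + 0.10 + 0.55
  thr <- qnorm(c(0.75, 0.90, 0.97), 0, sqrt(tot))
  cfg <- sim_config(n_lines = 6, generations = 2, sires_per_gen = 7,
                    dams_per_gen = 100, mode = "ordinal",
                    thresholds = rbind(thr, thr),
                    sex_effect = 0, line_effect_sd = 0, sexline_sd = 0,
                    scorer_sd = 0, age_slope = 0, seed = 7)
  ds <- simulate_dataset(cfg)
  n <- nrow(ds$phenotypes)
  prev <- c(0.75, 0.15, 0.07, 0.03)
  for (s in 0:3) {
    obs <- mean(ds$phenotypes$ED03 == s)
    se <- sqrt(prev[s + 1] * (1 - prev[s + 1]) / n)
    expect_lt(abs(obs - prev[s + 1]), 3 * se + 0.01)
  }
  expect_true(all(ds$phenotypes$SD06 ==
                    ds$phenotypes$ED03 + ds$phenotypes$TD03))
})

test_that("datasets round-trip through disk and are seed-deterministic", {
  cfg <- sim_config(n_lines = 1, generations = 3, sires_per_gen = 3,
                    dams_per_gen = 10, mode = "ordinal", seed = 8)
  ds <- simulate_dataset(cfg)
  d1 <- withr::local_tempdir()
  write_dataset(ds, d1)
  back <- read_dataset(d1)
  expect_equal(back$pedigree$id, ds$pedigree$id)
  expect_equal(back$pedigree$F, ds$pedigree$F)
  expect_equal(back$phenotypes$ED03, ds$phenotypes$ED03)
  expect_equal(back$phenotypes$birth_date, ds$phenotypes$birth_date)
  expect_equal(nrow(back$truth), nrow(ds$phenotypes))
  expect_equal(back$config$seed, cfg$seed)

  # same seed, fresh run: byte-identical files
  d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
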