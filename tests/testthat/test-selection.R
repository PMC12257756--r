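test_that("detrending removes herd-year-season means from EBVs", {
  set.seed(2)
  hys <- rep(letters[1:5], each = 20)
  trend <- rep(seq(0, 2, length.out = 5), each = 20)
  ebv <- trend + rnorm(100, 0, 0.3)
  adj <- detrend_ebv(ebv, hys)
  expect_equal(as.numeric(tapply(adj, hys, mean)), rep(0, 5), tolerance = 1e-10)
  expect_equal(mean(adj), 0, tolerance = 1e-12)

  # single level: centering only
  expect_equal(detrend_ebv(c(1, 2, 3), rep("x", 3)), c(-1, 0, 1))
  # EBVs equal to the level means leave zero residuals
  expect_equal(detrend_ebv(trend, hys), rep(0, 100), tolerance = 1e-12)
  expect_warning(detrend_ebv(c(1, 2, 3), c("a", "a", "b")), "single animal")
})

test_that("normal-theory selection intensity matches closed forms", {
  expect_equal(round(normal_intensity(0.05), 3), 2.063)
  expect_equal(normal_intensity(0.5), sqrt(2 / pi), tolerance = 1e-12)
  expect_lt(normal_intensity(0.999), 0.01)
  expect_error(normal_intensity(0))
})

test_that("realized intensity converges to normal theory on normal EBVs", {
  set.seed(7)
  ebv <- rnorm(1e6)
  expect_lt(abs(realized_intensity(ebv, 0.05) - normal_intensity(0.05)), 0.01)
  expect_lt(abs(realized_intensity(ebv, 0.05, tail = "upper") -
                  normal_intensity(0.05)), 0.01)
})

test_that("realized intensity handles ties, scale and degenerate input", {
  # two-point distribution: selected animals all sit at the low mass point
  ebv <- c(rep(0, 900), rep(1, 100))
  i_obs <- realized_intensity(ebv, 0.05, tail = "lower")
  i_expected <- abs(0 - mean(ebv)) / sd(ebv)   # enumeration: selected mean is 0
  expect_equal(as.numeric(i_obs), i_expected)
  expect_lt(i_obs, normal_intensity(0.05))

  # location/scale invariance
  set.seed(1)
  x <- rnorm(2000)
  expect_equal(as.numeric(realized_intensity(x, 0.1)),
               as.numeric(realized_intensity(5 + 3 * x, 0.1)), tolerance = 1e-12)

  expect_error(realized_intensity(rep(1, 100), 0.05), "standard deviation")
  expect_error(realized_intensity(rnorm(100), 0.001), "at least 1")
})

test_that("response table combines intensity, accuracy and correlation", {
  i <- c(a = 2, b = 1)
  r <- c(a = 0.5, b = 0.4)
  rg <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  rep0 <- response_table(i, r, rg)
  expect_equal(unname(diag(rep0$R)), c(1, 0.4))
  expect_equal(rep0$R["b", "a"], 0)   # uncorrelated: no indirect response

  rg[1, 2] <- rg[2, 1] <- 0.8
  rep1 <- response_table(i, r, rg)
  expect_equal(rep1$R["b", "a"], 1 * 0.8)
  # indirect selection on 'a' beats direct selection for response in 'b'
  expect_equal(rep1$best, c(a = "a", b = "a"))

  rg[1, 2] <- rg[2, 1] <- 1.2
  expect_error(response_table(i, r, rg), "-1, 1")
})
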