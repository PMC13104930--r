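test_that("parity metrics hit closed-form anchors", {
  set.seed(1)
  T_ <- matrix(runif(200), 40, 5)
  # perfect parity
  m <- parity_metrics(T_, T_)
  expect_equal(m$r2, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$slope, 1)
  # predicting the pooled mean: r2 = 0, slope = 0
  mu <- matrix(mean(T_), nrow(T_), ncol(T_))
  m0 <- parity_metrics(T_, mu)
  expect_equal(m0$r2, 0)
  expect_equal(m0$slope, 0)
  # affine prediction: slope recovered exactly, free intercept absorbs the offset
  ma <- parity_metrics(T_, 0.5 * T_ + 0.25)
  expect_equal(ma$slope, 0.5)
  # rmse^2 equals the mean squared error to machine precision
  P_ <- T_ + matrix(rnorm(200, sd = 0.1), 40, 5)
  mp <- parity_metrics(T_, P_)
  expect_equal(mp$rmse^2, mean((P_ - T_)^2))
  expect_equal(mp$r2, 1 - sum((P_ - T_)^2) / sum((T_ - mean(T_))^2))
})

test_that("parity metrics are symmetric under record permutation", {
  set.seed(2)
  T_ <- matrix(runif(100), 20, 5)
  P_ <- matrix(runif(100), 20, 5)
  p <- sample(20)
  expect_equal(parity_metrics(T_, P_), parity_metrics(T_[p, ], P_[p, ]))
})

test_that("zero-variance truth flags r2 as undefined", {
  T_ <- matrix(0.2, 10, 5)
  m <- parity_metrics(T_, T_ + 0.01)
  expect_false(m$r2_defined)
  expect_true(is.na(m$r2))
})

test_that("undefined predictions are scored as zero vectors", {
  T_ <- matrix(c(0.6, 0.4, 0.3, 0.7), 2, 2, byrow = TRUE)
  P_ <- rbind(c(0.6, 0.4), c(NA, NA))
  a <- aae(T_, P_)
  expect_equal(a$aae, c(0.15, 0.35)) # second record contributes |truth|
  m <- parity_metrics(T_, P_)
  expect_equal(m$rmse^2, mean(c(0, 0, 0.09, 0.49)))
})

test_that("aae matches direct means and drops empty strata", {
  # single record: aae is the absolute error vector itself
  T_ <- matrix(c(0.5, 0.5, 0, 0, 0), 1)
  P_ <- matrix(c(0.6, 0.5, 0, 0, 0.1), 1)
  a <- aae(T_, P_, chromophores = paf_chromophores())
  expect_equal(a$aae, c(0.1, 0, 0, 0, 0.1))
  expect_equal(a$n, rep(1, 5))
  # perfect prediction: all zeros
  expect_true(all(aae(T_, T_)$aae == 0))
  # stratified: only populated bins appear
  T2 <- matrix(runif(40), 8, 5)
  P2 <- matrix(runif(40), 8, 5)
  snr <- c(rep(5, 4), rep(35, 4)) # two occupied bins out of eight
  s <- aae(T2, P2, stratify = snr, breaks = snr_breaks())
  expect_equal(length(unique(s$stratum)), 2)
  expect_true(all(s$n == 4))
  got <- s$aae[s$stratum == s$stratum[1]]
  expect_equal(got, colMeans(abs(P2[1:4, ] - T2[1:4, ])), ignore_attr = TRUE)
})

test_that("aae of a simplex-uniform predictor matches a Monte-Carlo oracle", {
  # truth and prediction both uniform on the 5-simplex; the expected
  # per-chromophore AAE is E|a - b| for independent Beta(1,4) marginals,
  # estimated here by an independent brute-force draw
  set.seed(33)
  n_oracle <- 2e5
  a_ <- rexp(n_oracle)
  asum <- a_ + rexp(n_oracle) + rexp(n_oracle) + rexp(n_oracle) + rexp(n_oracle)
  b_ <- rexp(n_oracle)
  bsum <- b_ + rexp(n_oracle) + rexp(n_oracle) + rexp(n_oracle) + rexp(n_oracle)
  oracle <- mean(abs(a_ / asum - b_ / bsum))

  T_ <- as.matrix(sample_concentrations(5e4, "random", seed = 34)[paf_chromophores()])
  P_ <- as.matrix(sample_concentrations(5e4, "random", seed = 35)[paf_chromophores()])
  got <- aae(T_, P_)$aae
  expect_true(all(abs(got - oracle) < 0.01))
})

test_that("uniform predictor upper-bounds NNLS on noiseless instances", {
  lib <- test_library()
  C <- as.matrix(sample_concentrations(300, "random", seed = 36)[paf_chromophores()])
  A <- clean_fingerprint(C, lib)
  res <- nnls_unmix(A, lib)
  aae_nnls <- mean(aae(C, res$nnls_fraction)$aae)
  unif <- as.matrix(sample_concentrations(300, "random", seed = 37)[paf_chromophores()])
  aae_unif <- mean(aae(C, unif)$aae)
  expect_lt(aae_nnls, aae_unif)
})

test_that("cohort comparison reproduces the Welch t-test", {
  eq <- compare_cohorts(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$p_value, 1)
  # degenerate zero-variance cohorts
  dg <- compare_cohorts(rep(1, 5), rep(0, 5))
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 0)
  expect_equal(compare_cohorts(rep(1, 5), rep(1, 5))$p_value, 1)
  # seeded normal cohorts against the textbook t CDF with Welch df
  set.seed(8)
  a <- rnorm(5, 1)
  b <- rnorm(5, 0)
  got <- compare_cohorts(a, b)
  va <- var(a) / 5
  vb <- var(b) / 5
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / 4 + vb^2 / 4)
  expect_equal(got$t_statistic, tstat, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * stats::pt(-abs(tstat), df), tolerance = 1e-6)
  expect_error(compare_cohorts(1, 1), "at least 2")
  expect_error(compare_cohorts(1:3, 1:4), "equal length")
})

test_that("oxygen saturation follows HbO2 / (HbO2 + HbR)", {
  expect_equal(so2(c(HbO2 = 0.3, HbR = 0.1, lipid = 0.6)), 0.75)
  expect_equal(so2(c(HbO2 = 0.2, HbR = 0)), 1)
  expect_true(is.na(so2(c(HbO2 = 0, HbR = 0, water = 1))))
  m <- rbind(c(HbO2 = 0.5, HbR = 0.5), c(HbO2 = 0, HbR = 0))
  expect_equal(so2(m), c(0.5, NA))
  # always in [0, 1] when defined
  C <- as.matrix(sample_concentrations(2000, "random", seed = 39)[paf_chromophores()])
  s <- so2(C)
  expect_true(all(s >= 0 & s <= 1, na.rm = TRUE))
  expect_error(so2(c(a = 1)), "HbO2")
})
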