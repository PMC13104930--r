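test_that("every class samples on the simplex and obeys its constraint", {
  n <- 2000
  for (cls in c(mixture_classes(), anatomical_classes())) {
    C <- as.matrix(sample_concentrations(n, cls, seed = 5)[paf_chromophores()])
    expect_true(all(C >= 0), info = cls)
    expect_true(max(abs(rowSums(C) - 1)) < 1e-9, info = cls)
    mx <- apply(C, 1, max)
    supp <- rowSums(C > 0)
    switch(cls,
      pure = {
        expect_true(all(supp == 1) && all(mx == 1))
      },
      extreme = expect_true(all(mx >= 0.90 & mx <= 0.99)),
      dominant = expect_true(all(mx >= 0.70 & mx <= 0.90)),
      binary = {
        expect_true(all(supp == 2))
        expect_true(min(C[C > 0]) > 0.01)
      },
      random = expect_true(all(supp == 5)),
      vessel_like = {
        hb <- C[, "HbO2"] + C[, "HbR"]
        expect_true(all(hb >= 0.7 & hb <= 1))
        expect_true(all(C[, "HbO2"] >= C[, "HbR"])) # arterial bias s >= 0.5
      },
      fat_dominant = expect_true(all(C[, "lipid"] >= 0.6 & C[, "lipid"] <= 0.95)),
      collagen_rich = expect_true(all(C[, "collagen"] >= 0.5 & C[, "collagen"] <= 0.9)),
      background = expect_true(all(C[, "water"] >= 0.7 & C[, "water"] <= 1))
    )
  }
})

test_that("fluence profile matches the exponential attenuation prior", {
  g <- default_grid()
  expect_equal(fluence_profile(0, g), rep(1, 53))
  phi <- fluence_profile(20, g)
  expect_equal(phi[53], 1) # longest wavelength untouched for any x
  expect_equal(phi[1], exp(-20)) # shortest wavelength fully attenuated
  expect_true(all(diff(phi) >= 0)) # monotone non-decreasing in wavelength
  # pointwise non-increasing in severity
  xs <- seq(0, 20, by = 2.5)
  profs <- fluence_profile(xs, g)
  expect_true(all(apply(profs, 2, function(col) all(diff(col) <= 0))))
  expect_true(all(profs > 0 & profs <= 1))
  expect_error(fluence_profile(-1, g), "non-negative")
})

test_that("forward model is linear in concentrations and fluence", {
  lib <- test_library()
  M <- lib$matrix
  # one-hot reproduces the library column exactly
  for (j in seq_len(5)) {
    c1 <- replace(rep(0, 5), j, 1)
    expect_equal(clean_fingerprint(c1, lib), unname(M[, j]))
  }
  # half-half mixture is the mean of columns
  expect_equal(
    clean_fingerprint(c(0.5, 0.5, 0, 0, 0), lib),
    unname((M[, 1] + M[, 2]) / 2)
  )
  # fluence scales elementwise
  f <- clean_fingerprint(c(0.2, 0.2, 0.2, 0.2, 0.2), lib)
  expect_equal(
    clean_fingerprint(c(0.2, 0.2, 0.2, 0.2, 0.2), lib, rep(0.5, 53)),
    f * 0.5
  )
  expect_error(clean_fingerprint(c(1, 0), lib), "does not match")
})

test_that("noise injection uses alpha = sqrt(10^(SNR/10) / Ps)", {
  # all-ones fingerprint, Ps = 1, 20 dB -> alpha = 10 exactly
  f0 <- rep(1, 53)
  noisy <- add_noise(f0, 20, seed = 1)
  eps <- noisy - 10 * f0
  expect_true(abs(mean(eps)) < 0.5 && abs(sd(eps) - 1) < 0.3)
  # high-SNR limit: relative noise contribution vanishes
  hi <- add_noise(f0, 120, seed = 1)
  alpha_hi <- sqrt(10^(120 / 10))
  expect_true(max(abs(hi / (alpha_hi * f0) - 1)) < 1e-4)
  expect_error(add_noise(rep(0, 53), 20), "all-zero")
})

test_that("max-normalization is exact, idempotent, and sign-preserving", {
  expect_equal(normalize_max(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(normalize_max(c(0.25, 0.5, 1)), c(0.25, 0.5, 1))
  v <- c(-1, 0.5, 2)
  nv <- normalize_max(v)
  expect_equal(max(nv), 1)
  expect_true(all(nv <= 1) && any(nv < 0))
  m <- matrix(c(1, 2, 3, 6), 2)
  expect_equal(apply(normalize_max(m), 1, max), c(1, 1))
  expect_error(normalize_max(c(0, 0)), "non-positive")
})

test_that("dataset generation honors size, composition and fluence mode", {
  lib <- test_library()
  d <- simulate_fingerprints(2000, lib, seed = 9)
  expect_equal(nrow(d), 2000)
  counts <- table(d$mixture_class)
  expect_true(all(counts[mixture_classes()] == 200)) # 50% over 5 classes
  expect_true(all(counts[anatomical_classes()] == 250)) # 50% over 4 patterns
  expect_true(all(d$fluence_x >= 0 & d$fluence_x <= 20))
  expect_true(all(d$snr_db >= 3 & d$snr_db <= 40))

  du <- simulate_fingerprints(100, lib, fluence = "unit", seed = 9)
  expect_true(all(du$fluence_x == 0))

  expect_error(
    simulate_fingerprints(10, lib, proportions = c(pure = 0.5, binary = 0.4)),
    "sum to 1"
  )
})

test_that("the same seed reproduces a dataset exactly", {
  lib <- test_library()
  d1 <- simulate_fingerprints(500, lib, seed = 77)
  d2 <- simulate_fingerprints(500, lib, seed = 77)
  expect_identical(d1$amplitudes, d2$amplitudes)
  expect_identical(d1$concentration, d2$concentration)
  d3 <- simulate_fingerprints(500, lib, seed = 78)
  expect_false(identical(d1$amplitudes, d3$amplitudes))
})

test_that("noiseless unit-fluence pure fingerprints equal library columns", {
  lib <- test_library()
  C <- diag(5)
  A <- clean_fingerprint(C, lib)
  expect_equal(unname(t(A)), unname(lib$matrix))
})

test_that("structural classification recovers generating mixture classes", {
  lib <- test_library()
  for (cls in c("pure", "binary", "extreme", "dominant")) {
    C <- as.matrix(sample_concentrations(200, cls, seed = 3)[paf_chromophores()])
    expect_true(all(structural_class(C) == cls), info = cls)
  }
})

test_that("simulator config YAML round-trips into generator arguments", {
  p <- tempfile(fileext = ".yml")
  yaml::write_yaml(list(
    size = 50,
    fluence = list(mode = "unit", x_range = c(0, 20)),
    noise = list(snr_range_db = c(10, 30)),
    seed = 4
  ), p)
  cfg <- read_sim_config(p)
  d <- do.call(simulate_fingerprints, c(list(lib = test_library()), cfg))
  expect_equal(nrow(d), 50)
  expect_true(all(d$fluence_x == 0))
  expect_true(all(d$snr_db >= 10 & d$snr_db <= 30))
})
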