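test_that("stack construction validates shape, grid and energies", {
  g <- default_grid()
  arr <- array(1, c(53, 4, 6))
  s <- multispectral_stack(arr, g)
  expect_s3_class(s, "paf_stack")
  expect_error(multispectral_stack(array(1, c(10, 4, 6)), g), "does not match")
  expect_error(multispectral_stack(matrix(1, 53, 4), g), "3D")
  expect_error(
    multispectral_stack(arr, g, pulse_energy = rep(0, 53)),
    "positive"
  )
  expect_error(
    multispectral_stack(arr, g, pulse_energy = rep(1, 10)),
    "per wavelength"
  )
})

test_that("energy normalization divides frames and is idempotent", {
  g <- new_grid(c(700, 800), list(c(700, 800)))
  arr <- array(1, c(2, 3, 3))
  arr[2, , ] <- 6
  en <- c(1, 2)
  s <- multispectral_stack(arr, g, pulse_energy = en)
  s1 <- energy_normalize(s)
  expect_equal(unclass(s1)[2, , ], matrix(3, 3, 3), ignore_attr = TRUE)
  expect_equal(unclass(s1)[1, , ], matrix(1, 3, 3), ignore_attr = TRUE)
  expect_equal(attr(s1, "pulse_energy"), c(1, 1))
  expect_equal(unclass(energy_normalize(s1)), unclass(s1))
  # uniform energies only rescale globally
  s2 <- energy_normalize(multispectral_stack(arr, g, pulse_energy = c(2, 2)))
  expect_equal(unclass(s2), unclass(arr) / 2, ignore_attr = TRUE)
  expect_error(energy_normalize(multispectral_stack(arr, g)), "pulse_energy")
})

test_that("maximum amplitude projection collapses the depth axis", {
  g <- new_grid(c(700, 800), list(c(700, 800)))
  # single slice: identity
  a1 <- array(runif(2 * 1 * 3 * 3), c(2, 1, 3, 3))
  p1 <- map_projection(multispectral_stack(a1, g))
  expect_equal(unclass(p1), a1[, 1, , ], ignore_attr = TRUE)
  # monotone ramp along z: max is the last slice
  a2 <- array(0, c(2, 4, 3, 3))
  for (z in 1:4) a2[, z, , ] <- z
  p2 <- map_projection(multispectral_stack(a2, g))
  expect_true(all(unclass(p2) == 4))
  # commutes with per-wavelength positive scaling
  a3 <- array(runif(2 * 4 * 3 * 3), c(2, 4, 3, 3))
  sc <- c(2, 0.5)
  a3s <- a3 * array(sc, dim(a3))
  p3 <- map_projection(multispectral_stack(a3, g))
  p3s <- map_projection(multispectral_stack(a3s, g))
  expect_equal(unclass(p3s), unclass(p3) * array(sc, dim(unclass(p3))),
    ignore_attr = TRUE
  )
  expect_error(map_projection(multispectral_stack(array(1, c(2, 3, 3)), g)), "4D")
})

test_that("noiseless phantom is unmixed exactly by NNLS, region by region", {
  lib <- test_library()
  ph <- phantom_stack(lib, snr_db = NULL, region_size = 4, gap = 2)
  comps <- ph$truth[paf_chromophores()]
  cmap <- unmix_image(ph$stack, lib, "nnls")
  st <- region_stats(cmap, clean_phantom_labels(region_size = 4, gap = 2))
  for (r in seq_len(5)) {
    for (ch in paf_chromophores()) {
      truth_val <- comps[[ch]][r]
      got <- st$mean[st$roi == r & st$chromophore == ch]
      expect_equal(got, truth_val, tolerance = 1e-6)
    }
  }
  # background pixels are masked, not unmixed
  bg <- cmap$masked[clean_phantom_labels(region_size = 4, gap = 2)[cbind(cmap$y, cmap$x)] == 0]
  expect_true(all(bg))
})

test_that("phantom at 10 dB yields correct region-mean argmax under NNLS", {
  lib <- test_library()
  ph <- phantom_stack(lib, snr_db = 10, region_size = 8, gap = 2, seed = 5)
  cmap <- unmix_image(ph$stack, lib, "nnls")
  st <- region_stats(cmap, ph$labels)
  truth <- ph$truth[paf_chromophores()]
  for (r in seq_len(5)) {
    means <- vapply(
      paf_chromophores(),
      function(ch) st$mean[st$roi == r & st$chromophore == ch], numeric(1)
    )
    expect_equal(
      unname(which.max(means)),
      unname(which.max(unlist(truth[r, ]))),
      info = paste("region", r)
    )
  }
})

test_that("relabeling chromophore order permutes map channels identically", {
  lib <- test_library()
  perm <- c(3, 1, 5, 2, 4)
  lib_p <- structure(
    list(
      grid = lib$grid,
      chromophores = lib$chromophores[perm],
      matrix = lib$matrix[, perm]
    ),
    class = "paf_library"
  )
  st <- clean_phantom(lib, region_size = 3, gap = 1)
  m1 <- unmix_image(st, lib, "nnls")
  m2 <- unmix_image(st, lib_p, "nnls")
  for (ch in paf_chromophores()) {
    expect_equal(m1[[ch]], m2[[ch]], tolerance = 1e-9)
  }
  expect_equal(m1$so2, m2$so2, tolerance = 1e-9)
})

test_that("region statistics are local and support fold changes", {
  lib <- test_library()
  stck <- clean_phantom(lib, region_size = 3, gap = 1)
  cmap <- unmix_image(stck, lib, "nnls")
  labels <- clean_phantom_labels(region_size = 3, gap = 1)
  st <- region_stats(cmap, labels)
  # constant region: sd 0
  expect_true(all(st$sd[st$roi == 3] < 1e-9))
  # locality: stats for region 1 unchanged when another region's label is dropped
  labels2 <- labels
  labels2[labels2 == 5] <- 0
  st2 <- region_stats(cmap, labels2)
  expect_equal(
    st[st$roi == 1, ],
    st2[st2$roi == 1, ]
  )
  # fold change between lipid means of the lipid and collagen+water regions
  l3 <- st$mean[st$roi == 3 & st$chromophore == "lipid"]
  l4 <- st$mean[st$roi == 4 & st$chromophore == "lipid"]
  expect_gt(l3, 10 * l4 + 0.5)
  expect_error(region_stats(cmap, labels * 0), "no labeled")
})

test_that("TIFF frames and pulse-energy tables round-trip into a stack", {
  skip_if_not_installed("tiff")
  g <- new_grid(c(700, 800), list(c(700, 800)))
  f1 <- tempfile(fileext = ".tif")
  f2 <- tempfile(fileext = ".tif")
  img1 <- matrix(runif(12), 3, 4)
  img2 <- matrix(runif(12), 3, 4)
  tiff::writeTIFF(img1, f1, bits.per.sample = 32)
  tiff::writeTIFF(img2, f2, bits.per.sample = 32)
  ep <- tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,energy", "800,2", "700,1"), ep)
  en <- load_pulse_energy(ep, g)
  expect_equal(en, c(1, 2))
  s <- stack_from_tiff(c(f1, f2), g, pulse_energy = en)
  expect_equal(dim(s), c(2, 3, 4))
  expect_equal(unclass(s)[1, , ], img1, tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(stack_from_tiff(f1, g), "one TIFF per")
  writeLines(c("wavelength_nm,energy", "700,1"), ep)
  expect_error(load_pulse_energy(ep, g), "800")
})
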