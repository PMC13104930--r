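# shared fixtures; heavyweight objects are memoized for the whole test run

.paf_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .paf_cache)) assign(key, force(expr), .paf_cache)
  get(key, .paf_cache)
}

test_library <- function() memo("lib", synthetic_nir_library())

# small sub-grid library for fast solver tests
small_library <- function(K = 8, N = 3) {
  memo(sprintf("lib_%d_%d", K, N), {
    grid <- new_grid(seq(700, 970, length.out = K), list(c(700, 970)))
    build_library(synthetic_spectra(N, seed = 11), grid)
  })
}

# the scaled-down trained model shared by the acceptance suite:
# 1e5 fingerprints with random fluence severity, 15 epochs, hidden 64
acceptance_fit <- function() {
  memo("acc_fit", {
    lib <- test_library()
    train <- simulate_fingerprints(1e5, lib, fluence = "random", seed = 301)
    paf_train(
      train, lib,
      model = model_config(hidden_size = 64, num_layers = 1),
      training = train_config(
        batch_size = 128, learning_rate = 1e-3, epochs = 15, seed = 302
      )
    )
  })
}

acceptance_fluence_test <- function() {
  memo("acc_test_fluence", {
    simulate_fingerprints(5e4, test_library(), fluence = "random", seed = 303)
  })
}

acceptance_unit_test <- function() {
  memo("acc_test_unit", {
    simulate_fingerprints(5e4, test_library(), fluence = "unit", seed = 304)
  })
}

# projected-gradient NNLS oracle, independent of the active-set solver
pg_nnls <- function(M, f, iters = 20000, tol = 1e-12) {
  MtM <- crossprod(M)
  Mtf <- crossprod(M, f)
  L <- max(eigen(MtM, symmetric = TRUE, only.values = TRUE)$values)
  x <- rep(0, ncol(M))
  for (i in seq_len(iters)) {
    g <- MtM %*% x - Mtf
    xn <- pmax(x - as.vector(g) / L, 0)
    if (max(abs(xn - x)) < tol) {
      x <- xn
      break
    }
    x <- xn
  }
  x
}

nnls_objective <- function(M, f, x) sum((M %*% x - f)^2)

# noiseless phantom variants used by the image-pipeline tests
clean_phantom <- function(lib, region_size = 4, gap = 2) {
  phantom_stack(lib, snr_db = NULL, region_size = region_size, gap = gap)$stack
}

clean_phantom_labels <- function(region_size = 4, gap = 2) {
  phantom_stack(test_library(),
    snr_db = NULL,
    region_size = region_size, gap = gap
  )$labels
}

write_spectrum_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
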