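#' Mixture and anatomical class labels
#'
#' Concentration vectors are sampled either from five mixture classes of
#' increasing spectral complexity (`pure`, `extreme`, `dominant`, `random`,
#' `binary`) or from four anatomical patterns mimicking tissue composition
#' (`vessel_like`, `fat_dominant`, `collagen_rich`, `background`).
#'
#' @return Character vector of class labels.
#' @export
mixture_classes <- function() {
  c("pure", "extreme", "dominant", "random", "binary")
}

#' @rdname mixture_classes
#' @export
anatomical_classes <- function() {
  c("vessel_like", "fat_dominant", "collagen_rich", "background")
}

# rows of a symmetric Dirichlet(1) draw (uniform on the simplex)
rdirichlet1 <- function(n, k) {
  if (k == 1) return(matrix(1, n, 1))
  g <- matrix(rexp(n * k), n, k)
  g / rowSums(g)
}

#' Sample concentration vectors by class
#'
#' Draws `n` chromophore concentration vectors on the simplex obeying the
#' constraint of the requested class:
#' \describe{
#'   \item{pure}{one chromophore at 100\%.}
#'   \item{extreme}{a dominant chromophore uniform in `[0.90, 0.99]`, the
#'     remainder split over the others by a Dirichlet(1) draw.}
#'   \item{dominant}{dominant fraction uniform in `[0.70, 0.90]`, remainder
#'     Dirichlet.}
#'   \item{random}{symmetric Dirichlet(1), i.e. uniform on the simplex.}
#'   \item{binary}{exactly two nonzero chromophores, each above 1\%.}
#'   \item{vessel_like}{total hemoglobin uniform in `[0.7, 1.0]`, split
#'     between HbO2 and HbR with an arterial-biased oxygenation fraction
#'     `s ~ U(0.5, 1)`; remainder Dirichlet over lipid/water/collagen.}
#'   \item{fat_dominant}{lipid uniform in `[0.6, 0.95]`, remainder Dirichlet.}
#'   \item{collagen_rich}{collagen uniform in `[0.5, 0.9]`, remainder Dirichlet.}
#'   \item{background}{water uniform in `[0.7, 1.0]`, remainder Dirichlet.}
#' }
#'
#' @param n Number of draws.
#' @param class One class label from [mixture_classes()] or
#'   [anatomical_classes()].
#' @param chromophores Chromophore labels (default [paf_chromophores()];
#'   anatomical classes require the canonical five).
#' @param seed Optional integer seed (draws from the current RNG stream when
#'   `NULL`).
#' @return Tibble with one numeric column per chromophore plus
#'   `mixture_class`; every row sums to 1.
#' @export
#' @examples
#' sample_concentrations(3, "binary", seed = 1)
sample_concentrations <- function(n, class,
                                  chromophores = paf_chromophores(),
                                  seed = NULL) {
  class <- match.arg(class, c(mixture_classes(), anatomical_classes()))
  N <- length(chromophores)
  if (class %in% anatomical_classes() &&
    !identical(chromophores, paf_chromophores())) {
    abort("anatomical classes require the canonical five chromophores")
  }
  C <- with_seed_(seed, sample_conc_matrix(n, class, N, chromophores))
  out <- as_tibble(as.data.frame(C))
  names(out) <- chromophores
  out$mixture_class <- class
  out
}

# matrix backend shared by sample_concentrations() and the dataset generator;
# consumes the current RNG stream
sample_conc_matrix <- function(n, class, N, chromophores) {
  C <- matrix(0, n, N)
  dominant_fill <- function(lo, hi) {
    dom <- sample.int(N, n, replace = TRUE)
    m <- runif(n, lo, hi)
    # Dirichlet(1) over the non-dominant chromophores, vectorized by zeroing
    # the dominant column of an exponential draw before normalizing
    g <- matrix(rexp(n * N), n, N)
    g[cbind(seq_len(n), dom)] <- 0
    g <- g / rowSums(g) * (1 - m)
    g[cbind(seq_len(n), dom)] <- m
    C <<- g
  }
  anatomical_fill <- function(anchor, lo, hi) {
    j <- match(anchor, chromophores)
    m <- runif(n, lo, hi)
    rest <- rdirichlet1(n, N - 1) * (1 - m)
    C[, j] <<- m
    C[, -j] <<- rest
  }
  switch(class,
    pure = {
      j <- sample.int(N, n, replace = TRUE)
      C[cbind(seq_len(n), j)] <- 1
    },
    extreme = dominant_fill(0.90, 0.99),
    dominant = dominant_fill(0.70, 0.90),
    random = {
      C <- rdirichlet1(n, N)
    },
    binary = {
      j1 <- sample.int(N, n, replace = TRUE)
      shift <- sample.int(N - 1, n, replace = TRUE)
      j2 <- 1 + (j1 - 1 + shift) %% N
      w <- runif(n, 0.011, 0.989)
      C[cbind(seq_len(n), j1)] <- w
      C[cbind(seq_len(n), j2)] <- 1 - w
    },
    vessel_like = {
      m <- runif(n, 0.7, 1.0)
      s <- runif(n, 0.5, 1.0) # arterial-biased oxygenation fraction
      rest <- rdirichlet1(n, 3) * (1 - m)
      C[, match("HbO2", chromophores)] <- s * m
      C[, match("HbR", chromophores)] <- (1 - s) * m
      C[, match(c("lipid", "water", "collagen"), chromophores)] <- rest
    },
    fat_dominant = anatomical_fill("lipid", 0.6, 0.95),
    collagen_rich = anatomical_fill("collagen", 0.5, 0.9),
    background = anatomical_fill("water", 0.7, 1.0)
  )
  colnames(C) <- chromophores
  C
}

#' Parametric fluence profile
#'
#' Exponential attenuation prior modeling depth-dependent spectral
#' reddening: `phi_k = exp(-(1 - u_k)^2 * x)` where `u_k` is the wavelength
#' min-max normalized over the full grid. Shorter wavelengths are attenuated
#' more strongly; the longest wavelength always has unit fluence, and `x = 0`
#' gives uniform (unit) fluence.
#'
#' @param x Fluence severity, a non-negative scalar (or vector, giving one
#'   profile per row of the result).
#' @param grid A `paf_grid`.
#' @return Numeric vector of length K (or a `length(x)` x K matrix), values
#'   in `(0, 1]`, non-decreasing in wavelength.
#' @export
#' @examples
#' phi <- fluence_profile(20, default_grid())
#' range(phi)
fluence_profile <- function(x, grid) {
  if (any(x < 0)) abort("fluence severity x must be non-negative")
  u <- grid_unit_position(grid)
  if (length(x) == 1) {
    exp(-(1 - u)^2 * x)
  } else {
    exp(-outer(x, (1 - u)^2))
  }
}

#' Noiseless fingerprint from the forward model
#'
#' Applies the linear photoacoustic forward model: the fingerprint is the
#' fluence profile times the library-weighted concentration vector,
#' `f0 = phi * (M c)`, evaluated elementwise per wavelength.
#'
#' @param concentration Length-N concentration vector (or n x N matrix, one
#'   row per fingerprint).
#' @param lib A `paf_library`.
#' @param fluence Length-K fluence profile in `(0, 1]` (or n x K matrix);
#'   defaults to unit fluence.
#' @return Length-K amplitude vector (or n x K matrix).
#' @export
clean_fingerprint <- function(concentration, lib,
                              fluence = rep(1, nrow(lib$matrix))) {
  M <- lib$matrix
  K <- nrow(M)
  one <- is.null(dim(concentration))
  C <- if (one) matrix(concentration, 1) else as.matrix(concentration)
  if (ncol(C) != ncol(M)) {
    abort(sprintf(
      "concentration length %d does not match library N = %d",
      ncol(C), ncol(M)
    ))
  }
  Phi <- if (is.null(dim(fluence))) {
    if (length(fluence) != K) abort("fluence length does not match grid K")
    matrix(fluence, nrow(C), K, byrow = TRUE)
  } else {
    as.matrix(fluence)
  }
  if (any(Phi <= 0) || any(Phi > 1)) {
    abort("fluence values must lie in (0, 1]")
  }
  A <- (C %*% t(M)) * Phi
  if (one) drop(A) else A
}

#' Inject SNR-calibrated Gaussian noise
#'
#' Scales the clean fingerprint so that its power relative to unit-power
#' Gaussian noise matches the requested SNR, then adds independent standard
#' normal noise per wavelength: with signal power `Ps = mean(f0^2)` the
#' scale is `alpha = sqrt(10^(snr_db/10) / Ps)` and the output is
#' `alpha * f0 + e`, `e ~ N(0, 1)`.
#'
#' @param f0 Length-K clean fingerprint (or n x K matrix, with `snr_db` a
#'   scalar or length-n vector).
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param seed Optional integer seed.
#' @return Noisy fingerprint(s), same shape as `f0`.
#' @export
add_noise <- function(f0, snr_db, seed = NULL) {
  one <- is.null(dim(f0))
  A <- if (one) matrix(f0, 1) else as.matrix(f0)
  ps <- rowMeans(A^2)
  if (any(ps == 0)) abort("cannot add noise to an all-zero fingerprint")
  alpha <- sqrt(10^(snr_db / 10) / ps)
  out <- with_seed_(seed, {
    A * alpha + matrix(rnorm(length(A)), nrow(A), ncol(A))
  })
  if (one) drop(out) else out
}

#' Max-normalize fingerprints
#'
#' Divides each fingerprint by its maximum value so the largest amplitude is
#' exactly 1, emphasizing spectral shape over absolute intensity. This is
#' the model-input convention for the recurrent network; the NNLS baseline
#' consumes un-normalized fingerprints. Noisy fingerprints may retain
#' negative entries after normalization. Idempotent.
#'
#' @param f Length-K fingerprint or n x K matrix (rows normalized
#'   independently).
#' @return Same shape as `f`, each fingerprint's maximum equal to 1.
#' @export
normalize_max <- function(f) {
  one <- is.null(dim(f))
  A <- if (one) matrix(f, 1) else as.matrix(f)
  mx <- apply(A, 1, max)
  if (any(!is.finite(mx)) || any(mx <= 0)) {
    abort("cannot max-normalize a fingerprint with non-positive maximum")
  }
  out <- A / mx
  if (one) drop(out) else out
}

default_class_proportions <- function() {
  p <- c(
    rep(0.5 / 5, 5), # half the records, equally over mixture classes
    rep(0.5 / 4, 4)  # half over the anatomical patterns
  )
  names(p) <- c(mixture_classes(), anatomical_classes())
  p
}

#' Simulate a fingerprint dataset
#'
#' Generates `n` synthetic fingerprints: concentration vectors sampled by
#' class (by default half the records split equally over the five mixture
#' classes and half over the four anatomical patterns), pushed through the
#' forward model with an exponential fluence distortion, and corrupted with
#' SNR-calibrated Gaussian noise. Fully reproducible from `seed`.
#'
#' @param n Dataset size.
#' @param lib A `paf_library`.
#' @param proportions Named numeric vector of class proportions summing to 1
#'   (default [default_class_proportions()]).
#' @param fluence `"random"` (severity `x ~ U(x_range)`), `"unit"` (x = 0),
#'   or a fixed non-negative number.
#' @param x_range Sampling interval for the fluence severity (default
#'   `c(0, 20)`).
#' @param snr_range_db SNR sampling interval in dB (default `c(3, 40)`).
#' @param seed Integer seed driving all randomness.
#' @return Tibble with columns `mixture_class`, `fluence_x`, `snr_db`, and
#'   matrix columns `concentration` (n x N ground truth) and `amplitudes`
#'   (n x K noisy un-normalized fingerprints). The library's grid,
#'   chromophores and hash are carried in attributes.
#' @export
#' @examples
#' lib <- synthetic_nir_library()
#' d <- simulate_fingerprints(100, lib, fluence = "unit", seed = 1)
#' dplyr::count(d, mixture_class)
simulate_fingerprints <- function(n, lib,
                                  proportions = default_class_proportions(),
                                  fluence = c("random", "unit"),
                                  x_range = c(0, 20),
                                  snr_range_db = c(3, 40),
                                  seed = 1L) {
  stopifnot(inherits(lib, "paf_library"))
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort("class proportions must sum to 1")
  }
  if (is.null(names(proportions)) ||
    !all(names(proportions) %in% c(mixture_classes(), anatomical_classes()))) {
    abort("proportions must be named by valid class labels")
  }
  chrom <- lib$chromophores
  N <- length(chrom)
  K <- nrow(lib$matrix)

  # largest-remainder apportionment of n over the classes
  raw <- proportions * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    up <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[up] <- counts[up] + 1
  }

  with_seed_(seed, {
    C <- matrix(0, n, N)
    cls <- character(n)
    at <- 1L
    for (k in seq_along(counts)) {
      nk <- counts[k]
      if (nk == 0) next
      idx <- at:(at + nk - 1)
      C[idx, ] <- sample_conc_matrix(nk, names(counts)[k], N, chrom)
      cls[idx] <- names(counts)[k]
      at <- at + nk
    }

    x <- if (is.numeric(fluence)) {
      if (any(fluence < 0)) abort("fluence severity must be non-negative")
      rep(fluence[1], n)
    } else {
      switch(match.arg(fluence),
        unit = rep(0, n),
        random = runif(n, x_range[1], x_range[2])
      )
    }
    snr <- runif(n, snr_range_db[1], snr_range_db[2])

    Phi <- fluence_profile(x, lib$grid)
    if (is.null(dim(Phi))) Phi <- matrix(Phi, n, K, byrow = TRUE)
    A0 <- (C %*% t(lib$matrix)) * Phi
    ps <- rowMeans(A0^2)
    alpha <- sqrt(10^(snr / 10) / ps)
    A <- A0 * alpha + matrix(rnorm(n * K), n, K)

    colnames(C) <- chrom
    out <- tibble(
      mixture_class = cls,
      fluence_x = x,
      snr_db = snr,
      concentration = C,
      amplitudes = A
    )
    attr(out, "grid") <- lib$grid
    attr(out, "chromophores") <- chrom
    attr(out, "library_hash") <- library_hash(lib)
    attr(out, "seed") <- seed
    out
  })
}

library_hash <- function(lib) {
  rlang::hash(list(lib$grid$wavelengths_nm, lib$chromophores, lib$matrix))
}

#' Post-hoc structural mixture classification
#'
#' Classifies concentration vectors by their structure rather than by the
#' class that generated them: one-hot is `pure`, two-component support is
#' `binary`, a maximum in `[0.9, 0.99]` is `extreme`, in `[0.7, 0.9)` is
#' `dominant`, anything else `random`. Useful for reporting per-group
#' accuracy when anatomical draws should be folded into mixture groups.
#'
#' @param concentration n x N concentration matrix (or a dataset tibble with
#'   a `concentration` column).
#' @return Character vector of structural class labels.
#' @export
structural_class <- function(concentration) {
  C <- if (is.data.frame(concentration)) {
    concentration$concentration
  } else {
    as.matrix(concentration)
  }
  supp <- rowSums(C > 1e-12)
  mx <- apply(C, 1, max)
  dplyr::case_when(
    supp == 1 ~ "pure",
    supp == 2 ~ "binary",
    mx >= 0.9 ~ "extreme",
    mx >= 0.7 ~ "dominant",
    TRUE ~ "random"
  )
}

#' Read a simulator configuration from YAML
#'
#' Maps a YAML file with keys `size`, `class_proportions`, `fluence`
#' (`mode`, `x_range`), `noise` (`snr_range_db`) and `seed` onto the
#' arguments of [simulate_fingerprints()].
#'
#' @param path YAML file path.
#' @return Named list of arguments suitable for
#'   `do.call(simulate_fingerprints, c(list(lib = lib), cfg))`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- list(n = as.integer(y$size))
  if (!is.null(y$class_proportions)) {
    cfg$proportions <- unlist(y$class_proportions)
  }
  if (!is.null(y$fluence$mode)) cfg$fluence <- y$fluence$mode
  if (!is.null(y$fluence$x_range)) cfg$x_range <- as.numeric(y$fluence$x_range)
  if (!is.null(y$noise$snr_range_db)) {
    cfg$snr_range_db <- as.numeric(y$noise$snr_range_db)
  }
  if (!is.null(y$seed)) cfg$seed <- as.integer(y$seed)
  cfg
}

#' Export a fingerprint dataset to CSV
#'
#' Flattens the matrix columns into named scalar columns (`amp_700` ...,
#' `HbO2` ...) for small datasets; intended for interchange, not bulk
#' storage.
#'
#' @param data Dataset tibble from [simulate_fingerprints()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fingerprints_csv <- function(data, path) {
  grid <- attr(data, "grid")
  amp <- as.data.frame(data$amplitudes)
  names(amp) <- paste0("amp_", grid$wavelengths_nm)
  conc <- as.data.frame(data$concentration)
  flat <- dplyr::bind_cols(
    data[, c("mixture_class", "fluence_x", "snr_db")],
    conc, amp
  )
  readr::write_csv(flat, path)
  invisible(path)
}
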