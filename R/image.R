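#' Multispectral photoacoustic image stack
#'
#' Wraps a 3D `(wavelength, y, x)` or 4D `(wavelength, z, y, x)` array with
#' its wavelength grid and optional per-wavelength pulse energies. The
#' wavelength axis comes first and must match the grid length.
#'
#' @param data Numeric 3D or 4D array, wavelength axis first.
#' @param grid A `paf_grid` with K matching `dim(data)[1]`.
#' @param pulse_energy Optional positive per-wavelength pulse energies
#'   (length K), used by [energy_normalize()].
#' @param pixel_size_mm Optional pixel/voxel size metadata.
#' @return A `paf_stack` object (the array with attributes).
#' @export
multispectral_stack <- function(data, grid, pulse_energy = NULL,
                                pixel_size_mm = NULL) {
  stopifnot(inherits(grid, "paf_grid"))
  d <- dim(data)
  if (is.null(d) || !(length(d) %in% c(3, 4))) {
    abort("data must be a 3D (wavelength, y, x) or 4D (wavelength, z, y, x) array")
  }
  if (d[1] != length(grid$wavelengths_nm)) {
    abort(sprintf(
      "wavelength axis length %d does not match grid K = %d",
      d[1], length(grid$wavelengths_nm)
    ))
  }
  if (!is.null(pulse_energy)) {
    if (length(pulse_energy) != d[1]) {
      abort("pulse_energy must have one entry per wavelength")
    }
    if (any(!is.finite(pulse_energy)) || any(pulse_energy <= 0)) {
      abort("pulse energies must be positive and finite")
    }
  }
  structure(
    data,
    grid = grid,
    pulse_energy = pulse_energy,
    pixel_size_mm = pixel_size_mm,
    class = "paf_stack"
  )
}

#' @export
print.paf_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<paf_stack> %s (K = %d wavelengths)%s\n",
    paste(d, collapse = " x "), d[1],
    if (is.null(attr(x, "pulse_energy"))) "" else ", energy-calibrated"
  ))
  invisible(x)
}

#' Correct for pulse-to-pulse laser energy
#'
#' Divides each wavelength frame by its recorded pulse energy, removing
#' per-pulse laser energy fluctuations (it does not compensate depth- or
#' tissue-dependent fluence). Energies are reset to 1 afterwards, so the
#' operation is idempotent.
#'
#' @param stack A `paf_stack` with `pulse_energy` set.
#' @return The normalized `paf_stack`.
#' @export
energy_normalize <- function(stack) {
  stopifnot(inherits(stack, "paf_stack"))
  en <- attr(stack, "pulse_energy")
  if (is.null(en)) abort("stack has no pulse_energy table")
  d <- dim(stack)
  out <- unclass(stack) / array(en, d) # recycles along axis 1
  out <- multispectral_stack(
    out, attr(stack, "grid"),
    pulse_energy = rep(1, d[1]),
    pixel_size_mm = attr(stack, "pixel_size_mm")
  )
  out
}

#' Maximum amplitude projection
#'
#' Collapses a volumetric stack to 2D by taking, per wavelength and per
#' `(y, x)` position, the maximum over the depth axis.
#'
#' @param stack A 4D `paf_stack` `(wavelength, z, y, x)`.
#' @return A 3D `paf_stack` `(wavelength, y, x)`.
#' @export
map_projection <- function(stack) {
  stopifnot(inherits(stack, "paf_stack"))
  d <- dim(stack)
  if (length(d) != 4) abort("map_projection needs a 4D stack with a depth axis")
  if (d[2] < 1) abort("empty depth axis")
  out <- apply(unclass(stack), c(1, 3, 4), max)
  multispectral_stack(
    out, attr(stack, "grid"),
    pulse_energy = attr(stack, "pulse_energy"),
    pixel_size_mm = attr(stack, "pixel_size_mm")
  )
}

#' Per-pixel spectral unmixing of an image stack
#'
#' Extracts every pixel's wavelength vector as a fingerprint and unmixes it.
#' The recurrent-model path max-normalizes each fingerprint before
#' prediction; the NNLS path solves on the raw energy-normalized vector and
#' renormalizes the coefficients onto the simplex. Pixels whose peak
#' amplitude falls below `amplitude_threshold` times the image maximum, or
#' whose fingerprint contains non-finite values, are masked rather than
#' unmixed. Oxygen saturation is computed at unmasked pixels.
#'
#' @param stack A 3D `paf_stack` `(wavelength, y, x)` (apply
#'   [map_projection()] first for volumes), energy-normalized if pulse
#'   energies are relevant.
#' @param lib A `paf_library` on the same grid.
#' @param method A fitted `paf_fit` (recurrent model) or `"nnls"`.
#' @param amplitude_threshold Mask threshold relative to the image maximum
#'   (default 0.05).
#' @return A `paf_concentration_map`: tibble with `y`, `x`, `masked`, one
#'   fraction column per chromophore, and `so2`; method and shape are
#'   carried in attributes.
#' @export
unmix_image <- function(stack, lib, method = "nnls",
                        amplitude_threshold = 0.05) {
  stopifnot(inherits(stack, "paf_stack"), inherits(lib, "paf_library"))
  d <- dim(stack)
  if (length(d) != 3) abort("unmix_image needs a 3D (wavelength, y, x) stack")
  gw <- attr(stack, "grid")$wavelengths_nm
  if (!isTRUE(all.equal(gw, lib$grid$wavelengths_nm))) {
    abort("stack and library wavelength grids differ")
  }
  K <- d[1]
  npix <- d[2] * d[3]
  # pixel-major fingerprints: row = pixel, column = wavelength
  F_ <- t(matrix(as.numeric(stack), K, npix))
  peak <- apply(F_, 1, function(r) if (all(is.finite(r))) max(r) else NA_real_)
  thr <- amplitude_threshold * max(F_[is.finite(F_)], na.rm = TRUE)
  masked <- !is.finite(peak) | peak < thr | peak <= 0
  chrom <- lib$chromophores
  P <- matrix(NA_real_, npix, length(chrom))
  colnames(P) <- chrom
  tag <- "NNLS"
  if (inherits(method, "paf_fit")) {
    tag <- "PAF"
    if (any(!masked)) {
      P[!masked, ] <- predict(method, F_[!masked, , drop = FALSE],
        grid = lib$grid, type = "matrix"
      )
    }
  } else if (identical(method, "nnls")) {
    if (any(!masked)) {
      res <- nnls_unmix(F_[!masked, , drop = FALSE], lib)
      P[!masked, ] <- res$nnls_fraction
    }
  } else {
    abort("method must be a paf_fit or \"nnls\"")
  }
  idx <- expand.grid(y = seq_len(d[2]), x = seq_len(d[3]))
  out <- dplyr::bind_cols(
    tibble(y = idx$y, x = idx$x, masked = masked),
    as_tibble(as.data.frame(P))
  )
  out$so2 <- so2(P)
  attr(out, "method") <- tag
  attr(out, "shape") <- d[2:3]
  attr(out, "chromophores") <- chrom
  attr(out, "amplitude_threshold") <- amplitude_threshold
  class(out) <- c("paf_concentration_map", class(out))
  out
}

#' Per-region statistics of a concentration map
#'
#' Mean and standard deviation of each chromophore fraction (and sO2) over
#' the unmasked pixels of each labeled region of interest. Fold changes
#' between regions can be computed as ratios of the reported means.
#'
#' @param map A `paf_concentration_map`.
#' @param rois Integer label matrix of the map's `(y, x)` shape; 0 = no ROI.
#' @return Tibble with `roi`, `chromophore`, `mean`, `sd`, `n`.
#' @export
region_stats <- function(map, rois) {
  stopifnot(inherits(map, "paf_concentration_map"))
  shape <- attr(map, "shape")
  if (!all(dim(rois) == shape)) abort("ROI labels must match the map shape")
  chrom <- c(attr(map, "chromophores"), "so2")
  lab <- rois[cbind(map$y, map$x)]
  labels <- sort(unique(lab[lab > 0]))
  if (length(labels) == 0) abort("no labeled ROI pixels")
  dplyr::bind_rows(lapply(labels, function(l) {
    sel <- lab == l & !map$masked
    if (!any(sel)) abort(sprintf("ROI %d has no unmasked pixels", l))
    dplyr::bind_rows(lapply(chrom, function(ch) {
      v <- map[[ch]][sel]
      v <- v[is.finite(v)]
      tibble(
        roi = l, chromophore = ch,
        mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
        n = length(v)
      )
    }))
  }))
}

phantom_compositions <- function() {
  list(
    hbo2_rich = c(HbO2 = 0.9, HbR = 0.1, lipid = 0, water = 0, collagen = 0),
    hbr_rich = c(HbO2 = 0.1, HbR = 0.9, lipid = 0, water = 0, collagen = 0),
    lipid = c(HbO2 = 0, HbR = 0, lipid = 1, water = 0, collagen = 0),
    collagen_water = c(HbO2 = 0, HbR = 0, lipid = 0, water = 0.4, collagen = 0.6),
    water = c(HbO2 = 0, HbR = 0, lipid = 0, water = 1, collagen = 0)
  )
}

#' Synthetic five-region phantom stack
#'
#' Builds a fully synthetic analogue of a multicomponent imaging phantom:
#' five labeled square regions (oxygenated-blood-rich, deoxygenated-blood-
#' rich, lipid, collagen+water, water) on a signal-free background, forward-
#' modeled through the spectral library with a configurable fluence severity
#' and per-pixel SNR-calibrated noise.
#'
#' @param lib A `paf_library` with the canonical five chromophores.
#' @param snr_db Per-pixel SNR in dB (default 10, a realistically low
#'   experimental level), or `NULL` for a noiseless phantom.
#' @param fluence_x Fluence severity (default 0 = unit fluence).
#' @param region_size Side of each square region in pixels.
#' @param gap Background gap between regions in pixels.
#' @param seed Integer seed for the noise.
#' @return List with `stack` (3D `paf_stack`), `labels` (integer y x x
#'   matrix, 0 = background), `truth` (tibble: region label, name and true
#'   fractions).
#' @export
phantom_stack <- function(lib, snr_db = 10, fluence_x = 0,
                          region_size = 10, gap = 3, seed = 1L) {
  stopifnot(inherits(lib, "paf_library"))
  comps <- phantom_compositions()
  chrom <- paf_chromophores()
  if (!identical(lib$chromophores, chrom)) {
    abort("phantom_stack requires the canonical five-chromophore library")
  }
  nr <- length(comps)
  ny <- region_size + 2 * gap
  nx <- nr * region_size + (nr + 1) * gap
  labels <- matrix(0L, ny, nx)
  for (r in seq_len(nr)) {
    x0 <- gap + (r - 1) * (region_size + gap)
    labels[(gap + 1):(gap + region_size), (x0 + 1):(x0 + region_size)] <- r
  }
  K <- nrow(lib$matrix)
  phi <- fluence_profile(fluence_x, lib$grid)
  Cm <- do.call(rbind, comps)[, chrom]
  F0 <- clean_fingerprint(Cm, lib, phi) # nr x K clean fingerprints
  arr <- array(0, c(K, ny, nx))
  with_seed_(seed, {
    for (r in seq_len(nr)) {
      pix <- which(labels == r, arr.ind = TRUE)
      n <- nrow(pix)
      fp <- matrix(F0[r, ], n, K, byrow = TRUE)
      if (!is.null(snr_db)) fp <- add_noise(fp, rep(snr_db, n))
      for (i in seq_len(n)) arr[, pix[i, 1], pix[i, 2]] <- fp[i, ]
    }
  })
  truth <- dplyr::bind_cols(
    tibble(region = seq_len(nr), name = names(comps)),
    as_tibble(as.data.frame(Cm))
  )
  list(
    stack = multispectral_stack(arr, lib$grid),
    labels = labels,
    truth = truth
  )
}

#' Load a multispectral stack from single-wavelength TIFF frames
#'
#' Stacks one grayscale 2D TIFF per wavelength (in grid order) into a 3D
#' `paf_stack`. Requires the `tiff` package.
#'
#' @param files Character vector of TIFF paths, one per grid wavelength.
#' @param grid A `paf_grid` of matching length.
#' @param pulse_energy Optional per-wavelength energies (see
#'   [load_pulse_energy()]).
#' @return A 3D `paf_stack`.
#' @export
stack_from_tiff <- function(files, grid, pulse_energy = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("reading TIFF stacks requires the 'tiff' package")
  }
  if (length(files) != length(grid$wavelengths_nm)) {
    abort("need exactly one TIFF per grid wavelength")
  }
  frames <- lapply(files, tiff::readTIFF)
  d <- dim(frames[[1]])
  arr <- array(0, c(length(files), d[1], d[2]))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
  multispectral_stack(arr, grid, pulse_energy = pulse_energy)
}

#' Load a per-wavelength pulse-energy table
#'
#' Reads a two-column CSV `wavelength_nm,energy` and returns energies
#' aligned to `grid` order.
#'
#' @param path CSV path.
#' @param grid A `paf_grid`.
#' @return Numeric vector of energies in grid order.
#' @export
load_pulse_energy <- function(path, grid) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  names(tb)[1:2] <- c("wavelength_nm", "energy")
  idx <- match(grid$wavelengths_nm, tb$wavelength_nm)
  if (any(is.na(idx))) {
    abort(sprintf(
      "no pulse energy recorded for %g nm",
      grid$wavelengths_nm[which(is.na(idx))[1]]
    ))
  }
  en <- tb$energy[idx]
  if (any(!is.finite(en)) || any(en <= 0)) {
    abort("pulse energies must be positive and finite")
  }
  en
}
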