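#' Dual-band near-infrared wavelength grid
#'
#' Builds the default acquisition grid: two laser bands, 700--970 nm
#' ("signal") and 1160--1400 nm ("idle"), sampled at 10 nm steps inclusive of
#' both band edges. The default grid has K = 53 points (28 + 25).
#'
#' @param step Wavelength step in nm (default 10).
#' @param band_edges List of `c(start, end)` pairs in nm.
#' @return A `paf_grid` object: list with `wavelengths_nm` (strictly
#'   increasing numeric) and `band_edges`.
#' @export
#' @examples
#' g <- default_grid()
#' length(g$wavelengths_nm)  # 53
default_grid <- function(step = 10, band_edges = list(c(700, 970), c(1160, 1400))) {
  wl <- unlist(lapply(band_edges, function(b) seq(b[1], b[2], by = step)))
  new_grid(wl, band_edges)
}

#' Construct a wavelength grid
#'
#' @param wavelengths_nm Strictly increasing numeric vector of wavelengths.
#' @param band_edges List of `c(start, end)` nm pairs; every grid point must
#'   fall inside exactly one band. Defaults to one band spanning the grid.
#' @return A `paf_grid` object.
#' @export
new_grid <- function(wavelengths_nm,
                     band_edges = list(range(wavelengths_nm))) {
  wl <- as.numeric(wavelengths_nm)
  if (length(wl) < 1) abort("a wavelength grid needs at least one point")
  if (any(!is.finite(wl))) abort("grid wavelengths must be finite")
  if (is.unsorted(wl, strictly = TRUE)) {
    abort("grid wavelengths must be strictly increasing")
  }
  hits <- vapply(wl, function(w) {
    sum(vapply(band_edges, function(b) w >= b[1] && w <= b[2], logical(1)))
  }, integer(1))
  if (any(hits != 1L)) {
    abort(sprintf(
      "grid point %g nm lies in %d bands (must be exactly 1)",
      wl[which(hits != 1L)[1]], hits[which(hits != 1L)[1]]
    ))
  }
  structure(
    list(wavelengths_nm = wl, band_edges = band_edges),
    class = "paf_grid"
  )
}

#' @export
print.paf_grid <- function(x, ...) {
  bands <- paste(vapply(x$band_edges, function(b) {
    sprintf("%g-%g nm", b[1], b[2])
  }, character(1)), collapse = ", ")
  cat(sprintf(
    "<paf_grid> K = %d wavelengths in bands %s\n",
    length(x$wavelengths_nm), bands
  ))
  invisible(x)
}

#' @export
length.paf_grid <- function(x) length(x$wavelengths_nm)

# wavelengths min-max normalized over the full grid, used both by the
# fluence prior and as the per-step position feature of the recurrent model
grid_unit_position <- function(grid) {
  wl <- grid$wavelengths_nm
  if (length(wl) == 1) return(0)
  (wl - min(wl)) / (max(wl) - min(wl))
}

#' Construct an absorption spectrum
#'
#' A per-chromophore absorption-coefficient spectrum in the source's raw
#' absorbance units. Rows are sorted by wavelength; values must be
#' non-negative and finite.
#'
#' @param wavelength_nm Numeric wavelengths in nm.
#' @param value Non-negative absorption values, same length.
#' @param name Chromophore label.
#' @return A `paf_spectrum`: tibble with columns `wavelength_nm`, `value`
#'   and a `chromophore` attribute.
#' @export
absorption_spectrum <- function(wavelength_nm, value, name) {
  w <- as.numeric(wavelength_nm)
  v <- as.numeric(value)
  if (length(w) != length(v)) abort("wavelengths and values differ in length")
  if (length(w) < 2) abort(sprintf("spectrum '%s' needs at least 2 rows", name))
  if (any(!is.finite(w)) || any(!is.finite(v))) {
    abort(sprintf("spectrum '%s' contains non-finite entries", name))
  }
  if (any(v < 0)) {
    abort(sprintf(
      "spectrum '%s' has a negative value at row %d",
      name, which(v < 0)[1]
    ))
  }
  ord <- order(w)
  w <- w[ord]
  v <- v[ord]
  if (anyDuplicated(w)) {
    abort(sprintf("spectrum '%s' has duplicated wavelengths", name))
  }
  out <- tibble(wavelength_nm = w, value = v)
  attr(out, "chromophore") <- as.character(name)
  class(out) <- c("paf_spectrum", class(out))
  out
}

#' Load an absorption spectrum from a two-column CSV
#'
#' Reads a `wavelength_nm,value` table (header optional), sorts by
#' wavelength, and validates it. Parse failures report the offending row.
#'
#' @param path Path to the CSV file.
#' @param name Chromophore label to attach.
#' @return A `paf_spectrum` object.
#' @export
load_spectrum <- function(path, name) {
  if (!file.exists(path)) abort(sprintf("spectrum file not found: '%s'", path))
  raw <- read.csv(path,
    header = FALSE, colClasses = "character",
    strip.white = TRUE, blank.lines.skip = TRUE
  )
  if (ncol(raw) < 2) abort(sprintf("'%s' must have two columns", path))
  offset <- 0L
  if (nrow(raw) >= 1 &&
    is.na(suppressWarnings(as.numeric(raw[1, 1])))) {
    raw <- raw[-1, , drop = FALSE] # header row
    offset <- 1L
  }
  if (nrow(raw) < 2) {
    abort(sprintf("'%s' has fewer than 2 data rows", path))
  }
  w <- suppressWarnings(as.numeric(raw[[1]]))
  v <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(!is.finite(w) | !is.finite(v))
  if (length(bad) > 0) {
    abort(sprintf(
      "non-numeric cell in row %d of '%s'", bad[1] + offset, path
    ))
  }
  neg <- which(v < 0)
  if (length(neg) > 0) {
    abort(sprintf(
      "negative absorption value in row %d of '%s'", neg[1] + offset, path
    ))
  }
  absorption_spectrum(w, v, name)
}

#' Build a spectral library on a common wavelength grid
#'
#' Linearly interpolates each chromophore's absorption spectrum onto the
#' grid, retaining raw absorbance units (no rescaling). Every grid point
#' must lie inside every spectrum's wavelength support: extrapolation is an
#' error. A warning is issued when column maxima differ by more than 1000x,
#' which usually indicates mixed units across sources.
#'
#' @param spectra List of `paf_spectrum` objects (or a named list of
#'   two-column data frames). Order defines the column order.
#' @param grid A `paf_grid`.
#' @return A `paf_library`: list with `grid`, `chromophores`, and `matrix`
#'   (K x N absorption values, one column per chromophore).
#' @export
#' @examples
#' lib <- synthetic_nir_library()
#' dim(lib$matrix)  # 53 x 5
build_library <- function(spectra, grid) {
  stopifnot(inherits(grid, "paf_grid"))
  if (length(spectra) < 1) abort("need at least one spectrum")
  nms <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    attr(s, "chromophore") %||% names(spectra)[i] %||% paste0("chr", i)
  }, character(1))
  wl <- grid$wavelengths_nm
  cols <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    sw <- s[["wavelength_nm"]]
    sv <- s[["value"]]
    out_of <- wl < min(sw) | wl > max(sw)
    if (any(out_of)) {
      abort(sprintf(
        "grid point %g nm is outside the support of chromophore '%s' (%g-%g nm)",
        wl[which(out_of)[1]], nms[i], min(sw), max(sw)
      ))
    }
    approx(sw, sv, xout = wl, method = "linear", ties = "ordered")$y
  })
  m <- do.call(cbind, cols)
  colnames(m) <- nms
  maxes <- apply(m, 2, max)
  if (max(maxes) > 0 && min(maxes) > 0 && max(maxes) / min(maxes) > 1e3) {
    warn(paste0(
      "library column maxima differ by more than 1000x; ",
      "check that all spectra use consistent units"
    ))
  }
  structure(
    list(grid = grid, chromophores = nms, matrix = m),
    class = "paf_library"
  )
}

#' @export
print.paf_library <- function(x, ...) {
  cat(sprintf(
    "<paf_library> %d wavelengths x %d chromophores (%s)\n",
    nrow(x$matrix), ncol(x$matrix), paste(x$chromophores, collapse = ", ")
  ))
  invisible(x)
}

#' @export
as_tibble.paf_library <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$matrix))
  dplyr::bind_cols(tibble(wavelength_nm = x$grid$wavelengths_nm), out)
}

#' Write / read a spectral library as CSV plus a YAML sidecar
#'
#' The CSV holds `wavelength_nm` plus one named column per chromophore at
#' full precision; the sidecar (`<path>.yml`) records the band edges so the
#' grid round-trips.
#'
#' @param lib A `paf_library`.
#' @param path Output CSV path.
#' @return `write_library` returns `path` invisibly; `read_library` returns
#'   a `paf_library`.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "paf_library"))
  readr::write_csv(as_tibble(lib), path)
  yaml::write_yaml(
    list(
      band_edges = lapply(lib$grid$band_edges, as.numeric),
      chromophores = lib$chromophores
    ),
    paste0(path, ".yml")
  )
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  # base strtod parsing round-trips the written doubles exactly
  tb <- read.csv(path, check.names = FALSE)
  side <- paste0(path, ".yml")
  wl <- tb$wavelength_nm
  band_edges <- if (file.exists(side)) {
    lapply(yaml::read_yaml(side)$band_edges, as.numeric)
  } else {
    list(range(wl))
  }
  grid <- new_grid(wl, band_edges)
  m <- as.matrix(tb[, setdiff(names(tb), "wavelength_nm"), drop = FALSE])
  structure(
    list(grid = grid, chromophores = colnames(m), matrix = m),
    class = "paf_library"
  )
}

# sum-of-Gaussians spectrum evaluated over a wavelength vector
gaussian_sum_spectrum <- function(wl, centers, widths, amps, baseline = 0.02) {
  v <- rep(baseline, length(wl))
  for (j in seq_along(centers)) {
    v <- v + amps[j] * exp(-0.5 * ((wl - centers[j]) / widths[j])^2)
  }
  v
}

#' Synthetic near-infrared chromophore spectra
#'
#' A deterministic, fully synthetic stand-in for digitized literature
#' absorption spectra of the five dominant endogenous NIR chromophores.
#' Each spectrum is a smooth sum of Gaussians whose peak positions follow
#' well-known qualitative features of the real absorbers (deoxyhemoglobin
#' peak near 760 nm, lipid peaks near 930 and 1210 nm, water bands near 970
#' and beyond 1400 nm, collagen overlapping lipid and water around
#' 1200--1350 nm), so that spectral overlap structure -- in particular the
#' difficulty of collagen -- is qualitatively realistic. The absolute values
#' are NOT measured absorption coefficients; supply digitized spectra via
#' [load_spectrum()] for quantitative work with real data.
#'
#' @param step Sampling step in nm of the source tables (default 2).
#' @return Named list of five `paf_spectrum` objects in canonical order.
#' @seealso [synthetic_nir_library()]
#' @export
synthetic_nir_spectra <- function(step = 2) {
  wl <- seq(650, 1450, by = step)
  spec <- list(
    HbO2 = gaussian_sum_spectrum(
      wl,
      centers = c(920, 1120), widths = c(95, 160), amps = c(0.85, 0.35)
    ),
    HbR = gaussian_sum_spectrum(
      wl,
      centers = c(758, 1060), widths = c(55, 190), amps = c(1.15, 0.30)
    ),
    lipid = gaussian_sum_spectrum(
      wl,
      centers = c(930, 1210, 1395), widths = c(35, 45, 60),
      amps = c(0.55, 1.60, 0.50)
    ),
    water = gaussian_sum_spectrum(
      wl,
      centers = c(975, 1195, 1430), widths = c(45, 70, 80),
      amps = c(0.70, 0.45, 1.40)
    ),
    collagen = gaussian_sum_spectrum(
      wl,
      centers = c(910, 1200, 1350), widths = c(60, 60, 70),
      amps = c(0.50, 1.20, 0.80)
    )
  )
  out <- lapply(names(spec), function(nm) {
    absorption_spectrum(wl, spec[[nm]], nm)
  })
  names(out) <- names(spec)
  out
}

#' Synthetic spectral library on the default grid
#'
#' Convenience wrapper: [synthetic_nir_spectra()] interpolated onto `grid`.
#'
#' @param grid A `paf_grid` (default [default_grid()]).
#' @return A `paf_library` (53 x 5 on the default grid).
#' @export
synthetic_nir_library <- function(grid = default_grid()) {
  build_library(synthetic_nir_spectra(), grid)
}

#' Random smooth synthetic spectra
#'
#' Generates `n` random sum-of-Gaussians spectra with a controllable degree
#' of pairwise overlap, for property tests and solver benchmarks. With
#' `overlap = 0` every spectrum draws its own peak centers; with
#' `overlap = 1` all spectra share one pool of centers and differ only in
#' amplitudes and widths.
#'
#' @param n Number of spectra.
#' @param seed Integer seed (required, for reproducibility).
#' @param n_peaks Gaussians per spectrum.
#' @param overlap Probability in `[0, 1]` that a peak center is drawn from
#'   a shared pool rather than independently.
#' @param wavelength_range Support of the spectra in nm.
#' @return Named list of `paf_spectrum` objects (`chr1` ... `chrn`).
#' @export
synthetic_spectra <- function(n, seed, n_peaks = 3, overlap = 0,
                              wavelength_range = c(650, 1450)) {
  with_seed_(seed, {
    wl <- seq(wavelength_range[1], wavelength_range[2], by = 2)
    pool <- runif(n_peaks, wavelength_range[1] + 50, wavelength_range[2] - 50)
    out <- lapply(seq_len(n), function(i) {
      shared <- runif(n_peaks) < overlap
      centers <- ifelse(
        shared, pool,
        runif(n_peaks, wavelength_range[1] + 50, wavelength_range[2] - 50)
      )
      widths <- runif(n_peaks, 30, 120)
      amps <- runif(n_peaks, 0.2, 1.5)
      absorption_spectrum(
        wl, gaussian_sum_spectrum(wl, centers, widths, amps),
        paste0("chr", i)
      )
    })
    names(out) <- paste0("chr", seq_len(n))
    out
  })
}
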