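#' Non-negative least squares unmixing of one fingerprint
#'
#' Solves `min || M c - f ||_2` subject to `c >= 0` with a deterministic
#' Lawson-Hanson active-set solver (ties in active-set entry broken by
#' lowest index). Raw coefficients are in library units; for comparison
#' against ground-truth fractions they are renormalized onto the simplex.
#' When every coefficient is zero the fractions are undefined (`NA`), which
#' downstream metrics score as a zero prediction.
#'
#' NNLS consumes the raw (energy-normalized but not max-scaled) fingerprint:
#' it relies on relative amplitudes, and the solution is scale-equivariant,
#' so a secondary max-scaling only rescales the raw coefficients.
#'
#' @param lib A `paf_library`.
#' @param f Length-K fingerprint (amplitudes on the library grid).
#' @return List with `raw_coefficients` (length N, `>= 0`), `fractions`
#'   (simplex vector, or `NA`s when undefined), `defined` (logical) and
#'   `residual_norm`.
#' @export
#' @examples
#' lib <- synthetic_nir_library()
#' f <- clean_fingerprint(c(1, 0, 0, 0, 0), lib)
#' nnls_solve(lib, f)$fractions
nnls_solve <- function(lib, f) {
  stopifnot(inherits(lib, "paf_library"))
  f <- as.numeric(f)
  if (length(f) != nrow(lib$matrix)) {
    abort(sprintf(
      "fingerprint length %d does not match library grid K = %d",
      length(f), nrow(lib$matrix)
    ))
  }
  if (any(!is.finite(f))) abort("fingerprint has non-finite amplitudes")
  res <- nnls_batch_cpp(lib$matrix, matrix(f, 1))
  raw <- drop(res$coefficients)
  names(raw) <- lib$chromophores
  s <- sum(raw)
  fr <- if (s > 0) raw / s else rep(NA_real_, length(raw))
  names(fr) <- lib$chromophores
  list(
    raw_coefficients = raw,
    fractions = fr,
    defined = s > 0,
    residual_norm = res$residual_norm[1]
  )
}

#' Batch NNLS unmixing
#'
#' Applies [nnls_solve()] to every fingerprint, preserving row order.
#' Data-frame-first: given a dataset tibble with an `amplitudes` matrix
#' column the results are appended as new columns; a bare matrix of
#' fingerprints is also accepted.
#'
#' @param data Dataset tibble (with matrix column `amplitudes`) or an
#'   n x K matrix.
#' @param lib A `paf_library`.
#' @return The input tibble with matrix column `nnls_fraction` (n x N,
#'   simplex rows, `NA` where undefined), `nnls_raw` (n x N raw
#'   coefficients), `nnls_residual` and logical `nnls_defined` appended.
#'   For matrix input, a fresh tibble with those columns.
#' @export
nnls_unmix <- function(data, lib) {
  stopifnot(inherits(lib, "paf_library"))
  A <- if (is.data.frame(data)) data$amplitudes else as.matrix(data)
  if (is.null(A)) abort("data has no 'amplitudes' column")
  if (ncol(A) != nrow(lib$matrix)) {
    abort(sprintf(
      "fingerprint length %d does not match library grid K = %d",
      ncol(A), nrow(lib$matrix)
    ))
  }
  if (nrow(A) == 0) {
    res <- list(
      coefficients = matrix(numeric(0), 0, ncol(lib$matrix)),
      residual_norm = numeric(0)
    )
  } else {
    res <- nnls_batch_cpp(lib$matrix, A)
  }
  raw <- res$coefficients
  colnames(raw) <- lib$chromophores
  s <- rowSums(raw)
  fr <- raw / ifelse(s > 0, s, NA_real_)
  out <- if (is.data.frame(data)) data else tibble(.rows = nrow(A))
  out$nnls_raw <- raw
  out$nnls_fraction <- fr
  out$nnls_residual <- res$residual_norm
  out$nnls_defined <- s > 0
  out
}
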