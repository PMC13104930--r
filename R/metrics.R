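as_conc_matrix <- function(x) {
  m <- if (is.data.frame(x)) as.matrix(x) else as.matrix(x)
  storage.mode(m) <- "double"
  m
}

# undefined predictions (all-NA rows from degenerate NNLS solutions) are
# scored as an all-zero prediction so they count as maximal error instead of
# silently dropping out
zero_fill_undefined <- function(pred) {
  bad <- !is.finite(pred)
  if (any(bad)) pred[bad] <- 0
  pred
}

parity_one <- function(tv, pv) {
  ssres <- sum((pv - tv)^2)
  sstot <- sum((tv - mean(tv))^2)
  r2 <- if (sstot > 0) 1 - ssres / sstot else NA_real_
  slope <- if (sstot > 0) {
    sum((tv - mean(tv)) * (pv - mean(pv))) / sstot
  } else {
    NA_real_
  }
  tibble(
    r2 = r2,
    rmse = sqrt(mean((pv - tv)^2)),
    slope = slope,
    r2_regression = if (sstot > 0 && sd(pv) > 0) stats::cor(tv, pv)^2 else NA_real_,
    r2_defined = sstot > 0,
    n = length(tv)
  )
}

#' Parity metrics between true and predicted concentrations
#'
#' Pools all chromophore components of all records into one parity cloud
#' (the headline convention) and reports the coefficient of determination
#' `r2 = 1 - SS_res / SS_tot` about the mean of the true values, the root
#' mean squared componentwise error, and the free-intercept ordinary
#' least-squares slope of predicted on true. The squared Pearson correlation
#' is emitted alongside (`r2_regression`) as a sensitivity variant. Rows of
#' `pred` that are entirely `NA` (undefined unmixing solutions) are scored
#' as zero predictions. When the true values have zero variance `r2` and
#' `slope` are undefined (`r2_defined = FALSE`).
#'
#' @param truth n x N matrix (or data frame) of true fractions.
#' @param pred n x N matrix of predicted fractions, same shape.
#' @param by Optional length-n grouping vector (e.g. mixture class); metrics
#'   are then reported per group.
#' @return Tibble with one row (or one row per group).
#' @export
#' @examples
#' t <- matrix(runif(20), 10)
#' parity_metrics(t, t)  # r2 = 1, rmse = 0, slope = 1
parity_metrics <- function(truth, pred, by = NULL) {
  T_ <- as_conc_matrix(truth)
  P_ <- zero_fill_undefined(as_conc_matrix(pred))
  if (!all(dim(T_) == dim(P_))) abort("truth and pred shapes differ")
  if (nrow(T_) < 1) abort("need at least one record")
  if (is.null(by)) {
    return(parity_one(as.vector(T_), as.vector(P_)))
  }
  stopifnot(length(by) == nrow(T_))
  groups <- split(seq_len(nrow(T_)), by)
  dplyr::bind_rows(
    lapply(groups, function(idx) {
      parity_one(as.vector(T_[idx, , drop = FALSE]),
                 as.vector(P_[idx, , drop = FALSE]))
    }),
    .id = "group"
  )
}

#' Default SNR and fluence strata
#'
#' 5 dB-wide SNR bins over `[3, 40]` dB and width-2 fluence-severity bins
#' over `[0, 20]`.
#'
#' @return Numeric break vectors for [aae()].
#' @export
snr_breaks <- function() c(seq(3, 38, by = 5), 40)

#' @rdname snr_breaks
#' @export
fluence_breaks <- function() seq(0, 20, by = 2)

#' Average absolute error per chromophore
#'
#' The mean of `|pred - true|` per chromophore, optionally stratified by a
#' covariate (SNR, fluence severity, mixture class, ...). Numeric
#' stratifiers are binned with `breaks`; empty strata are absent from the
#' result rather than reported as zero.
#'
#' @param truth,pred n x N matrices of true and predicted fractions
#'   (all-`NA` prediction rows are scored as zero).
#' @param stratify Optional length-n vector: numeric (binned by `breaks`)
#'   or discrete labels.
#' @param breaks Bin breaks for a numeric stratifier (e.g. [snr_breaks()]).
#' @param chromophores Column labels (defaults to `colnames(truth)` or the
#'   canonical five).
#' @return Tibble with columns `chromophore`, `aae`, `n` (and `stratum`,
#'   `stratum_mid` when stratified).
#' @export
aae <- function(truth, pred, stratify = NULL, breaks = NULL,
                chromophores = NULL) {
  T_ <- as_conc_matrix(truth)
  P_ <- zero_fill_undefined(as_conc_matrix(pred))
  if (!all(dim(T_) == dim(P_))) abort("truth and pred shapes differ")
  chrom <- chromophores %||% colnames(T_) %||%
    paste0("c", seq_len(ncol(T_)))
  E <- abs(P_ - T_)
  if (is.null(stratify)) {
    return(tibble(
      chromophore = chrom,
      aae = colMeans(E),
      n = nrow(E)
    ))
  }
  stopifnot(length(stratify) == nrow(T_))
  if (is.numeric(stratify) && !is.null(breaks)) {
    bin <- cut(stratify, breaks = breaks, include.lowest = TRUE, right = FALSE)
    mids <- (head(breaks, -1) + breaks[-1]) / 2
    midmap <- stats::setNames(mids, levels(bin))
  } else {
    bin <- factor(stratify)
    midmap <- NULL
  }
  keep <- !is.na(bin)
  out <- dplyr::bind_rows(lapply(levels(droplevels(bin[keep])), function(lv) {
    idx <- which(bin == lv)
    tibble(
      stratum = lv,
      chromophore = chrom,
      aae = colMeans(E[idx, , drop = FALSE]),
      n = length(idx)
    )
  }))
  if (!is.null(midmap)) out$stratum_mid <- unname(midmap[out$stratum])
  out
}

#' Compare per-test-set metrics between two methods
#'
#' Welch's two-sample, two-tailed t-test on matched lists of metric values
#' (one value per independent test set). When both cohorts are degenerate
#' (zero variance) the comparison falls back to an exact rule: equal means
#' give `t = 0, p = 1`; unequal means are flagged with `p = 0`.
#'
#' @param a,b Equal-length numeric vectors of per-test-set metric values.
#' @param metric_name Label carried into the result.
#' @return One-row tibble with means, `t_statistic`, `p_value` and a
#'   `degenerate` flag.
#' @export
compare_cohorts <- function(a, b, metric_name = "metric") {
  if (length(a) != length(b)) abort("cohorts must have equal length")
  if (length(a) < 2) abort("need at least 2 test sets per cohort")
  degen <- sd(a) == 0 && sd(b) == 0
  if (degen) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    tt <- list(
      statistic = if (same) 0 else sign(mean(a) - mean(b)) * Inf,
      p.value = if (same) 1 else 0
    )
  } else {
    tt <- t.test(a, b, alternative = "two.sided", var.equal = FALSE)
  }
  tibble(
    metric = metric_name,
    mean_a = mean(a),
    mean_b = mean(b),
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    degenerate = degen,
    n = length(a)
  )
}

#' Hemoglobin oxygen saturation
#'
#' `sO2 = HbO2 / (HbO2 + HbR)` from a concentration vector, matrix or data
#' frame with `HbO2` and `HbR` entries. Undefined (both zero, or missing
#' inputs) yields `NA` rather than an error.
#'
#' @param x Named numeric vector, n x N matrix with named columns, or data
#'   frame.
#' @return Numeric in `[0, 1]` (or `NA` where undefined), one value per row.
#' @export
#' @examples
#' so2(c(HbO2 = 0.3, HbR = 0.1, lipid = 0.6))  # 0.75
so2 <- function(x) {
  if (is.null(dim(x))) {
    if (!all(c("HbO2", "HbR") %in% names(x))) {
      abort("x must contain HbO2 and HbR entries")
    }
    hbo <- x[["HbO2"]]
    hbr <- x[["HbR"]]
  } else {
    m <- if (is.data.frame(x)) x else as.data.frame(x)
    hbo <- m[["HbO2"]]
    hbr <- m[["HbR"]]
  }
  if (is.null(hbo) || is.null(hbr)) abort("x must contain HbO2 and HbR entries")
  tot <- hbo + hbr
  out <- ifelse(is.finite(tot) & tot > 0, hbo / tot, NA_real_)
  unname(out)
}
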