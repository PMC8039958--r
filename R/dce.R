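#' Dynamic contrast-enhanced (DCE) MRI series
#'
#' Container for a per-pixel T1-weighted signal-versus-time stack. The signal
#' is stored as a `(rows, cols, time)` array; `times` gives the acquisition
#' timestamp (seconds) of each repetition and `baseline_index` marks the last
#' pre-contrast repetition (contrast is injected after it).
#'
#' @param signal numeric array `(rows, cols, n_repetitions)`.
#' @param times strictly increasing numeric vector of acquisition times in
#'   seconds, one per repetition (at least 3).
#' @param baseline_index 1-based index of the last pre-contrast repetition;
#'   must satisfy `1 <= baseline_index < n_repetitions`.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(signal, times, baseline_index = 1L) {
  if (length(dim(signal)) != 3L)
    stop("`signal` must be a 3D array (rows, cols, time)")
  nt <- dim(signal)[3]
  if (length(times) != nt)
    stop("length(times) must equal the number of repetitions")
  if (nt < 3L) stop("a DCE series needs at least 3 repetitions")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  baseline_index <- as.integer(baseline_index)
  if (baseline_index < 1L || baseline_index >= nt)
    stop("`baseline_index` must lie in [1, n_repetitions - 1]")
  structure(list(signal = signal, times = as.numeric(times),
                 baseline_index = baseline_index),
            class = "dce_series")
}

.dce_flat <- function(series) {
  d <- dim(series$signal)
  matrix(series$signal, d[1] * d[2], d[3])
}

.warn_nan_once <- function(m, what) {
  if (anyNA(m))
    warning(sprintf("NaN/NA signal encountered while computing %s; affected pixels propagate NA", what),
            call. = FALSE)
}

#' Area under the DCE time-series curve
#'
#' Per pixel, the sum of the full dynamic curve over all repetitions (not
#' only the initial uptake), so that slowly enhancing regions - a potential
#' hypoxia signature - contribute. A trapezoidal alternative weighted by the
#' sampling interval is available behind `method = "trapezoid"`.
#'
#' @param series a [dce_series()].
#' @param method `"sum"` (default, plain sum of samples) or `"trapezoid"`.
#' @return numeric matrix `(rows, cols)`. NA in the input propagates.
#' @export
compute_auc <- function(series, method = c("sum", "trapezoid")) {
  stopifnot(inherits(series, "dce_series"))
  method <- match.arg(method)
  m <- .dce_flat(series)
  .warn_nan_once(m, "AUC")
  d <- dim(series$signal)
  if (method == "sum") {
    auc <- rowSums(m)
  } else {
    t <- series$times
    w <- diff(t)
    mid <- (m[, -1, drop = FALSE] + m[, -ncol(m), drop = FALSE]) / 2
    auc <- as.vector(mid %*% w)
  }
  matrix(auc, d[1], d[2])
}

# per-pixel earliest argmax and max, tolerating partial NA (all-NA -> NA)
.series_peak <- function(m) {
  m2 <- m
  m2[is.na(m2)] <- -Inf
  imax <- max.col(m2, ties.method = "first")
  smax <- m2[cbind(seq_len(nrow(m2)), imax)]
  allna <- !is.finite(smax) & smax < 0
  smax[allna] <- NA_real_
  imax[allna] <- NA_integer_
  list(imax = imax, smax = smax)
}

#' Slope of contrast enhancement
#'
#' Per pixel, the signal change from baseline to maximum enhancement over the
#' corresponding time difference (intensity per second). Pixels whose peak
#' coincides with the baseline repetition get slope 0 by convention; all-NA
#' pixels give NA.
#'
#' @inheritParams compute_auc
#' @return numeric matrix `(rows, cols)`.
#' @export
compute_slope <- function(series) {
  stopifnot(inherits(series, "dce_series"))
  m <- .dce_flat(series)
  .warn_nan_once(m, "slope")
  d <- dim(series$signal)
  b <- series$baseline_index
  pk <- .series_peak(m)
  sbase <- m[, b]
  dt <- series$times[pk$imax] - series$times[b]
  slope <- (pk$smax - sbase) / dt
  slope[!is.na(dt) & dt == 0] <- 0
  matrix(slope, d[1], d[2])
}

#' Time to maximum enhancement (TTM)
#'
#' Per pixel, the time (seconds, measured from the baseline acquisition) at
#' which the maximum signal is reached. Ties are broken by the earliest
#' occurrence; all-NA pixels give NA.
#'
#' @inheritParams compute_auc
#' @return numeric matrix `(rows, cols)`; values are elements of
#'   `times - times[baseline_index]`.
#' @export
compute_ttm <- function(series) {
  stopifnot(inherits(series, "dce_series"))
  m <- .dce_flat(series)
  .warn_nan_once(m, "TTM")
  d <- dim(series$signal)
  pk <- .series_peak(m)
  ttm <- series$times[pk$imax] - series$times[series$baseline_index]
  ttm[is.na(pk$imax)] <- NA_real_
  matrix(ttm, d[1], d[2])
}

#' Compute all three semi-quantitative DCE parametric maps
#'
#' @inheritParams compute_auc
#' @return list of class `param_maps` with elements `auc`, `slope`, `ttm`.
#' @export
dce_param_maps <- function(series, method = "sum") {
  maps <- list(auc = compute_auc(series, method = method),
               slope = compute_slope(series),
               ttm = compute_ttm(series))
  class(maps) <- "param_maps"
  maps
}
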