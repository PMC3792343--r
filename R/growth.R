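#' Per-point windowed R-squared of a log2-OD series
#'
#' Each interior point is assigned the R-squared of the least-squares line
#' through the 7-point window centred on it (the point plus the three before
#' and after). The first and last three points carry `NA`. Windows with zero
#' variance in the response (e.g. a flat reading) are assigned 0, which
#' excludes them from the linear region.
#'
#' @param times Numeric vector of times (minutes).
#' @param y Numeric vector of log2(OD600) values, same length.
#' @return Numeric vector of R-squared values with `NA` at the boundaries.
#' @export
windowed_r2 <- function(times, y) {
  n <- length(y)
  stopifnot(length(times) == n)
  if (n < 7L) {
    loxtron_error("loxtron_bounds_error",
                  sprintf("windowed R-squared needs at least 7 points; got %d", n))
  }
  r2 <- rep(NA_real_, n)
  for (i in 4:(n - 3L)) {
    idx <- (i - 3L):(i + 3L)
    yy <- y[idx]; tt <- times[idx]
    if (sd(yy) == 0 || sd(tt) == 0) {
      r2[i] <- 0
    } else {
      r <- suppressWarnings(stats::cor(tt, yy))
      r2[i] <- if (is.na(r)) 0 else r^2
    }
  }
  r2
}

#' Detect the linear (exponential) region shared by replicates
#'
#' Per-point windowed R-squared values are averaged across replicates at each
#' time point, and the longest contiguous stretch with averaged R-squared of
#' at least `threshold` is taken as the linear range (the same time window is
#' used for all replicates). Ties between equal-length stretches resolve to
#' the earliest.
#'
#' @param curve A `growth_curve` (see [make_growth_curves()]), or a list with
#'   `times` and an `od` matrix (one column per replicate).
#' @param threshold Averaged R-squared cutoff (default 0.99).
#' @return A list with `t_start`, `t_end` (minutes) and the index range
#'   `idx` of the window.
#' @export
linear_region <- function(curve, threshold = 0.99) {
  y <- log2(curve$od)
  r2 <- sapply(seq_len(ncol(y)), function(r) windowed_r2(curve$times, y[, r]))
  avg <- rowMeans(r2)
  ok <- !is.na(avg) & avg >= threshold
  if (!any(ok)) {
    loxtron_error("loxtron_no_linear_region_error",
                  "no stretch of averaged R-squared above threshold")
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  best <- cand[which.max(runs$lengths[cand])]  # which.max takes the earliest tie
  idx <- starts[best]:ends[best]
  list(t_start = curve$times[idx[1]], t_end = curve$times[idx[length(idx)]],
       idx = idx)
}

#' Estimate the doubling time from replicate growth curves
#'
#' Fits a least-squares line to log2(OD600) versus time (minutes) for each
#' replicate over the common linear region found by [linear_region()]. The
#' slope has units of doublings per minute, so each replicate's doubling
#' time is its reciprocal; the result is the replicate mean with the
#' standard error across replicates.
#'
#' @param curve A `growth_curve`.
#' @param threshold Passed to [linear_region()].
#' @return A `doubling_time_result`: list with `doubling_time` (minutes),
#'   `standard_error`, `per_replicate`, and `linear_window`.
#' @export
doubling_time <- function(curve, threshold = 0.99) {
  region <- linear_region(curve, threshold)
  idx <- region$idx
  tt <- curve$times[idx]
  dts <- vapply(seq_len(ncol(curve$od)), function(r) {
    yy <- log2(curve$od[idx, r])
    slope <- stats::coef(stats::lm(yy ~ tt))[2]
    if (!is.finite(slope) || slope <= 0) {
      loxtron_error("loxtron_no_growth_error",
                    "non-positive slope in linear window: no growth")
    }
    1 / slope
  }, numeric(1))
  structure(list(
    doubling_time = mean(dts),
    standard_error = if (length(dts) > 1L) sd(dts) / sqrt(length(dts)) else 0,
    per_replicate = dts,
    linear_window = c(region$t_start, region$t_end)
  ), class = "doubling_time_result")
}

#' @export
print.doubling_time_result <- function(x, ...) {
  cat(sprintf("doubling time: %.2f min (SE %.2f, %d replicates), window %.1f-%.1f min\n",
              x$doubling_time, x$standard_error, length(x$per_replicate),
              x$linear_window[1], x$linear_window[2]))
  invisible(x)
}
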