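#' SDNN of a window of RR intervals
#'
#' Sample standard deviation (N - 1 denominator) of the normal-to-normal
#' intervals in a window: sqrt(sum((RR_i - mRR)^2) / (N - 1)).
#'
#' @param x Numeric vector of RR intervals (ms), length >= 2.
#' @return SDNN in ms.
#' @export
#' @examples
#' sdnn(c(800, 810, 790, 800))  # sqrt(200/3)
sdnn <- function(x) {
  if (length(x) < 2) stop("SDNN needs at least 2 intervals", call. = FALSE)
  stats::sd(x)
}

#' Per-second HRV stream from an RR series
#'
#' At each second, SDNN over the most recent `window_beats` beats (all
#' beats with time <= t), or over all available beats while fewer than
#' `window_beats` have occurred. Ticks with fewer than `warmup_beats`
#' beats yield `NA`.
#'
#' @param rr Data frame with columns `t_s` (beat times, strictly
#'   increasing) and `rr_ms` (positive intervals).
#' @param span Number of 1 Hz ticks; defaults to the last beat time.
#' @param window_beats Window size in beats (default 300).
#' @param warmup_beats Minimum beats before HRV is emitted (default 30).
#' @return Data frame with columns `t_s`, `hrv_ms` and logical `partial`
#'   (fewer than `window_beats` beats in the window).
#' @export
hrv_series <- function(rr, span = NULL, window_beats = 300,
                       warmup_beats = 30) {
  stopifnot(is.data.frame(rr), nrow(rr) > 0)
  if (any(rr$rr_ms <= 0)) stop("RR intervals must be positive", call. = FALSE)
  if (is.unsorted(rr$t_s, strictly = TRUE))
    stop("beat times must be strictly increasing", call. = FALSE)
  if (is.null(span)) span <- floor(max(rr$t_s))
  ticks <- seq_len(span)
  idx <- findInterval(ticks, rr$t_s)        # beats with time <= t
  k <- pmin(idx, window_beats)

  # centred cumulative sums give O(1) windowed variance
  x <- rr$rr_ms - mean(rr$rr_ms)
  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x^2))
  lo <- idx - k
  sum1 <- s1[idx + 1L] - s1[lo + 1L]
  sum2 <- s2[idx + 1L] - s2[lo + 1L]
  v <- (sum2 - sum1^2 / k) / (k - 1)
  hrv <- sqrt(pmax(v, 0))
  hrv[idx < warmup_beats] <- NA_real_
  data.frame(t_s = ticks, hrv_ms = hrv, partial = idx < window_beats)
}

#' Remove out-of-range pupil samples
#'
#' Retains samples with diameter inside the physiological band; values
#' smaller than `lower` or larger than `upper` are treated as artifacts
#' (blinks, tracking loss) and excluded. The bounds themselves are kept.
#'
#' @param pupil Data frame with columns `t_s` and `pd_mm`.
#' @param lower,upper Band limits in mm (defaults 2 and 8).
#' @return The filtered data frame, with attribute `n_removed`.
#' @export
clean_pupil <- function(pupil, lower = 2, upper = 8) {
  stopifnot(is.data.frame(pupil))
  keep <- pupil$pd_mm >= lower & pupil$pd_mm <= upper
  out <- pupil[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Estimate per-participant normalization moments from a resting baseline
#'
#' Computes the per-second HRV stream and per-second mean cleaned pupil
#' diameter over the rest recording and returns their means and SDs,
#' which are then used to z-normalize session features and remove
#' inter-individual differences.
#'
#' @param baseline A list with data frames `rr` and `pupil` (a 5-min rest
#'   recording).
#' @param window_beats,warmup_beats Passed to [hrv_series()].
#' @return An object of class `ofs_baseline`: list with `hrv_mean`,
#'   `hrv_sd`, `pd_mean`, `pd_sd`.
#' @export
estimate_baseline <- function(baseline, window_beats = 300,
                              warmup_beats = 30) {
  stopifnot(is.list(baseline), is.data.frame(baseline$rr),
            is.data.frame(baseline$pupil))
  hrv <- hrv_series(baseline$rr, window_beats = window_beats,
                    warmup_beats = warmup_beats)$hrv_ms
  hrv <- hrv[is.finite(hrv)]
  pupil <- clean_pupil(baseline$pupil)
  pd <- tapply(pupil$pd_mm, ceiling(pupil$t_s), mean)
  if (length(hrv) < 2 || length(pd) < 2)
    stop("baseline recording too short to estimate moments", call. = FALSE)
  out <- list(hrv_mean = mean(hrv), hrv_sd = stats::sd(hrv),
              pd_mean = mean(pd), pd_sd = stats::sd(pd))
  if (out$hrv_sd <= 0 || out$pd_sd <= 0)
    stop("degenerate baseline: zero variance", call. = FALSE)
  structure(out, class = "ofs_baseline")
}

#' @export
print.ofs_baseline <- function(x, ...) {
  cat(sprintf("Baseline moments: HRV %.2f +/- %.2f ms, PD %.3f +/- %.3f mm\n",
              x$hrv_mean, x$hrv_sd, x$pd_mean, x$pd_sd))
  invisible(x)
}

#' z-normalize a stream against baseline moments
#'
#' @param x Numeric vector.
#' @param center,scale Baseline mean and SD; `scale` must be positive.
#' @return `(x - center) / scale`.
#' @export
z_normalize <- function(x, center, scale) {
  if (!is.finite(scale) || scale <= 0)
    stop("baseline SD must be positive", call. = FALSE)
  (x - center) / scale
}

#' Build the per-second z-normalized feature table
#'
#' Per-second mean of the cleaned pupil diameter and the per-second HRV
#' (SDNN over the last `window_beats` beats), each z-normalized against
#' the participant's resting baseline. Seconds lacking either channel
#' carry `NA` and are excluded from modelling downstream.
#'
#' @param rr,pupil Session streams as returned by [generate_physio()].
#' @param baseline An [estimate_baseline()] object.
#' @param span Session span in seconds; defaults to the pupil stream end.
#' @param window_beats,warmup_beats Passed to [hrv_series()].
#' @return Data frame of class `ofs_features` with columns `t_s`,
#'   `hrv_z`, `pd_z`, one row per second; attribute `n_missing` counts
#'   incomplete rows.
#' @export
build_feature_table <- function(rr, pupil, baseline, span = NULL,
                                window_beats = 300, warmup_beats = 30) {
  stopifnot(inherits(baseline, "ofs_baseline"))
  if (is.null(span)) span <- floor(max(pupil$t_s))
  if (span < 1 || nrow(rr) == 0 || nrow(pupil) == 0)
    stop("streams do not overlap the requested span", call. = FALSE)
  hrv <- hrv_series(rr, span = span, window_beats = window_beats,
                    warmup_beats = warmup_beats)
  cleaned <- clean_pupil(pupil)
  pd_sec <- tapply(cleaned$pd_mm, ceiling(cleaned$t_s), mean)
  pd <- rep(NA_real_, span)
  sec <- as.integer(names(pd_sec))
  ok <- sec >= 1 & sec <= span
  pd[sec[ok]] <- pd_sec[ok]
  out <- data.frame(
    t_s = seq_len(span),
    hrv_z = z_normalize(hrv$hrv_ms, baseline$hrv_mean, baseline$hrv_sd),
    pd_z = z_normalize(pd, baseline$pd_mean, baseline$pd_sd))
  attr(out, "n_missing") <- sum(!stats::complete.cases(out))
  class(out) <- c("ofs_features", "data.frame")
  out
}
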