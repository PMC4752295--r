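# Traditional heart-rate-variability features: the ten time/frequency
# domain indices used as the comparison baseline, plus the periodogram
# machinery shared with the spectral morphology features.

#' Time-domain HRV features
#'
#' Computes SDNN (sample standard deviation of the R-R intervals, n-1
#' denominator), SDSD, RMSSD and pNN50 from the interval series `z` (ms).
#' SDSD is implemented literally as printed in the source formulation:
#' the square root of the mean squared deviation of the *absolute*
#' successive differences about their mean, averaged over the n-1
#' difference terms. Set `conventional = TRUE` for the textbook variant
#' (sample SD of the signed successive differences).
#'
#' @param z an [rr_series()] or numeric vector of R-R intervals in ms,
#'   length >= 3.
#' @param conventional use sample SD of signed differences for SDSD.
#' @return named numeric vector: `sdnn`, `sdsd`, `rmssd`, `pnn50`.
#' @export
time_domain_features <- function(z, conventional = FALSE) {
  if (inherits(z, "rr_series")) z <- z$z
  n <- length(z)
  if (n < 3) stop("need at least 3 R-R intervals")
  u <- diff(z)
  sdsd <- if (conventional) {
    sd(u)
  } else {
    au <- abs(u)
    sqrt(mean((au - mean(au))^2))
  }
  c(
    sdnn = sd(z),
    sdsd = sdsd,
    rmssd = sqrt(mean(u^2)),
    pnn50 = 100 * sum(abs(u) > 50) / (n - 1)
  )
}

#' Periodogram PSD of the R-R tachogram
#'
#' The irregularly spaced tachogram (interval value against cumulative
#' time) is cubic-spline resampled on a uniform grid at `resample_rate`
#' Hz, mean-removed, and transformed with an FFT periodogram normalized so
#' that integrated power equals the variance of the resampled tachogram.
#'
#' @param z an [rr_series()] or numeric vector (ms).
#' @param resample_rate uniform resampling rate in Hz (default 4).
#' @return object of class `psd_estimate`: `frequencies` (Hz), `power`
#'   (ms^2/Hz), `resample_rate`, and `low_confidence` flag set when the
#'   window is too short to resolve 0.04 Hz.
#' @export
psd_rr <- function(z, resample_rate = 4) {
  if (inherits(z, "rr_series")) z <- z$z
  n <- length(z)
  if (n < 8) stop("need at least 8 R-R intervals for a PSD")
  t_beat <- cumsum(z) / 1000  # s
  duration <- t_beat[n] - t_beat[1]
  low_conf <- n < 30 || duration < 60
  if (low_conf) {
    warning("short tachogram (< 30 intervals or < 60 s): ",
            "low-frequency estimates are low-confidence")
  }
  grid <- seq(t_beat[1], t_beat[n], by = 1 / resample_rate)
  xs <- spline(t_beat, z, xout = grid, method = "natural")$y
  pg <- periodogram(xs, resample_rate)
  structure(list(frequencies = pg$freq, power = pg$power,
                 resample_rate = resample_rate, df = pg$df,
                 low_confidence = low_conf),
            class = "psd_estimate")
}

#' LF/HF band powers of a tachogram PSD
#'
#' Integrates the PSD over the low-frequency band `[0.004, 0.15)` Hz and
#' the high-frequency band `[0.15, 0.4]` Hz and forms the HF/LF ratio.
#' The 0.004 Hz lower edge follows the source formulation; set
#' `lf_low = 0.04` for the conventional HRV band.
#'
#' @param psd a [psd_rr()] result.
#' @param lf_low lower edge of the LF band in Hz.
#' @return named numeric vector `lf`, `hf`, `hf_lf` (ratio; `NA` when
#'   LF power is zero).
#' @export
band_powers <- function(psd, lf_low = 0.004) {
  f <- psd$frequencies
  p <- psd$power
  lf <- sum(p[f >= lf_low & f < 0.15]) * psd$df
  hf <- sum(p[f >= 0.15 & f <= 0.4]) * psd$df
  c(lf = lf, hf = hf, hf_lf = if (lf > 0) hf / lf else NA_real_)
}

#' Distribution moments of the R-R series
#'
#' Mean (ms), skewness and non-excess kurtosis of the window's intervals.
#'
#' @param z an [rr_series()] or numeric vector (ms), length >= 3.
#' @return named numeric vector `rr_mean`, `rr_skew`, `rr_kurt`
#'   (skew/kurt `NA` for zero variance).
#' @export
moment_features <- function(z) {
  if (inherits(z, "rr_series")) z <- z$z
  if (length(z) < 3) stop("need at least 3 R-R intervals")
  c(rr_mean = mean(z), rr_skew = skewness(z), rr_kurt = kurtosis(z))
}

#' The ten traditional HRV features
#'
#' Convenience wrapper assembling the complete comparison feature group:
#' SDNN, SDSD, RMSSD, pNN50, LF power, HF power, HF/LF ratio, mean,
#' skewness and kurtosis of the R-R series.
#'
#' @param z an [rr_series()] or numeric vector (ms).
#' @param ... passed to [time_domain_features()] and [band_powers()].
#' @return named numeric vector of 10 features (prefix `hrv_`).
#' @export
hrv_features <- function(z, ...) {
  td <- time_domain_features(z)
  bp <- band_powers(psd_rr(z))
  mm <- moment_features(z)
  out <- c(td, bp, mm)
  names(out) <- paste0("hrv_", names(out))
  out
}

#' Names of the ten traditional HRV features
#'
#' The comparison feature group, addressable by name.
#'
#' @return character vector of 10 names.
#' @export
hrv_feature_names <- function() {
  paste0("hrv_", c("sdnn", "sdsd", "rmssd", "pnn50",
                   "lf", "hf", "hf_lf", "rr_mean", "rr_skew", "rr_kurt"))
}
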