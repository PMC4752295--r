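# Fiducial detection: adaptive-threshold R-peak detection on the
# wavelet-filtered signal, windowed-extremum P/Q/S/T delineation,
# missing-peak imputation from the previous beat's timing scaled by the
# R-R ratio, and amplitude normalization.

#' Detect R peaks with a slope-energy adaptive-threshold detector
#'
#' Operates on the low-frequency-filtered signal (see
#' [filter_lowfreq_wavelet()]). The squared first derivative is integrated
#' over a 120 ms moving window (QRS complexes have steep slopes, so the
#' transform strongly suppresses P/T waves and broadband noise); local
#' maxima of this slope energy above an adaptive threshold (exponentially
#' tracked running peak estimate) are accepted under a 200 ms refractory
#' rule, keeping the larger of two competing candidates, and each accepted
#' event is refined to the extremum of the dominant-polarity signal within
#' +/- 60 ms.
#'
#' @param samples filtered ECG amplitudes.
#' @param fs sampling rate, Hz.
#' @param refractory refractory period in seconds (default 0.2).
#' @param threshold_frac acceptance threshold as a fraction of the running
#'   slope-energy peak estimate (default 0.25).
#' @return strictly increasing R times in seconds (possibly empty, with a
#'   warning, for degenerate input).
#' @export
detect_r_peaks <- function(samples, fs, refractory = 0.2, threshold_frac = 0.25) {
  n <- length(samples)
  if (n < 10 || diff(range(samples)) == 0) {
    warning("degenerate input: no peaks found")
    return(numeric(0))
  }
  # dominant polarity from extreme quantiles
  hi <- quantile(samples, 0.999, names = FALSE)
  lo <- quantile(samples, 0.001, names = FALSE)
  s <- if (abs(lo) > abs(hi)) -samples else samples
  # band-limit before differentiating (broadband noise would otherwise
  # dominate the derivative): ~24 ms moving average
  wsm <- max(3L, as.integer(0.024 * fs))
  ssm <- as.numeric(stats::filter(s, rep(1 / wsm, wsm), sides = 2))
  ssm[is.na(ssm)] <- 0
  # slope energy: squared derivative, integrated over ~120 ms
  d <- c(0, diff(ssm))
  w <- max(3L, as.integer(0.12 * fs))
  if (w %% 2 == 0) w <- w + 1L
  e <- as.numeric(stats::filter(d^2, rep(1 / w, w), sides = 2))
  e[is.na(e)] <- 0
  # initial peak estimate: median of block maxima over ~2 s blocks
  block <- max(2L, as.integer(2 * fs))
  nb <- max(1L, n %/% block)
  bmax <- vapply(seq_len(nb), function(b) {
    max(e[((b - 1) * block + 1):min(n, b * block)])
  }, numeric(1))
  peak_est <- median(bmax)
  if (!is.finite(peak_est) || peak_est <= 0) {
    warning("degenerate input: no positive slope energy")
    return(numeric(0))
  }
  cand <- which(e[2:(n - 1)] > e[1:(n - 2)] & e[2:(n - 1)] >= e[3:n]) + 1L
  refr <- refractory * fs
  half <- as.integer(0.06 * fs)
  acc_idx <- integer(0)   # refined R sample indices
  acc_amp <- numeric(0)   # slope energy of the accepted event
  last <- -Inf
  thr <- threshold_frac * peak_est
  for (i in cand) {
    a <- e[i]
    if (a < thr) next
    seg <- max(1L, i - half):min(n, i + half)
    ridx <- seg[which.max(s[seg])]
    if (ridx - last <= refr) {
      if (length(acc_amp) && a > acc_amp[length(acc_amp)]) {
        acc_idx[length(acc_idx)] <- ridx
        acc_amp[length(acc_amp)] <- a
        last <- ridx
        peak_est <- 0.875 * peak_est + 0.125 * a
        thr <- threshold_frac * peak_est
      }
      next
    }
    acc_idx <- c(acc_idx, ridx)
    acc_amp <- c(acc_amp, a)
    last <- ridx
    peak_est <- 0.875 * peak_est + 0.125 * a
    thr <- threshold_frac * peak_est
  }
  if (length(acc_idx) == 0) {
    warning("no peaks found")
    return(numeric(0))
  }
  (sort(unique(acc_idx)) - 1) / fs
}

WAVES <- c("p", "q", "r", "s", "t")

empty_fiducials <- function(n) {
  fid <- data.frame(beat = seq_len(n))
  for (w in WAVES) {
    fid[[paste0("t_", w)]] <- NA_real_
    fid[[paste0("a_", w)]] <- NA_real_
  }
  for (w in WAVES) fid[[paste0("imputed_", w)]] <- FALSE
  fid
}

#' Delineate P, Q, S and T peaks around detected R peaks
#'
#' Local-extremum search in physiologic windows relative to each R peak:
#' Q = minimum in (R - 80 ms, R); S = minimum in (R, R + 120 ms);
#' T = maximum in (R + 80 ms, R + 0.6 RR); P = maximum in
#' (R - 0.35 RR, R - 100 ms). Q and S are searched as minima (negative
#' polarity waves), P and T as maxima. A wave whose search window is
#' truncated by the record edge, or whose extremum lacks prominence above
#' the local noise floor, is marked missing (to be filled by
#' [augment_missing_peaks()]).
#'
#' @param samples ECG amplitudes (filtered).
#' @param fs sampling rate, Hz.
#' @param r_times R-peak times in seconds (length >= 2).
#' @param prominence minimal extremum prominence, as a fraction of the
#'   mean absolute R amplitude (default 0.04).
#' @return `fiducial_set` data frame: per beat times `t_p..t_t`,
#'   amplitudes `a_p..a_t`, and `imputed_*` flags (all `FALSE` here).
#' @export
delineate_pqst <- function(samples, fs, r_times, prominence = 0.04) {
  n_beats <- length(r_times)
  if (n_beats < 2) stop("need at least 2 R peaks")
  n <- length(samples)
  fid <- empty_fiducials(n_beats)
  r_idx <- round(r_times * fs) + 1L
  r_amp <- samples[pmin(pmax(r_idx, 1L), n)]
  prom <- prominence * mean(abs(r_amp))
  rr_prev <- c(NA, diff(r_times))
  rr_next <- c(diff(r_times), NA)
  rr_prev[1] <- rr_next[1]
  rr_next[n_beats] <- rr_prev[n_beats]
  win <- function(t0, t1) {
    i0 <- floor(t0 * fs) + 1L
    i1 <- ceiling(t1 * fs) + 1L
    if (i0 < 1L || i1 > n || i1 <= i0) return(NULL)
    i0:i1
  }
  for (b in seq_len(n_beats)) {
    tr <- r_times[b]
    fid$t_r[b] <- tr
    fid$a_r[b] <- r_amp[b]
    specs <- list(
      q = list(idx = win(tr - 0.080, tr - 1 / fs), type = "min"),
      s = list(idx = win(tr + 1 / fs, tr + 0.120), type = "min"),
      t = list(idx = win(tr + 0.080, tr + 0.6 * rr_next[b]), type = "max"),
      p = list(idx = win(tr - 0.35 * rr_prev[b], tr - 0.100), type = "max")
    )
    for (w in names(specs)) {
      sp <- specs[[w]]
      if (is.null(sp$idx)) next
      seg <- samples[sp$idx]
      if (sp$type == "max") {
        j <- which.max(seg)
        ok <- seg[j] - median(seg) > prom
      } else {
        j <- which.min(seg)
        ok <- median(seg) - seg[j] > prom
      }
      if (ok) {
        fid[[paste0("t_", w)]][b] <- (sp$idx[j] - 1) / fs
        fid[[paste0("a_", w)]][b] <- seg[j]
      }
    }
  }
  class(fid) <- c("fiducial_set", "data.frame")
  fid
}

#' Impute missing P/Q/S/T peaks from neighboring beats
#'
#' A missing wave in beat `i` receives the previous beat's R-relative
#' offset scaled by the ratio of the current and previous R-R intervals:
#' `offset(W, i) = offset(W, i-1) * RR(i) / RR(i-1)`; the amplitude is
#' copied from the previous beat. Leading missing values are filled from
#' the next beat with the reciprocal scaling. Non-missing fiducials are
#' never altered.
#'
#' @param fiducials a `fiducial_set`.
#' @return `fiducial_set` with no missing waves and `imputed_*` flags set.
#' @export
augment_missing_peaks <- function(fiducials) {
  fid <- fiducials
  n <- nrow(fid)
  rr <- c(NA, diff(fid$t_r))
  rr[1] <- rr[2]
  for (w in setdiff(WAVES, "r")) {
    tcol <- paste0("t_", w); acol <- paste0("a_", w); icol <- paste0("imputed_", w)
    if (all(is.na(fid[[tcol]]))) {
      stop("wave '", w, "' missing in all beats; cannot augment")
    }
    off <- fid[[tcol]] - fid$t_r
    # forward pass
    for (b in 2:n) {
      if (is.na(off[b]) && !is.na(off[b - 1])) {
        off[b] <- off[b - 1] * rr[b] / rr[b - 1]
        fid[[acol]][b] <- fid[[acol]][b - 1]
        fid[[icol]][b] <- TRUE
      }
    }
    # leading gap: fill backwards from the first complete beat
    for (b in (n - 1):1) {
      if (is.na(off[b]) && !is.na(off[b + 1])) {
        off[b] <- off[b + 1] * rr[b] / rr[b + 1]
        fid[[acol]][b] <- fid[[acol]][b + 1]
        fid[[icol]][b] <- TRUE
      }
    }
    fid[[tcol]] <- fid$t_r + off
  }
  fid
}

#' Normalize window amplitude by median and mean R amplitude
#'
#' Subtracts the median of the window samples and divides by the mean of
#' the median-subtracted R amplitudes, so the output median is 0 and the
#' mean normalized R amplitude is 1. All fiducial amplitudes are re-read
#' from the normalized signal. Invariant to positive affine transforms of
#' the input.
#'
#' @param samples window amplitudes.
#' @param fiducials a `fiducial_set` with times on the same clock as
#'   `samples` starting at `t = 0` (use `offset` otherwise).
#' @param fs sampling rate, Hz.
#' @param offset time (s) of `samples[1]` on the fiducials' clock.
#' @return list `samples` (normalized), `fiducials` (amplitudes re-read).
#' @export
normalize_amplitude <- function(samples, fiducials, fs, offset = 0) {
  med <- median(samples)
  idx_r <- round((fiducials$t_r - offset) * fs) + 1L
  idx_r <- pmin(pmax(idx_r, 1L), length(samples))
  mean_r <- mean(samples[idx_r] - med)
  if (!is.finite(mean_r) || mean_r == 0) stop("zero mean R amplitude")
  out <- (samples - med) / mean_r
  fid <- fiducials
  for (w in WAVES) {
    tcol <- paste0("t_", w); acol <- paste0("a_", w)
    idx <- round((fid[[tcol]] - offset) * fs) + 1L
    idx <- pmin(pmax(idx, 1L), length(out))
    fid[[acol]] <- out[idx]
  }
  list(samples = out, fiducials = fid)
}
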