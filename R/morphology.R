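# Peak-based morphology features: interval-ratio features, amplitude
# difference/ratio/interaction features, spectral summaries of the HRV
# tachogram, and ECG-derived respiration features.

INTERVAL_PAIRS <- c("pq", "pr", "ps", "pt", "qr", "qs", "qt", "rs", "rt", "st")
B2B_INTERVALS <- c("pp", "qq", "rr", "ss", "tt")
ALL_INTERVALS <- c(INTERVAL_PAIRS, B2B_INTERVALS)

# Per-beat interval matrix over beats 2..n (where all 15 intervals are
# defined): 10 intra-beat pairwise intervals plus 5 beat-to-beat same-wave
# intervals, in seconds.
interval_matrix <- function(fiducials) {
  n <- nrow(fiducials)
  stopifnot(n >= 2)
  beats <- 2:n
  m <- matrix(NA_real_, length(beats), length(ALL_INTERVALS),
              dimnames = list(NULL, ALL_INTERVALS))
  tcol <- function(w) fiducials[[paste0("t_", w)]]
  for (pair in INTERVAL_PAIRS) {
    w1 <- substr(pair, 1, 1); w2 <- substr(pair, 2, 2)
    m[, pair] <- (tcol(w2) - tcol(w1))[beats]
  }
  for (bb in B2B_INTERVALS) {
    w <- substr(bb, 1, 1)
    m[, bb] <- tcol(w)[beats] - tcol(w)[beats - 1]
  }
  m
}

#' Interval-ratio features
#'
#' For every ordered pair (A, B) of distinct intervals among the 10
#' intra-beat intervals (PQ, PR, ..., ST) and the 5 beat-to-beat same-wave
#' intervals (PP, QQ, RR, SS, TT), the feature `t_A.B` is the mean over
#' beats of the per-beat ratio A(i)/B(i) (beats 2..n, where every interval
#' is defined). All 210 features are dimensionless, hence independent of
#' heart rate and of global time rescaling. Beats with a zero denominator
#' are skipped with a warning; a feature with no usable beats errors.
#'
#' @param fiducials an augmented `fiducial_set` (no missing waves).
#' @return named numeric vector of 210 features (`t_<a>.<b>`).
#' @export
interval_ratio_features <- function(fiducials) {
  m <- interval_matrix(fiducials)
  out <- numeric(0)
  warned <- FALSE
  for (a in ALL_INTERVALS) for (b in ALL_INTERVALS) {
    if (a == b) next
    num <- m[, a]; den <- m[, b]
    use <- is.finite(num) & is.finite(den) & den != 0
    if (!all(use) && !warned) {
      warning("beats with zero-length denominator skipped")
      warned <- TRUE
    }
    if (!any(use)) stop("no usable beats for interval ratio ", a, "/", b)
    val <- mean(num[use] / den[use])
    out[sprintf("t_%s.%s", a, b)] <- val
  }
  out
}

amplitude_base <- function(fiducials) {
  n <- nrow(fiducials)
  beats <- 2:n
  acol <- function(w) fiducials[[paste0("a_", w)]]
  base <- matrix(NA_real_, length(beats), length(ALL_INTERVALS),
                 dimnames = list(NULL, ALL_INTERVALS))
  for (pair in INTERVAL_PAIRS) {
    w1 <- substr(pair, 1, 1); w2 <- substr(pair, 2, 2)
    base[, pair] <- (acol(w2) - acol(w1))[beats]
  }
  for (bb in B2B_INTERVALS) {
    w <- substr(bb, 1, 1)
    base[, bb] <- acol(w)[beats] - acol(w)[beats - 1]
  }
  base
}

#' Amplitude difference, ratio and interaction features
#'
#' Base features: for each intra-beat wave pair (X, Y) in P-Q-R-S-T order
#' the per-beat difference `a_y(i) - a_x(i)`, and for each wave W the
#' beat-to-beat difference `a_w(i) - a_w(i-1)` (15 base series over beats
#' 2..n). The feature `a_<xy>` is the mean of its base series. For every
#' ordered pair of base series, the ratio feature `a_<A>.<B>` is the mean
#' of per-beat ratios (beats with zero denominator skipped; all skipped
#' yields `NA`); for every unordered pair, the interaction feature
#' `a_<A>x<B>` is the mean of per-beat products. 330 features in total.
#'
#' @param fiducials an augmented `fiducial_set` with normalized amplitudes.
#' @return named numeric vector (15 + 210 + 105 features).
#' @export
amplitude_features <- function(fiducials) {
  base <- amplitude_base(fiducials)
  out <- numeric(0)
  for (nm in ALL_INTERVALS) out[paste0("a_", nm)] <- mean(base[, nm])
  for (a in ALL_INTERVALS) for (b in ALL_INTERVALS) {
    if (a == b) next
    num <- base[, a]; den <- base[, b]
    use <- is.finite(num) & is.finite(den) & den != 0
    out[sprintf("a_%s.%s", a, b)] <-
      if (any(use)) mean(num[use] / den[use]) else NA_real_
  }
  k <- length(ALL_INTERVALS)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- ALL_INTERVALS[i]; b <- ALL_INTERVALS[j]
    out[sprintf("a_%sx%s", a, b)] <- mean(base[, a] * base[, b])
  }
  out
}

#' Spectral summary features of the HRV tachogram
#'
#' Dominant frequency and its power, median frequency (50% cumulative
#' power) and edge frequency (95% cumulative power) of the R-R
#' periodogram.
#'
#' @param z an [rr_series()] or numeric vector (ms), length >= 30.
#' @param psd optional precomputed [psd_rr()] result.
#' @return named numeric vector `hrvx_dom_f`, `hrvx_dom_amp`,
#'   `hrvx_median_f`, `hrvx_edge_f`.
#' @export
hrv_spectral_extra <- function(z, psd = NULL) {
  if (is.null(psd)) psd <- psd_rr(z)
  s <- psd_summary(psd$frequencies, psd$power)
  setNames(as.numeric(s), paste0("hrvx_", names(s)))
}

#' ECG-derived respiration (EDR) waveform
#'
#' The beat-wise R amplitude series sampled at the R times, linearly
#' detrended and cubic-spline resampled to a uniform rate. Respiratory
#' modulation of the R amplitude makes this a surrogate respiration
#' signal.
#'
#' @param fiducials a `fiducial_set` (>= 10 beats).
#' @param rate output sampling rate, Hz (default 4).
#' @return numeric vector with attributes `rate` and `t0`.
#' @export
derive_respiration <- function(fiducials, rate = 4) {
  n <- nrow(fiducials)
  if (n < 10) stop("need at least 10 beats for EDR")
  tr <- fiducials$t_r
  ar <- fiducials$a_r
  fit <- lm.fit(cbind(1, tr), ar)
  detr <- fit$residuals
  grid <- seq(tr[1], tr[n], by = 1 / rate)
  edr <- spline(tr, detr, xout = grid, method = "natural")$y
  attr(edr, "rate") <- rate
  attr(edr, "t0") <- tr[1]
  edr
}

#' Respiratory features from the EDR signal
#'
#' Spread (standard deviation), dominant frequency and its power, median
#' and 95% edge frequency, computed on the EDR signal and on its first
#' difference (prefixes `resp_` and `dresp_`). For a constant EDR the
#' spectral features are `NA` and the spread 0.
#'
#' @param edr a [derive_respiration()] result (>= 30 s recommended).
#' @return named numeric vector of 10 features.
#' @export
respiratory_features <- function(edr) {
  rate <- attr(edr, "rate")
  if (is.null(rate)) rate <- 4
  feats <- function(x, prefix) {
    spread <- sd(x)
    if (!is.finite(spread) || spread == 0) {
      s <- c(dom_f = NA_real_, dom_amp = NA_real_,
             median_f = NA_real_, edge_f = NA_real_)
    } else {
      pg <- periodogram(x, rate)
      # ignore the DC bin: respiration lives strictly above 0 Hz
      s <- psd_summary(pg$freq[-1], pg$power[-1])
    }
    setNames(c(spread, as.numeric(s)),
             paste0(prefix, c("spread", "dom_f", "dom_amp", "median_f", "edge_f")))
  }
  c(feats(as.numeric(edr), "resp_"), feats(diff(as.numeric(edr)), "dresp_"))
}

#' All peak-based morphology features of a window
#'
#' Assembles [interval_ratio_features()], [amplitude_features()],
#' [hrv_spectral_extra()] and [respiratory_features()] (554 features).
#'
#' @param fiducials augmented, normalized `fiducial_set`.
#' @return named numeric vector.
#' @export
morphology_features <- function(fiducials) {
  z <- rr_series(r_times = fiducials$t_r)
  c(
    interval_ratio_features(fiducials),
    amplitude_features(fiducials),
    hrv_spectral_extra(z),
    respiratory_features(derive_respiration(fiducials))
  )
}

morphology_feature_names <- function() {
  ord <- unlist(lapply(ALL_INTERVALS, function(a) {
    sprintf("t_%s.%s", a, setdiff(ALL_INTERVALS, a))
  }))
  amp_base <- paste0("a_", ALL_INTERVALS)
  amp_ratio <- unlist(lapply(ALL_INTERVALS, function(a) {
    sprintf("a_%s.%s", a, setdiff(ALL_INTERVALS, a))
  }))
  k <- length(ALL_INTERVALS)
  amp_int <- unlist(lapply(seq_len(k - 1), function(i) {
    sprintf("a_%sx%s", ALL_INTERVALS[i], ALL_INTERVALS[(i + 1):k])
  }))
  c(ord, amp_base, amp_ratio, amp_int,
    paste0("hrvx_", c("dom_f", "dom_amp", "median_f", "edge_f")),
    unlist(lapply(c("resp_", "dresp_"), function(p) {
      paste0(p, c("spread", "dom_f", "dom_amp", "median_f", "edge_f"))
    })))
}
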