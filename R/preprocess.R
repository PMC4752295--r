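# Preprocessing: tumbling beat-count windowing, per-window polynomial
# baseline removal, Savitzky-Golay smoothing.

#' Segment a record into tumbling beat-count windows
#'
#' Consecutive non-overlapping windows each containing exactly
#' `beats_per_window` R peaks; the trailing partial window is discarded.
#' Sample boundaries between adjacent windows are placed at the midpoint
#' between the last beat of one window and the first beat of the next, so
#' windows partition the used samples. Each window is tagged with the
#' stage containing its midpoint sample.
#'
#' @param record an `ecg_record` (fields `samples`, `fs`,
#'   `stage_boundaries`, `subject_id`).
#' @param r_times R-peak times (s) detected on the full record.
#' @param beats_per_window beats per window (default 120).
#' @return list of `beat_window` objects: `samples`, `fs`, `beat_count`,
#'   `r_times` (s, record clock), `start_index`, `subject_id`,
#'   `window_index`, `stage`.
#' @export
segment_windows <- function(record, r_times, beats_per_window = 120L) {
  stopifnot(beats_per_window >= 2)
  n_beats <- length(r_times)
  if (n_beats < beats_per_window) {
    stop("fewer beats (", n_beats, ") than beats_per_window")
  }
  n_win <- n_beats %/% beats_per_window
  fs <- record$fs
  n_samp <- length(record$samples)
  stage_starts <- record$stage_boundaries
  bounds <- integer(n_win + 1)
  bounds[1] <- 1L
  for (k in seq_len(n_win)) {
    last_beat <- r_times[k * beats_per_window]
    if (k < n_win) {
      nxt <- r_times[k * beats_per_window + 1]
      bounds[k + 1] <- min(n_samp, floor(fs * (last_beat + nxt) / 2) + 1L)
    } else {
      # last retained window extends half a median RR past its final beat
      half_rr <- median(diff(r_times)) / 2
      bounds[k + 1] <- min(n_samp, ceiling(fs * (last_beat + half_rr)) + 1L)
    }
  }
  lapply(seq_len(n_win), function(k) {
    i0 <- bounds[k]; i1 <- bounds[k + 1]
    mid <- (i0 + i1) %/% 2
    stage <- findInterval(mid, stage_starts) - 1L
    idx <- ((k - 1) * beats_per_window + 1):(k * beats_per_window)
    structure(list(
      samples = record$samples[i0:i1],
      fs = fs,
      beat_count = beats_per_window,
      r_times = r_times[idx],
      start_index = i0,
      subject_id = record$subject_id,
      window_index = k,
      stage = stage
    ), class = "beat_window")
  })
}

#' Remove baseline drift with a least-squares polynomial fit
#'
#' Fits a degree-`degree` polynomial (orthogonal basis, ordinary least
#' squares) to the window and subtracts it. The residual is orthogonal to
#' the polynomial basis, so the operation is idempotent. On an
#' ill-conditioned fit the degree is lowered with a warning.
#'
#' @param window a `beat_window`, or a bare numeric vector.
#' @param degree polynomial degree (default 6).
#' @return same type as input, with `samples` detrended.
#' @export
remove_baseline_poly <- function(window, degree = 6L) {
  x <- if (inherits(window, "beat_window")) window$samples else window
  n <- length(x)
  if (n <= degree + 1) stop("window shorter than degree + 1 samples")
  tt <- seq(-1, 1, length.out = n)
  deg <- degree
  fit <- NULL
  while (deg >= 1) {
    basis <- stats::poly(tt, degree = deg, raw = FALSE)
    fit <- tryCatch(lm.fit(cbind(1, basis), x), error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit$coefficients))) break
    warning("ill-conditioned polynomial fit; lowering degree to ", deg - 1)
    deg <- deg - 1
  }
  res <- fit$residuals
  if (inherits(window, "beat_window")) {
    window$samples <- res
    window
  } else {
    res
  }
}

#' Savitzky-Golay smoothing
#'
#' Moving local-polynomial least-squares smoother (unweighted, default
#' second-degree polynomial over a 15-sample frame, i.e. 30 ms at 500 Hz).
#' Interior points use the central projection coefficients; edge points
#' are re-fit on truncated frames so the output length equals the input
#' length and polynomials up to `poly_order` are reproduced exactly.
#'
#' @param samples numeric vector.
#' @param frame_len odd frame length, `> poly_order`.
#' @param poly_order local polynomial order (default 2).
#' @return smoothed vector of the same length.
#' @export
smooth_savitzky_golay <- function(samples, frame_len = 15L, poly_order = 2L) {
  frame_len <- as.integer(frame_len)
  if (frame_len %% 2 == 0) stop("frame_len must be odd")
  if (frame_len <= poly_order) stop("frame_len must exceed poly_order")
  n <- length(samples)
  if (n <= frame_len) frame_len <- max(poly_order + 1 + (poly_order %% 2), 2L * (n %/% 2) - 1L)
  half <- frame_len %/% 2
  # central coefficients: first row of the least-squares projector at the
  # frame center
  A <- outer(-half:half, 0:poly_order, `^`)
  proj <- A %*% solve(crossprod(A), t(A))
  w <- proj[half + 1, ]
  out <- as.numeric(stats::filter(samples, rev(w), sides = 2))
  # edges: polynomial fit on truncated frames
  for (i in seq_len(half)) {
    idx <- 1:min(n, i + half)
    B <- outer(idx - i, 0:poly_order, `^`)
    cf <- qr.solve(B, samples[idx])
    out[i] <- cf[1]
    j <- n - i + 1
    idx <- max(1, j - half):n
    B <- outer(idx - j, 0:poly_order, `^`)
    cf <- qr.solve(B, samples[idx])
    out[j] <- cf[1]
  }
  out
}
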