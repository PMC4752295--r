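# Periodized orthonormal discrete wavelet transform, implemented directly
# (no wavelet dependency): circular correlation/convolution via the FFT.
# With an orthonormal filter pair the analysis map is an orthogonal matrix,
# so synthesis-by-transpose gives perfect reconstruction and exact energy
# conservation.

# db4 analysis lowpass (8 taps, standard Daubechies extremal-phase values)
DB4_LOWPASS <- c(
  0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
  -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
  0.03288301166698295, -0.01059740178499728
)

# Quadrature-mirror highpass of an even-length orthonormal lowpass filter.
qmf_highpass <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L))
}

# Periodize a filter to length n (fold taps modulo n); identity when the
# filter already fits.
periodize_filter <- function(h, n) {
  if (length(h) <= n) return(c(h, rep(0, n - length(h))))
  idx <- ((seq_along(h) - 1) %% n) + 1
  as.numeric(tapply(h, idx, sum))[seq_len(n)]
}

# Circular correlation followed by dyadic downsampling (analysis branch).
# y[j] = sum_m h[m] x[2(j-1) + m] with periodic wrap-around.
circ_corr_down <- function(x, h) {
  n <- length(x)
  hp <- periodize_filter(h, n)
  y <- Re(fft(fft(x) * Conj(fft(hp)), inverse = TRUE)) / n
  y[seq(1, n, by = 2)]
}

# Transpose of circ_corr_down: upsample (odd slots) then circular convolution.
circ_up_conv <- function(a, h, n) {
  u <- numeric(n)
  u[seq(1, n, by = 2)] <- a
  hp <- periodize_filter(h, n)
  Re(fft(fft(u) * fft(hp), inverse = TRUE)) / n
}

# Multi-level periodized analysis. Input length must be a multiple of
# 2^levels. Returns detail coefficient vectors (finest first) and the
# final approximation.
dwt_periodic <- function(x, h, levels) {
  stopifnot(length(x) %% 2^levels == 0)
  g <- qmf_highpass(h)
  details <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    details[[lev]] <- circ_corr_down(a, g)
    a <- circ_corr_down(a, h)
  }
  list(details = details, approx = a)
}

# Inverse of dwt_periodic (exact for orthonormal h).
idwt_periodic <- function(decomp, h) {
  g <- qmf_highpass(h)
  a <- decomp$approx
  for (lev in rev(seq_along(decomp$details))) {
    n <- 2 * length(a)
    a <- circ_up_conv(a, h, n) + circ_up_conv(decomp$details[[lev]], g, n)
  }
  a
}

# Reflection-pad x at the end to length n (n - length(x) < length(x) assumed
# per chunk; applied repeatedly for heavy padding).
pad_reflect <- function(x, n) {
  while (length(x) < n) {
    need <- n - length(x)
    take <- min(need, length(x))
    x <- c(x, rev(x)[seq_len(take)])
  }
  x
}

#' Remove very-low-frequency content with a level-10 db4 wavelet filter
#'
#' Decomposes the signal with a 10-level Daubechies-4 discrete wavelet
#' transform, zeroes the level-10 approximation and level-10 detail
#' coefficients, and reconstructs. At 500 Hz this suppresses content below
#' roughly `fs / 2^11` (about 0.24 Hz) -- baseline wander and slow drift --
#' while leaving QRS timing and sharpness intact.
#'
#' @param samples numeric vector of ECG amplitudes.
#' @param fs sampling rate in Hz (recorded for documentation; the filter is
#'   defined in samples).
#' @param levels decomposition depth (default 10).
#' @return filtered signal, same length as `samples`.
#' @export
filter_lowfreq_wavelet <- function(samples, fs, levels = 10L) {
  if (any(!is.finite(samples))) stop("non-finite samples")
  n <- length(samples)
  block <- 2^levels
  n_pad <- ceiling(max(n, block) / block) * block
  x <- pad_reflect(samples, n_pad)
  dec <- dwt_periodic(x, DB4_LOWPASS, levels)
  dec$approx[] <- 0
  dec$details[[levels]][] <- 0
  y <- idwt_periodic(dec, DB4_LOWPASS)
  y[seq_len(n)]
}
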