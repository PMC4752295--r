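# Shared numeric helpers: moments, spectral summaries, AUC, intervals.

#' Sample skewness (third standardized moment)
#'
#' Uses the population (method-of-moments) estimator
#' \eqn{m_3 / m_2^{3/2}}. Returns `NA` for constant input.
#'
#' @param x numeric vector.
#' @return numeric scalar.
#' @export
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}

#' Sample kurtosis (fourth standardized moment, non-excess)
#'
#' The non-excess convention is used throughout the package: a normal
#' distribution has kurtosis 3, a uniform distribution 1.8.
#'
#' @param x numeric vector.
#' @return numeric scalar; `NA` for constant input.
#' @export
kurtosis <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(NA_real_)
  mean((x - m)^4) / s2^2
}

# One-sided periodogram of a uniformly sampled, mean-removed signal.
# Normalized so that sum(power) * df = var(x) (population variance),
# i.e. Parseval holds on the one-sided grid.
periodogram <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  X <- fft(x)
  df <- fs / n
  two_sided <- (Mod(X)^2) / (n^2 * df)
  half <- floor(n / 2)
  freq <- (0:half) * df
  pow <- two_sided[1:(half + 1)]
  # fold negative frequencies; DC and (for even n) Nyquist are unpaired
  if (n %% 2 == 0) {
    if (half >= 2) pow[2:half] <- 2 * pow[2:half]
  } else {
    if (half >= 1) pow[2:(half + 1)] <- 2 * pow[2:(half + 1)]
  }
  list(freq = freq, power = pow, df = df)
}

# Summary statistics of a one-sided PSD: dominant frequency and its power,
# median (50% cumulative power) and edge (95% cumulative power) frequency.
psd_summary <- function(freq, power, edge_quantile = 0.95) {
  ok <- is.finite(power) & power >= 0
  freq <- freq[ok]; power <- power[ok]
  tot <- sum(power)
  if (!is.finite(tot) || tot <= 0) {
    stop("all-zero power spectrum: spectral summary undefined")
  }
  cum <- cumsum(power) / tot
  i_dom <- which.max(power)
  c(
    dom_f = freq[i_dom],
    dom_amp = power[i_dom],
    median_f = freq[which(cum >= 0.5)[1]],
    edge_f = freq[which(cum >= edge_quantile)[1]]
  )
}

# Rank-based AUC of scores for a binary 0/1 label (positive = 1).
# Equivalent to the Mann-Whitney U statistic scaled to [0, 1].
auc_score <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  n1 <- length(pos); n0 <- length(neg)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Student-t 95% confidence half-width of a mean over fold metrics.
t_ci_halfwidth <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  qt(1 - (1 - level) / 2, df = n - 1) * sd(x) / sqrt(n)
}

# Mean absolute first difference; the "variability index" used by the
# taut-string and DTCWT feature families.
mean_abs_diff <- function(x) {
  if (length(x) < 2L) return(0)
  mean(abs(diff(x)))
}

# Deterministic child seed derivation (kept below 2^31).
child_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483629
}
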