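# Taut-string decomposition of the R-R series. Given the tube
# [z - eps, z + eps], the taut string x is the unique minimizer of
# sum (x_{i+1} - x_i)^2 subject to |x_i - z_i| <= eps (it simultaneously
# minimizes every convex symmetric function of the increments, including
# the l1 norm of the discrete second derivative). Computed by the greedy
# segment-fixing algorithm: repeatedly extend the longest feasible straight
# segment from the current anchor; when the slope window closes, bend at
# the barrier contact that defined the binding slope. Amortized linear
# time in practice (each pass fixes at least one knot).

#' R-R interval series
#'
#' Constructs the successive-difference series `z` (in ms) from R-peak
#' times, or validates a supplied interval vector.
#'
#' @param r_times R-peak times in seconds (length >= 3), or `NULL` when
#'   `z` is supplied directly.
#' @param z optional R-R intervals in milliseconds.
#' @return object of class `rr_series` with fields `z` (ms) and `r0`
#'   (time origin, s).
#' @export
rr_series <- function(r_times = NULL, z = NULL) {
  if (is.null(z)) {
    stopifnot(length(r_times) >= 3, !is.unsorted(r_times, strictly = TRUE))
    z <- diff(r_times) * 1000
    r0 <- r_times[1]
  } else {
    r0 <- 0
  }
  if (any(z <= 0)) stop("all R-R intervals must be positive")
  if (length(z) < 2) stop("need at least 2 R-R intervals")
  structure(list(z = as.numeric(z), r0 = r0), class = "rr_series")
}

# Greedy taut string through the corridor lo..hi with free (unpinned)
# endpoints. Returns x.
taut_string_tube <- function(lo, hi) {
  n <- length(lo)
  tol <- 1e-12 * max(1, max(abs(lo)), max(abs(hi)))
  x <- numeric(n)

  # Flat-start detection: running feasible window for a constant prefix.
  Lbar <- cummax(lo)
  Ubar <- cummin(hi)
  closed <- which(Lbar > Ubar + tol)
  if (length(closed) == 0L) {
    # a single flat line fits the whole tube; take the final window midpoint
    x[] <- (Lbar[n] + Ubar[n]) / 2
    return(x)
  }
  cc <- closed[1]
  if (hi[cc] < Lbar[cc - 1] - tol) {
    # corridor closes from above: string must descend; initial flat hugs the
    # highest lower-barrier point of the feasible prefix
    h1 <- Lbar[cc - 1]
    a <- max(which(lo[seq_len(cc - 1)] >= h1 - tol))
  } else {
    # closes from below: string must ascend; flat hugs the lowest upper point
    h1 <- Ubar[cc - 1]
    a <- max(which(hi[seq_len(cc - 1)] <= h1 + tol))
  }
  x[seq_len(a)] <- h1
  va <- h1

  # Greedy segment fixing from point anchor (a, va).
  while (a < n) {
    idx <- (a + 1):n
    d <- idx - a
    su <- (hi[idx] - va) / d
    sl <- (lo[idx] - va) / d
    smax <- cummin(su)
    smin <- cummax(sl)
    infeas <- which(smin > smax + tol)
    if (length(infeas) == 0L) {
      m <- n - a
      s <- min(max(0, smin[m]), smax[m])
      if (s == 0) {
        x[idx] <- va
        a <- n
      } else if (s > 0) {
        # rising tail: bend at the last lower contact that defines smin
        j <- max(which(sl[seq_len(m)] >= s - tol))
        x[(a + 1):(a + j)] <- va + s * seq_len(j)
        a <- a + j
        va <- x[a]
      } else {
        j <- max(which(su[seq_len(m)] <= s + tol))
        x[(a + 1):(a + j)] <- va + s * seq_len(j)
        a <- a + j
        va <- x[a]
      }
    } else {
      jstar <- infeas[1]
      if (smax[jstar] < smin[jstar - 1] - tol) {
        # upper barrier kills the window: descend at the minimum slope,
        # bending (concave knot) at its last lower-barrier contact
        s <- smin[jstar - 1]
        j <- max(which(sl[seq_len(jstar - 1)] >= s - tol))
        va_new <- lo[a + j]
      } else {
        # lower barrier kills: ascend at the maximum slope, bending
        # (convex knot) at its last upper-barrier contact
        s <- smax[jstar - 1]
        j <- max(which(su[seq_len(jstar - 1)] <= s + tol))
        va_new <- hi[a + j]
      }
      if (j > 1) x[(a + 1):(a + j - 1)] <- va + s * seq_len(j - 1)
      x[a + j] <- va_new
      a <- a + j
      va <- va_new
    }
  }
  pmin(pmax(x, lo), hi)
}

#' Taut-string decomposition of an R-R series
#'
#' Splits `z` into a smooth estimate `x` (the taut string through the
#' `eps`-tube) and a small-amplitude residual `y = z - x` with
#' \eqn{\|y\|_\infty \le \epsilon}. The estimate minimizes the squared
#' roughness \eqn{\sum_i (x_{i+1}-x_i)^2} over the tube.
#'
#' @param z an [rr_series()] or numeric vector of R-R intervals (ms).
#' @param epsilon tube half-width in ms, `>= 0`.
#' @return object of class `taut_string_result`: `epsilon`, `x`, `y`.
#' @export
taut_string <- function(z, epsilon) {
  if (inherits(z, "rr_series")) z <- z$z
  z <- as.numeric(z)
  if (!is.finite(epsilon) || epsilon < 0) stop("epsilon must be >= 0")
  if (epsilon == 0) {
    x <- z
  } else {
    x <- taut_string_tube(z - epsilon, z + epsilon)
  }
  structure(list(epsilon = epsilon, x = x, y = z - x),
            class = "taut_string_result")
}

# Count of inflection points of the piecewise-linear estimate: sign changes
# of the second difference, with zero runs collapsed (counted once).
inflection_count <- function(x) {
  if (length(x) < 3L) return(0L)
  d2 <- diff(x, differences = 2)
  tol <- 1e-9 * max(1, max(abs(x)))
  s <- sign(d2)
  s[abs(d2) <= tol] <- 0
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1] != s[-length(s)])
}

#' Taut-string feature family over an epsilon sweep
#'
#' For each tube width in `eps_grid` the decomposition `z = x + y` is
#' computed and eight features are extracted: mean, standard deviation,
#' skewness and kurtosis of the estimate `x`; standard deviation and
#' kurtosis of the residual `y`; the inflection-point count of `x`; and the
#' variability index `v(eps)` = mean absolute first difference of `y`.
#' With the default 8-point grid this yields 64 features. The feature
#' `ts_eps32_v` (i.e. `v(32 ms)`) is the "taut string 32" variability
#' index: it captures R-R variability of amplitude at or below 32 ms and
#' shrinks as hemodynamic reserve is exhausted.
#'
#' @param z an [rr_series()] or numeric vector (ms).
#' @param eps_grid increasing vector of tube half-widths in ms.
#' @return named numeric vector, `8 * length(eps_grid)` features.
#' @export
ts_feature_set <- function(z, eps_grid = c(4, 8, 16, 32, 64, 128, 256, 512)) {
  if (inherits(z, "rr_series")) z <- z$z
  stopifnot(length(eps_grid) >= 1, !is.unsorted(eps_grid))
  out <- numeric(0)
  for (eps in eps_grid) {
    ts <- taut_string(z, eps)
    x <- ts$x; y <- ts$y
    const_x <- diff(range(x)) <= 1e-12 * max(1, max(abs(x)))
    const_y <- diff(range(y)) <= 1e-12 * max(1, max(abs(y)), 1e-12)
    f <- c(
      x_mean = mean(x),
      x_sd = sd(x),
      x_skew = if (const_x) NA_real_ else skewness(x),
      x_kurt = if (const_x) NA_real_ else kurtosis(x),
      y_sd = sd(y),
      y_kurt = if (const_y) NA_real_ else kurtosis(y),
      inflect = as.numeric(inflection_count(x)),
      v = mean_abs_diff(y)
    )
    names(f) <- sprintf("ts_eps%g_%s", eps,
                        c("x_mean", "x_sd", "x_skew", "x_kurt",
                          "y_sd", "y_kurt", "inflect", "v"))
    out <- c(out, f)
  }
  out
}

ts_feature_names <- function(eps_grid = c(4, 8, 16, 32, 64, 128, 256, 512)) {
  unlist(lapply(eps_grid, function(eps) {
    sprintf("ts_eps%g_%s", eps, c("x_mean", "x_sd", "x_skew", "x_kurt",
                                  "y_sd", "y_kurt", "inflect", "v"))
  }))
}
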