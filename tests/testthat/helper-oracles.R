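# Independent oracles and fixture builders shared across tests. Each
# oracle is a deliberately naive re-statement of the defining formula
# (explicit loops, no shared code with the implementation under test).

# --- fixtures -----------------------------------------------------------

# Random but physiologically ordered fiducial set: P < Q < R < S < T per
# beat, strictly increasing R times.
random_fiducials <- function(n_beats = 20, seed = 1) {
  set.seed(seed)
  rr <- 0.8 + cumsum(rep(0, n_beats)) + runif(n_beats, -0.1, 0.1)
  t_r <- cumsum(rr)
  fid <- data.frame(beat = seq_len(n_beats))
  off <- list(p = -0.16, q = -0.03, r = 0, s = 0.03, t = 0.25)
  amp <- list(p = 0.12, q = -0.1, r = 1, s = -0.22, t = 0.3)
  for (w in names(off)) {
    jit_t <- if (w == "r") 0 else runif(n_beats, -0.005, 0.005)
    fid[[paste0("t_", w)]] <- t_r + off[[w]] + jit_t
    fid[[paste0("a_", w)]] <- amp[[w]] + runif(n_beats, -0.05, 0.05)
  }
  for (w in names(off)) fid[[paste0("imputed_", w)]] <- FALSE
  class(fid) <- c("fiducial_set", "data.frame")
  fid
}

# Synthetic feature table with subject/window structure.
synthetic_table <- function(n_subjects = 20, windows_per_subject = 12,
                            n_features = 10, seed = 1,
                            separation = 0, feature_names = NULL) {
  set.seed(seed)
  n <- n_subjects * windows_per_subject
  sid <- rep(sprintf("s%02d", seq_len(n_subjects)), each = windows_per_subject)
  label <- rep(rep(c("normal", "abnormal"), each = windows_per_subject / 2),
               n_subjects)
  X <- matrix(rnorm(n * n_features), n, n_features)
  X[label == "abnormal", ] <- X[label == "abnormal", ] + separation
  if (is.null(feature_names)) feature_names <- sprintf("f%03d", seq_len(n_features))
  colnames(X) <- feature_names
  tab <- data.frame(subject_id = sid,
                    window_index = rep(seq_len(windows_per_subject), n_subjects),
                    stage = rep(0L, n), severity = as.numeric(label == "abnormal") * 0.6,
                    severity_cont = as.numeric(label == "abnormal") * 0.75,
                    label = label, check.names = FALSE)
  cbind(tab, as.data.frame(X, check.names = FALSE))
}

# --- taut string oracle (box-constrained QP via L-BFGS-B) ---------------

qp_taut_oracle <- function(z, eps) {
  n <- length(z)
  obj <- function(x) sum(diff(x)^2)
  grad <- function(x) {
    g <- numeric(n)
    d <- diff(x)
    g[1] <- -2 * d[1]
    g[n] <- 2 * d[n - 1]
    if (n > 2) g[2:(n - 1)] <- 2 * d[1:(n - 2)] - 2 * d[2:(n - 1)]
    g
  }
  optim(z, obj, grad, method = "L-BFGS-B",
        lower = z - eps, upper = z + eps,
        control = list(maxit = 20000, factr = 1e1, pgtol = 1e-14))
}

# l1 norm of the discrete second derivative D*D(x) as printed.
dstar_d_l1 <- function(x) {
  n <- length(x)
  w <- diff(x)
  abs(-w[1]) + sum(abs(w[-(n - 1)] - w[-1])) + abs(w[n - 1])
}

# --- brute-force formula oracles ----------------------------------------

# Mean of per-beat interval ratios for named wave pairs; `a` and `b` are
# two-letter interval codes (distinct letters = intra-beat, doubled =
# beat-to-beat). Beats 2..n.
oracle_interval_ratio <- function(fid, a, b) {
  n <- nrow(fid)
  val <- function(code, i) {
    w1 <- substr(code, 1, 1); w2 <- substr(code, 2, 2)
    if (w1 == w2) {
      fid[[paste0("t_", w1)]][i] - fid[[paste0("t_", w1)]][i - 1]
    } else {
      fid[[paste0("t_", w2)]][i] - fid[[paste0("t_", w1)]][i]
    }
  }
  acc <- c()
  for (i in 2:n) acc <- c(acc, val(a, i) / val(b, i))
  mean(acc)
}

oracle_amp_diff <- function(fid, code) {
  n <- nrow(fid)
  w1 <- substr(code, 1, 1); w2 <- substr(code, 2, 2)
  acc <- c()
  for (i in 2:n) {
    acc <- c(acc, if (w1 == w2) {
      fid[[paste0("a_", w1)]][i] - fid[[paste0("a_", w1)]][i - 1]
    } else {
      fid[[paste0("a_", w2)]][i] - fid[[paste0("a_", w1)]][i]
    })
  }
  acc
}

oracle_hrv_time <- function(z) {
  n <- length(z)
  zbar <- sum(z) / n
  sdnn <- sqrt(sum((z - zbar)^2) / (n - 1))
  u <- z[-1] - z[-n]
  mu <- sum(abs(u)) / (n - 1)
  sdsd <- sqrt(sum((abs(u) - mu)^2) / (n - 1))
  rmssd <- sqrt(sum(u^2) / (n - 1))
  nn50 <- 0
  for (i in seq_len(n - 1)) if (abs(u[i]) > 50) nn50 <- nn50 + 1
  c(sdnn = sdnn, sdsd = sdsd, rmssd = rmssd, pnn50 = 100 * nn50 / (n - 1))
}

# --- detection scoring ---------------------------------------------------

f1_against_truth <- function(detected, truth, tol = 0.02) {
  if (length(detected) == 0) return(0)
  tp <- sum(vapply(truth, function(t) any(abs(detected - t) <= tol), logical(1)))
  prec <- sum(vapply(detected, function(t) any(abs(truth - t) <= tol),
                     logical(1))) / length(detected)
  recall <- tp / length(truth)
  if (prec + recall == 0) return(0)
  2 * prec * recall / (prec + recall)
}
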