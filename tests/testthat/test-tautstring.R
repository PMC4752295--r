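test_that("taut string handles the closed-form cases", {
  z <- c(812, 795, 830, 801, 790)
  ts0 <- taut_string(z, 0)
  expect_identical(ts0$x, z)
  expect_identical(ts0$y, rep(0, 5))

  expect_equal(taut_string(rep(777, 10), 25)$x, rep(777, 10))

  # linear ramp with total rise 2*eps: flat string at the tube midline
  ramp <- seq(800, 820, length.out = 15)
  ts <- taut_string(ramp, 10)
  expect_equal(ts$x, rep(810, 15), tolerance = 1e-9)
  expect_equal(sum(diff(ts$x)^2), 0)

  # forced alternation: residual carries the full swing, v = 80 ms
  alt <- 800 + c(40, -40, 40, -40, 40)
  feats <- ts_feature_set(alt, eps_grid = 40)
  expect_equal(unname(feats["ts_eps40_v"]), 80)

  expect_error(taut_string(z, -1), "epsilon")
})

test_that("taut string matches the QP oracle on z = [0,4,0,4,0]", {
  o <- qp_taut_oracle(c(0, 4, 0, 4, 0), 1)
  ts <- taut_string(c(0, 4, 0, 4, 0), 1)
  expect_lt(abs(sum(diff(ts$x)^2) - o$value), 1e-6)
  expect_equal(ts$x, c(1, 3, 1, 3, 1), tolerance = 1e-9)
})

test_that("taut string is optimal and tube feasible on random instances", {
  set.seed(10)
  for (k in 1:60) {
    n <- sample(3:50, 1)
    z <- 800 + cumsum(rnorm(n, 0, 30)) + rnorm(n, 0, 40)
    eps <- runif(1, 1, 80)
    ts <- taut_string(z, eps)
    expect_lte(max(abs(ts$y)), eps + 1e-9)
    o <- qp_taut_oracle(z, eps)
    expect_lte(sum(diff(ts$x)^2), o$value + 1e-6 * max(1, o$value))
  }
})

test_that("total variation and the variability index are monotone in epsilon", {
  set.seed(11)
  for (k in 1:20) {
    z <- 800 + cumsum(rnorm(40, 0, 20)) + rnorm(40, 0, 30)
    tv <- v <- numeric(0)
    for (eps in c(4, 8, 16, 32, 64, 128)) {
      ts <- taut_string(z, eps)
      tv <- c(tv, sum(abs(diff(ts$x))))
      v <- c(v, mean(abs(diff(ts$y))))
    }
    expect_true(all(diff(tv) <= 1e-9))
    expect_true(all(diff(v) >= -1e-9))
  }
})

test_that("the estimate also minimizes the l1 second-derivative objective", {
  # independent LP oracle through the system python (scipy.optimize.linprog)
  py <- Sys.which("python")
  skip_if(py == "", "python not available")
  script <- '
import json, sys
import numpy as np
from scipy.optimize import linprog
inst = json.load(open(sys.argv[1]))
out = []
for z, eps in inst:
    z = np.array(z, dtype=float); n = len(z)
    eps = float(np.ravel(eps)[0])
    # variables: x (n), t (n); minimize sum t s.t. -t <= DstarD x <= t, box
    A = np.zeros((n, n))
    A[0, 0], A[0, 1] = 1, -1
    for i in range(1, n - 1):
        A[i, i - 1], A[i, i], A[i, i + 1] = -1, 2, -1
    A[n - 1, n - 2], A[n - 1, n - 1] = -1, 1
    Aub = np.block([[A, -np.eye(n)], [-A, -np.eye(n)]])
    bub = np.zeros(2 * n)
    c = np.concatenate([np.zeros(n), np.ones(n)])
    bounds = [(zi - eps, zi + eps) for zi in z] + [(0.0, np.inf)] * n
    r = linprog(c, A_ub=Aub, b_ub=bub, bounds=bounds, method="highs")
    out.append(r.fun)
json.dump(out, open(sys.argv[2], "w"))
'
  set.seed(12)
  inst <- lapply(1:10, function(k) {
    n <- sample(5:20, 1)
    list(as.numeric(800 + cumsum(rnorm(n, 0, 25)) + rnorm(n, 0, 30)),
         runif(1, 5, 60))
  })
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  fscript <- tempfile(fileext = ".py")
  jsonlite::write_json(inst, fin, digits = NA)
  writeLines(script, fscript)
  status <- system2(py, c(fscript, fin, fout), stdout = FALSE, stderr = FALSE)
  skip_if(status != 0, "scipy LP oracle unavailable")
  lp_opt <- jsonlite::read_json(fout, simplifyVector = TRUE)
  for (k in seq_along(inst)) {
    ts <- taut_string(inst[[k]][[1]], inst[[k]][[2]])
    expect_lte(dstar_d_l1(ts$x), lp_opt[k] + 1e-6 * max(1, lp_opt[k]))
  }
})

test_that("the taut-string feature family has the frozen 8x8 layout", {
  set.seed(13)
  z <- 800 + cumsum(rnorm(200, 0, 15)) + rnorm(200, 0, 20)
  f <- ts_feature_set(z)
  expect_length(f, 64)
  expect_identical(names(f), hemowatch:::ts_feature_names())
  expect_true("ts_eps32_v" %in% names(f))

  # constant series: zero residuals, zero inflections at every epsilon
  fc <- ts_feature_set(rep(800, 50))
  expect_true(all(fc[grepl("_v$", names(fc))] == 0))
  expect_true(all(fc[grepl("_inflect$", names(fc))] == 0))
  expect_true(all(is.na(fc[grepl("_skew$|_kurt$", names(fc))])))
})

test_that("the variability index falls with simulated severity", {
  v32 <- matrix(NA_real_, 40, 4)
  p <- subject_params(severity_slope = 0.3)
  for (s in 1:40) {
    for (st in 0:3) {
      rr <- simulate_rr(p, 120, st, seed = s * 31 + st)
      v32[s, st + 1] <- ts_feature_set(rr, eps_grid = 32)["ts_eps32_v"]
    }
  }
  expect_true(all(diff(apply(v32, 2, median)) < 0))
})
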