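test_that("interval ratios match constant-case and brute-force oracles", {
  # all beats identical: QT = 400 ms, RR = 1000 ms
  fid <- random_fiducials(10, seed = 1)
  fid$t_r <- seq(1, by = 1, length.out = 10)
  fid$t_q <- fid$t_r - 0.05
  fid$t_t <- fid$t_q + 0.4
  fid$t_p <- fid$t_r - 0.2
  fid$t_s <- fid$t_r + 0.04
  f <- interval_ratio_features(fid)
  expect_equal(unname(f["t_qt.rr"]), 0.4, tolerance = 1e-12)
  # AM-GM: mean(A/B) * mean(B/A) >= 1, equality for constant ratios
  expect_equal(unname(f["t_qt.rr"] * f["t_rr.qt"]), 1, tolerance = 1e-12)

  # randomized fiducials against the naive loop oracle
  for (seed in 1:10) {
    fidr <- random_fiducials(25, seed = seed)
    fr <- interval_ratio_features(fidr)
    for (pair in list(c("qt", "rr"), c("pq", "st"), c("pp", "tt"),
                      c("rs", "qq"), c("st", "tt"))) {
      expect_equal(unname(fr[sprintf("t_%s.%s", pair[1], pair[2])]),
                   oracle_interval_ratio(fidr, pair[1], pair[2]),
                   tolerance = 1e-12)
    }
    expect_true(all(is.finite(fr)))
  }
  expect_length(interval_ratio_features(random_fiducials(12)), 210)
})

test_that("interval ratios are invariant to time shift and rescaling", {
  fid <- random_fiducials(20, seed = 5)
  f0 <- interval_ratio_features(fid)
  shifted <- fid
  for (w in c("p", "q", "r", "s", "t")) {
    shifted[[paste0("t_", w)]] <- shifted[[paste0("t_", w)]] + 17.3
  }
  expect_equal(interval_ratio_features(shifted), f0, tolerance = 1e-12)
  scaled <- fid
  for (w in c("p", "q", "r", "s", "t")) {
    scaled[[paste0("t_", w)]] <- scaled[[paste0("t_", w)]] * 1.7
  }
  expect_equal(interval_ratio_features(scaled), f0, tolerance = 1e-12)
})

test_that("amplitude features match Eqs 2-5 style oracles", {
  fid <- random_fiducials(12, seed = 6)
  fid$a_t <- rep(1.2, 12)
  fid$a_q <- rep(-0.2, 12)
  fid$a_r <- rep(1, 12)
  f <- amplitude_features(fid)
  expect_equal(unname(f["a_qt"]), 1.4, tolerance = 1e-12)
  expect_equal(unname(f["a_rr"]), 0, tolerance = 1e-12)
  expect_equal(unname(f["a_qtxrr"]), 0, tolerance = 1e-12)

  for (seed in 1:10) {
    fidr <- random_fiducials(25, seed = 100 + seed)
    fr <- amplitude_features(fidr)
    qt <- oracle_amp_diff(fidr, "qt"); rr <- oracle_amp_diff(fidr, "rr")
    pt <- oracle_amp_diff(fidr, "pt"); qq <- oracle_amp_diff(fidr, "qq")
    expect_equal(unname(fr["a_qt"]), mean(qt), tolerance = 1e-12)
    expect_equal(unname(fr["a_rr"]), mean(rr), tolerance = 1e-12)
    use <- rr != 0
    expect_equal(unname(fr["a_qt.rr"]), mean(qt[use] / rr[use]), tolerance = 1e-12)
    expect_equal(unname(fr["a_qtxrr"]), mean(qt * rr), tolerance = 1e-12)
    expect_equal(unname(fr["a_ptxqq"]), mean(pt * qq), tolerance = 1e-12)
  }
  expect_length(amplitude_features(fid), 15 + 210 + 105)
})

test_that("spectral summaries follow the cumulative-power definitions", {
  # single line: dominant = median = edge
  tt <- seq(0.8, 320, by = 0.8)
  z <- 800 + 40 * sin(2 * pi * 0.25 * tt)
  s <- hrv_spectral_extra(z)
  psd <- psd_rr(z)
  expect_lt(abs(s["hrvx_dom_f"] - 0.25), 2 * psd$df)
  expect_lt(abs(s["hrvx_median_f"] - 0.25), 2 * psd$df)
  expect_lt(abs(s["hrvx_edge_f"] - 0.25), 2 * psd$df)

  # flat PSD on [0, 0.5]: edge 0.475, median 0.25 (+- 1 bin)
  freq <- seq(0, 0.5, by = 0.005)
  flat <- hemowatch:::psd_summary(freq, rep(1, length(freq)))
  expect_lt(abs(flat["median_f"] - 0.25), 0.006)
  expect_lt(abs(flat["edge_f"] - 0.475), 0.006)

  # two equal lines at 0.1 and 0.3: median between, edge at the upper line
  pow <- numeric(length(freq)); pow[freq == 0.1] <- 1; pow[freq == 0.3] <- 1
  two <- hemowatch:::psd_summary(freq, pow)
  expect_true(two["median_f"] >= 0.1 && two["median_f"] <= 0.3)
  expect_equal(unname(two["edge_f"]), 0.3)
  expect_error(hemowatch:::psd_summary(freq, rep(0, length(freq))), "all-zero")
})

test_that("EDR recovers the respiratory modulation", {
  p <- subject_params(n_stages = 2, resp_freq = 0.25, r_mod_depth = 0.06)
  rec <- simulate_ecg(p, seed = 30, stage_durations = c(60, 60, 60),
                      snr_db = Inf, wander_amp = 0)
  filt <- filter_lowfreq_wavelet(rec$samples, rec$fs)
  r <- detect_r_peaks(filt, rec$fs)
  fid <- augment_missing_peaks(delineate_pqst(filt, rec$fs, r))
  norm <- normalize_amplitude(filt, fid, rec$fs)
  edr <- derive_respiration(norm$fiducials)
  pg <- hemowatch:::periodogram(as.numeric(edr), attr(edr, "rate"))
  expect_lt(abs(pg$freq[-1][which.max(pg$power[-1])] - 0.25), 2 * pg$df)

  # constant R amplitudes: EDR ~ 0 after detrend
  fidc <- random_fiducials(40, seed = 9)
  fidc$a_r <- 1
  expect_lt(max(abs(derive_respiration(fidc))), 1e-9)
  expect_error(derive_respiration(fidc[1:5, ]), "at least 10")
})

test_that("respiratory features scale as expected", {
  rate <- 4
  tt <- seq(0, 120, by = 1 / rate)
  a <- 0.05
  edr <- a * sin(2 * pi * 0.25 * tt)
  attr(edr, "rate") <- rate
  f <- respiratory_features(edr)
  expect_lt(abs(f["resp_spread"] - a / sqrt(2)) / (a / sqrt(2)), 0.05)
  expect_lt(abs(f["resp_dom_f"] - 0.25), 0.02)
  expect_lt(abs(f["dresp_dom_f"] - 0.25), 0.02)

  # doubled modulation depth: spectral peak power x4 within 15%
  f2 <- respiratory_features(structure(2 * as.numeric(edr), rate = rate))
  expect_lt(abs(f2[["resp_dom_amp"]] / f[["resp_dom_amp"]] - 4), 0.15 * 4)

  # white noise: edge >= median >= dominant-bin lower bound
  set.seed(31)
  for (k in 1:20) {
    e <- structure(rnorm(480), rate = rate)
    fn <- respiratory_features(e)
    expect_gte(fn[["resp_edge_f"]], fn[["resp_median_f"]])
  }

  # constant EDR: spread 0, spectral features missing
  fc <- respiratory_features(structure(rep(0.3, 200), rate = rate))
  expect_equal(unname(fc["resp_spread"]), 0)
  expect_true(is.na(fc["resp_dom_f"]))
})
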