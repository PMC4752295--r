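test_that("R detector is exact on clean synthetic ECG and robust to noise", {
  expect_warning(out <- detect_r_peaks(numeric(5000), 500), "degenerate")
  expect_length(out, 0)

  p <- subject_params(n_stages = 2)
  rec <- simulate_ecg(p, seed = 21, stage_durations = c(40, 40, 40),
                      snr_db = Inf, wander_amp = 0)
  r <- detect_r_peaks(filter_lowfreq_wavelet(rec$samples, rec$fs), rec$fs)
  expect_equal(f1_against_truth(r, rec$truth$t_r), 1.0)
  expect_true(all(diff(r) > 0.2))

  # inverted-polarity record
  rneg <- detect_r_peaks(filter_lowfreq_wavelet(-rec$samples, rec$fs), rec$fs)
  expect_equal(f1_against_truth(rneg, rec$truth$t_r), 1.0)
})

test_that("delineation hits truth within 10 ms and flags absent waves", {
  p <- subject_params(n_stages = 2)
  rec <- simulate_ecg(p, seed = 22, stage_durations = c(40, 40, 40),
                      snr_db = Inf, wander_amp = 0)
  filt <- filter_lowfreq_wavelet(rec$samples, rec$fs)
  r <- detect_r_peaks(filt, rec$fs)
  fid <- delineate_pqst(filt, rec$fs, r)
  for (w in c("p", "q", "s", "t")) {
    err <- abs(fid[[paste0("t_", w)]] - rec$truth[[paste0("t_", w)]])
    expect_lt(median(err, na.rm = TRUE), 0.010)
  }

  # zeroed P bump is reported missing
  morph0 <- hemowatch:::DEFAULT_MORPHOLOGY
  morph0$amp[morph0$wave == "p"] <- 0
  rec0 <- simulate_ecg(subject_params(n_stages = 2, morphology = morph0),
                       seed = 23, stage_durations = c(30, 30, 30),
                       snr_db = Inf, wander_amp = 0)
  filt0 <- filter_lowfreq_wavelet(rec0$samples, rec0$fs)
  fid0 <- delineate_pqst(filt0, rec0$fs, detect_r_peaks(filt0, rec0$fs))
  expect_gt(mean(is.na(fid0$t_p)), 0.9)

  # identical beats, constant RR: identical per-beat offsets within 1 sample
  offs <- fid$t_t - fid$t_r
  expect_lt(diff(range(offs, na.rm = TRUE)), 0.010)
})

test_that("missing-peak imputation follows the RR-ratio rule", {
  fid <- random_fiducials(6, seed = 3)
  # force known RR structure: t_r = 1, 2, 3.1 -> RR ratio 1.1
  fid <- fid[1:3, ]
  fid$t_r <- c(1, 2, 3.1)
  fid$t_t <- c(1.3, 2.3, NA)  # previous T offset +300 ms
  fid$a_t <- c(0.3, 0.31, NA)
  out <- augment_missing_peaks(fid)
  expect_equal(out$t_t[3] - out$t_r[3], 0.3 * 1.1, tolerance = 1e-12)
  expect_equal(out$a_t[3], 0.31)
  expect_true(out$imputed_t[3])
  expect_false(any(out$imputed_t[1:2]))

  # identity when nothing is missing
  full <- random_fiducials(8, seed = 4)
  expect_equal(augment_missing_peaks(full), full, tolerance = 1e-12)

  # all-missing wave errors
  gone <- full
  gone$t_p <- NA_real_
  expect_error(augment_missing_peaks(gone), "missing in all beats")
})

test_that("imputed times track truth when every 3rd T is removed", {
  p <- subject_params(n_stages = 2)
  rec <- simulate_ecg(p, seed = 24, stage_durations = c(40, 40, 40),
                      snr_db = Inf, wander_amp = 0)
  filt <- filter_lowfreq_wavelet(rec$samples, rec$fs)
  r <- detect_r_peaks(filt, rec$fs)
  fid <- delineate_pqst(filt, rec$fs, r)
  drop <- seq(3, nrow(fid), by = 3)
  fid$t_t[drop] <- NA_real_
  fid$a_t[drop] <- NA_real_
  out <- augment_missing_peaks(fid)
  err <- abs(out$t_t[drop] - rec$truth$t_t[drop])
  expect_lt(max(err), 0.025)
  # non-missing fiducials untouched
  keep <- setdiff(seq_len(nrow(fid)), drop)
  expect_identical(out$t_t[keep], fid$t_t[keep])
})

test_that("amplitude normalization is exact, idempotent and affine invariant", {
  p <- subject_params(n_stages = 2)
  rec <- simulate_ecg(p, seed = 25, stage_durations = c(30, 30, 30),
                      snr_db = Inf, wander_amp = 0.1)
  filt <- filter_lowfreq_wavelet(rec$samples, rec$fs)
  r <- detect_r_peaks(filt, rec$fs)
  fid <- augment_missing_peaks(delineate_pqst(filt, rec$fs, r))
  n1 <- normalize_amplitude(filt, fid, rec$fs)
  expect_lt(abs(median(n1$samples)), 1e-9)
  expect_equal(mean(n1$fiducials$a_r), 1, tolerance = 1e-9)

  # idempotence
  n2 <- normalize_amplitude(n1$samples, n1$fiducials, rec$fs)
  expect_equal(n2$samples, n1$samples, tolerance = 1e-9)

  # positive affine transform leaves the result unchanged
  n3 <- normalize_amplitude(2.5 * filt + 0.7, fid, rec$fs)
  expect_equal(n3$samples, n1$samples, tolerance = 1e-9)
  expect_equal(n3$fiducials$a_t, n1$fiducials$a_t, tolerance = 1e-9)

  expect_error(normalize_amplitude(numeric(100), fid[1:2, ], rec$fs), "zero mean R")
})
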