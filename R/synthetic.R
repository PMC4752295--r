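# Synthetic LBNP-like cohort generator. Stands in for the restricted human
# dataset: multi-subject single-lead ECG with known beat times and wave
# fiducials, R-R variability carrying low-frequency (~0.1 Hz Mayer wave)
# and high-frequency (respiratory sinus arrhythmia) oscillations plus
# broadband jitter, baseline wander, measurement noise, and a monotone
# severity effect across ordered stress stages: HRV amplitudes shrink
# multiplicatively and the T-wave amplitude drifts down additively, so
# that compensated and decompensating windows are learnably separable.

DEFAULT_MORPHOLOGY <- data.frame(
  wave = c("p", "q", "r", "s", "t"),
  amp = c(0.12, -0.10, 1.00, -0.22, 0.30),
  offset = c(-0.165, -0.030, 0.000, 0.030, 0.250),  # s, relative to R
  width = c(0.028, 0.010, 0.013, 0.012, 0.055),     # s, Gaussian sigma
  stringsAsFactors = FALSE
)

#' Subject-level simulation parameters
#'
#' @param subject_id character token.
#' @param baseline_hr baseline heart rate, beats/min, in `[40, 180]`.
#' @param hf_amp respiratory sinus arrhythmia depth, ms.
#' @param lf_amp Mayer-wave depth, ms.
#' @param resp_freq respiratory frequency, Hz, in `(0.1, 0.5)`.
#' @param jitter_sd broadband R-R jitter standard deviation, ms.
#' @param morphology data frame with columns `wave`, `amp`, `offset`,
#'   `width` (normalized units / seconds) describing the five Gaussian
#'   bumps of the beat template.
#' @param n_stages number of stress stages after baseline, `>= 2`.
#' @param severity_slope per-stage multiplicative shrink factor on HRV
#'   amplitudes and on the R-amplitude respiratory modulation, in `[0, 1)`.
#' @param t_amp_shift additive per-stage decrease of the T-wave amplitude
#'   (normalized units).
#' @param r_mod_depth relative respiratory modulation depth of the R
#'   amplitude at baseline.
#' @return object of class `subject_params`.
#' @export
subject_params <- function(subject_id = "s1",
                           baseline_hr = 65,
                           hf_amp = 40,
                           lf_amp = 25,
                           resp_freq = 0.25,
                           jitter_sd = 8,
                           morphology = DEFAULT_MORPHOLOGY,
                           n_stages = 5L,
                           severity_slope = 0.3,
                           t_amp_shift = 0.02,
                           r_mod_depth = 0.05) {
  stopifnot(baseline_hr >= 40, baseline_hr <= 180,
            resp_freq > 0.1, resp_freq < 0.5,
            n_stages >= 2,
            severity_slope >= 0, severity_slope < 1,
            hf_amp >= 0, lf_amp >= 0, jitter_sd >= 0)
  if (any(morphology$width <= 0)) stop("morphology widths must be positive")
  structure(list(subject_id = subject_id, baseline_hr = baseline_hr,
                 hf_amp = hf_amp, lf_amp = lf_amp, resp_freq = resp_freq,
                 jitter_sd = jitter_sd, morphology = morphology,
                 n_stages = as.integer(n_stages),
                 severity_slope = severity_slope,
                 t_amp_shift = t_amp_shift, r_mod_depth = r_mod_depth),
            class = "subject_params")
}

#' Simulate an R-R interval series for one stage
#'
#' Beat-to-beat intervals are the baseline mean (`60000 / baseline_hr` ms)
#' plus an HF oscillation at the respiratory frequency, an LF oscillation
#' at 0.1 Hz, and white jitter; all three amplitudes are attenuated by
#' `(1 - severity_slope)^stage_index`.
#'
#' @param params a [subject_params()].
#' @param duration stage duration in seconds.
#' @param stage_index 0-based stage (0 = baseline).
#' @param seed integer seed.
#' @return an [rr_series()] with attribute `beat_times` (s, cumulative,
#'   starting at the first interval's end).
#' @export
simulate_rr <- function(params, duration, stage_index = 0L, seed = 1L) {
  if (duration <= 0) stop("duration must be positive")
  m <- 60000 / params$baseline_hr
  if (duration * 1000 < 2 * m) stop("duration too short for 2 beats")
  atten <- (1 - params$severity_slope)^stage_index
  set.seed(as.integer(seed))
  phi_hf <- runif(1, 0, 2 * pi)
  phi_lf <- runif(1, 0, 2 * pi)
  n_max <- ceiling(duration * 1000 / m * 1.5) + 2
  jit <- rnorm(n_max, 0, params$jitter_sd * atten)
  t_cur <- 0
  z <- numeric(0)
  k <- 0
  while (TRUE) {
    k <- k + 1
    rr <- m +
      params$hf_amp * atten * sin(2 * pi * params$resp_freq * t_cur + phi_hf) +
      params$lf_amp * atten * sin(2 * pi * 0.1 * t_cur + phi_lf) +
      jit[min(k, n_max)]
    rr <- max(rr, 0.3 * m)  # physiologic floor
    if (t_cur + rr / 1000 > duration) break
    t_cur <- t_cur + rr / 1000
    z <- c(z, rr)
    if (k > n_max) break
  }
  if (length(z) < 2) stop("duration too short for 2 beats")
  out <- rr_series(z = z)
  attr(out, "beat_times") <- cumsum(z) / 1000
  out
}

# Continuous beat train across ordered stages: each beat's R-R interval is
# drawn from the HRV model of the stage its onset falls in, so there is no
# artificial gap at stage transitions.
beat_train <- function(params, stage_durations, seed) {
  total <- sum(stage_durations)
  starts <- cumsum(c(0, stage_durations))
  m <- 60000 / params$baseline_hr
  set.seed(as.integer(seed))
  phi_hf <- runif(1, 0, 2 * pi)
  phi_lf <- runif(1, 0, 2 * pi)
  n_max <- ceiling(total * 1000 / m * 1.5) + 2
  jit <- rnorm(n_max, 0, params$jitter_sd)
  t_cur <- 0
  beat_t <- numeric(0)
  beat_stage <- integer(0)
  k <- 0
  while (k < n_max) {
    k <- k + 1
    stage <- findInterval(t_cur, starts, rightmost.closed = FALSE) - 1L
    stage <- min(stage, length(stage_durations) - 1L)
    atten <- (1 - params$severity_slope)^stage
    rr <- m +
      params$hf_amp * atten * sin(2 * pi * params$resp_freq * t_cur + phi_hf) +
      params$lf_amp * atten * sin(2 * pi * 0.1 * t_cur + phi_lf) +
      jit[k] * atten
    rr <- max(rr, 0.3 * m)
    if (t_cur + rr / 1000 > total) break
    t_cur <- t_cur + rr / 1000
    beat_t <- c(beat_t, t_cur)
    beat_stage <- c(beat_stage,
                    min(findInterval(t_cur, starts) - 1L,
                        length(stage_durations) - 1L))
  }
  list(t = beat_t, stage = beat_stage)
}

# Gaussian bump accumulation for one beat template at time t_r.
add_beat <- function(samples, fs, t_r, morph, amps) {
  for (w in seq_len(nrow(morph))) {
    center <- t_r + morph$offset[w]
    sigma <- morph$width[w]
    i0 <- max(1L, floor((center - 4 * sigma) * fs) + 1L)
    i1 <- min(length(samples), ceiling((center + 4 * sigma) * fs) + 1L)
    if (i0 > i1) next
    tt <- (seq(i0, i1) - 1) / fs
    samples[i0:i1] <- samples[i0:i1] +
      amps[w] * exp(-(tt - center)^2 / (2 * sigma^2))
  }
  samples
}

#' Simulate a continuous multi-stage ECG record
#'
#' Places a five-Gaussian-bump beat template (P, Q, R, S, T) at beat times
#' drawn from [simulate_rr()] for each ordered stage, modulates the R
#' amplitude sinusoidally at the respiratory frequency (the substrate for
#' ECG-derived respiration), shifts the T amplitude down with stage
#' severity, and adds baseline wander (slow sinusoid plus low-order
#' polynomial drift) and white measurement noise at a configurable SNR.
#'
#' @param params a [subject_params()].
#' @param seed integer seed.
#' @param fs sampling rate, Hz.
#' @param stage_durations seconds per stage, length `n_stages + 1`
#'   (baseline first); default 300 s each.
#' @param snr_db signal-to-noise ratio in dB (`Inf` disables noise).
#' @param wander_amp baseline-wander amplitude in normalized units
#'   (0 disables).
#' @return object of class `ecg_record`: `samples`, `fs`,
#'   `stage_boundaries` (first sample index of each stage),
#'   `subject_id`, and `truth` (per-beat fiducial times/amplitudes,
#'   R times and stage of each beat).
#' @export
simulate_ecg <- function(params, seed = 1L, fs = 500,
                         stage_durations = NULL,
                         snr_db = 20, wander_amp = 0.08) {
  if (is.null(stage_durations)) {
    stage_durations <- rep(300, params$n_stages + 1)
  }
  stopifnot(length(stage_durations) == params$n_stages + 1)
  total_dur <- sum(stage_durations)
  n <- ceiling(total_dur * fs)
  samples <- numeric(n)
  stage_starts_t <- cumsum(c(0, stage_durations))[seq_along(stage_durations)]
  morph <- params$morphology
  i_r <- match("r", morph$wave)
  i_t <- match("t", morph$wave)

  train <- beat_train(params, stage_durations, seed)
  # drop beats whose template would be truncated at the record edges
  ok <- train$t > 0.30 & train$t < total_dur - 0.50
  beat_t <- train$t[ok]
  beat_stage <- train$stage[ok]

  n_beats <- length(beat_t)
  truth <- data.frame(beat = seq_len(n_beats), stage = beat_stage,
                      t_r = beat_t)
  amp_mat <- matrix(0, n_beats, nrow(morph))
  for (b in seq_len(n_beats)) {
    atten <- (1 - params$severity_slope)^beat_stage[b]
    amps <- morph$amp
    amps[i_r] <- amps[i_r] *
      (1 + params$r_mod_depth * atten * sin(2 * pi * params$resp_freq * beat_t[b]))
    amps[i_t] <- amps[i_t] - params$t_amp_shift * beat_stage[b]
    amp_mat[b, ] <- amps
    samples <- add_beat(samples, fs, beat_t[b], morph, amps)
  }
  for (w in seq_len(nrow(morph))) {
    truth[[paste0("t_", morph$wave[w])]] <- beat_t + morph$offset[w]
    truth[[paste0("a_", morph$wave[w])]] <- amp_mat[, w]
  }

  set.seed(as.integer(child_seed(seed, 9999)))
  if (wander_amp > 0) {
    tt <- (seq_len(n) - 1) / fs
    phi <- runif(1, 0, 2 * pi)
    drift <- runif(3, -1, 1)
    u <- tt / max(tt)
    samples <- samples + wander_amp * sin(2 * pi * 0.05 * tt + phi) +
      wander_amp * (drift[1] * u + drift[2] * u^2 + drift[3] * u^3)
  }
  if (is.finite(snr_db)) {
    p_sig <- mean(samples^2)
    noise_sd <- sqrt(p_sig) * 10^(-snr_db / 20)
    samples <- samples + rnorm(n, 0, noise_sd)
  }
  structure(list(
    samples = samples, fs = fs,
    stage_boundaries = floor(stage_starts_t * fs) + 1L,
    stage_durations = stage_durations,
    subject_id = params$subject_id,
    params = params,
    truth = truth
  ), class = "ecg_record")
}

#' Simulate a multi-subject LBNP-like cohort
#'
#' Subject parameters are drawn uniformly from the configured ranges; the
#' number of tolerated stress stages is drawn from the empirical tolerance
#' distribution of the LBNP protocol (most subjects reach 4-6 stages, few
#' reach 7-8), and the final stage is truncated uniformly between
#' `final_stage_range` seconds to emulate decompensation occurring
#' mid-stage. With `waveform = FALSE` only beat times and stage labels are
#' generated (fast path for beat-count bookkeeping at full cohort scale).
#'
#' @param n_subjects number of subjects, `>= 2`.
#' @param seed integer seed.
#' @param config list of ranges: `hr = c(lo, hi)` etc. (see defaults).
#' @param stage_duration full stage length in seconds (default 300).
#' @param final_stage_range truncation range of the final stage, seconds.
#' @param waveform generate full ECG waveforms (`TRUE`) or beat times only.
#' @param snr_db,wander_amp forwarded to [simulate_ecg()].
#' @return list of `ecg_record` (waveform mode) or list of per-subject
#'   lists with `beat_times`, `beat_stage`, `n_stages`, `subject_id`.
#' @export
simulate_cohort <- function(n_subjects, seed = 1L,
                            config = list(
                              hr = c(50, 80),
                              hf_amp = c(25, 55),
                              lf_amp = c(15, 35),
                              resp_freq = c(0.18, 0.32),
                              jitter_sd = c(5, 12),
                              severity_slope = c(0.2, 0.4)
                            ),
                            stage_duration = 300,
                            final_stage_range = c(150, 300),
                            waveform = TRUE,
                            snr_db = 20, wander_amp = 0.08) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  for (nm in names(config)) {
    rg <- config[[nm]]
    if (length(rg) != 2 || rg[2] < rg[1]) stop("degenerate range for ", nm)
  }
  # tolerance distribution: subjects reaching stress levels 4..8
  stage_levels <- 4:8
  stage_probs <- c(56, 55, 47, 16, 4) / 178
  set.seed(as.integer(seed))
  draws <- data.frame(
    hr = runif(n_subjects, config$hr[1], config$hr[2]),
    hf = runif(n_subjects, config$hf_amp[1], config$hf_amp[2]),
    lf = runif(n_subjects, config$lf_amp[1], config$lf_amp[2]),
    rf = runif(n_subjects, config$resp_freq[1], config$resp_freq[2]),
    jit = runif(n_subjects, config$jitter_sd[1], config$jitter_sd[2]),
    slope = runif(n_subjects, config$severity_slope[1], config$severity_slope[2]),
    n_stages = sample(stage_levels, n_subjects, replace = TRUE, prob = stage_probs),
    final_frac = runif(n_subjects, final_stage_range[1], final_stage_range[2])
  )
  lapply(seq_len(n_subjects), function(i) {
    p <- subject_params(
      subject_id = sprintf("s%03d", i),
      baseline_hr = draws$hr[i], hf_amp = draws$hf[i], lf_amp = draws$lf[i],
      resp_freq = draws$rf[i], jitter_sd = draws$jit[i],
      n_stages = draws$n_stages[i], severity_slope = draws$slope[i]
    )
    sd_i <- child_seed(seed, i)
    durs <- c(rep(stage_duration, p$n_stages), draws$final_frac[i])
    if (waveform) {
      simulate_ecg(p, seed = sd_i, stage_durations = durs,
                   snr_db = snr_db, wander_amp = wander_amp)
    } else {
      train <- beat_train(p, durs, sd_i)
      list(subject_id = p$subject_id, beat_times = train$t,
           beat_stage = train$stage, n_stages = p$n_stages, params = p)
    }
  })
}

#' Write an ECG record as CSV with a JSON truth sidecar
#'
#' Two-column CSV (`t_seconds`, `amplitude`) plus `<path>.json` holding the
#' ground-truth fiducials and stage boundaries.
#'
#' @param record an `ecg_record`.
#' @param path CSV output path.
#' @return invisibly, the sidecar path.
#' @export
write_ecg_csv <- function(record, path) {
  df <- data.frame(
    t_seconds = (seq_along(record$samples) - 1) / record$fs,
    amplitude = record$samples
  )
  write.csv(df, path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(
    subject_id = record$subject_id,
    fs = record$fs,
    stage_boundaries = record$stage_boundaries,
    truth = record$truth
  ), sidecar, digits = NA, auto_unbox = TRUE)
  invisible(sidecar)
}

#' Read an ECG record written by [write_ecg_csv()]
#'
#' @param path CSV path (expects `<path>.json` sidecar when present).
#' @return an `ecg_record` (truth present only if the sidecar exists).
#' @export
read_ecg_csv <- function(path) {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  fs <- round(1 / median(diff(df$t_seconds)))
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  structure(list(
    samples = df$amplitude,
    fs = if (!is.null(meta)) meta$fs else fs,
    stage_boundaries = if (!is.null(meta)) meta$stage_boundaries else 1L,
    subject_id = if (!is.null(meta)) meta$subject_id else basename(path),
    truth = if (!is.null(meta)) meta$truth else NULL
  ), class = "ecg_record")
}
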