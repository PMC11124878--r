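#' @name synth
#' @title Synthetic multi-session sEMG generator
#' @description
#' The generator emulates the statistical structure the identification
#' pipeline relies on, without claiming physiological fidelity: each
#' repetition is band-limited Gaussian noise (the standard surrogate for the
#' sEMG interference pattern) amplitude-modulated by a smooth
#' rest-contraction-rest envelope. Subject identity is carried by the
#' per-channel spectral signature (peak frequency and bandwidth of the
#' noise band); gesture identity is carried by the envelope shape (duty
#' factor and, for "dynamic" gestures, a slow modulation); sessions differ by
#' a multiplicative gain. Optional 60 Hz mains and sub-5 Hz baseline-wander
#' sinusoids exercise the preprocessing chain.
NULL

#' Generative parameters for one synthetic subject
#'
#' Usually produced by [make_subject_profiles()]; the constructor checks the
#' invariants (spectral band inside (0, fs/2), contraction gain > 1, positive
#' session multipliers).
#'
#' @param subject_id positive integer.
#' @param peak_freq length-2 numeric, per-channel spectral peak in Hz.
#' @param bandwidth length-2 numeric, per-channel half-bandwidth in Hz; the
#'   generated band is `peak_freq +/- bandwidth`.
#' @param contraction_gain length-2 numeric > 1, burst RMS relative to rest
#'   RMS per channel.
#' @param rise_time,fall_time envelope ramp durations in seconds.
#' @param rest_rms rest-level noise RMS (amplitude units).
#' @param session_gain positive numeric, one multiplier per session (near 1).
#' @param mains_amp amplitude of an additive 60 Hz sinusoid (default 0).
#' @param wander_amp,wander_freq amplitude and frequency (< 5 Hz) of an
#'   additive baseline-wander sinusoid (default amplitude 0).
#' @param fs sampling rate the band constraint is checked against.
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, peak_freq, bandwidth, contraction_gain,
                            rise_time = 0.15, fall_time = 0.15, rest_rms = 0.02,
                            session_gain = c(1, 1, 1), mains_amp = 0,
                            wander_amp = 0, wander_freq = 0.5, fs = 2000) {
  if (any(peak_freq - bandwidth <= 0) || any(peak_freq + bandwidth >= fs / 2))
    stop("peak_freq +/- bandwidth must stay inside (0, fs/2)")
  if (any(contraction_gain <= 1)) stop("contraction_gain must be > 1")
  if (any(session_gain <= 0)) stop("session_gain multipliers must be > 0")
  if (wander_freq >= 5) stop("wander_freq must be below 5 Hz")
  structure(list(subject_id = as.integer(subject_id),
                 peak_freq = peak_freq, bandwidth = bandwidth,
                 contraction_gain = contraction_gain,
                 rise_time = rise_time, fall_time = fall_time,
                 rest_rms = rest_rms, session_gain = session_gain,
                 mains_amp = mains_amp, wander_amp = wander_amp,
                 wander_freq = wander_freq),
            class = "subject_profile")
}

#' Generation settings for the synthetic dataset
#'
#' @param seed integer seed; all draws flow from it in a documented order
#'   (profiles first, then one independent substream per repetition).
#' @param rest_duration rest duration before and after the contraction, in
#'   seconds (default 0.5).
#' @param gesture_duration contraction duration in seconds (default 1; the
#'   reference protocol requires at least 1 s).
#' @param spec a [dataset_spec()] giving the factorial layout.
#' @param quantize_16bit if `TRUE`, amplitudes are rounded to a 16-bit grid
#'   spanning the dataset's dynamic range.
#' @return an object of class `generation_config`.
#' @export
generation_config <- function(seed = 1L, rest_duration = 0.5,
                              gesture_duration = 1.0, spec = dataset_spec(),
                              quantize_16bit = FALSE) {
  if (gesture_duration < 1.0)
    stop("gesture_duration must be >= 1 s for the reference protocol")
  if (rest_duration <= 0) stop("rest_duration must be positive")
  structure(list(seed = as.integer(seed), rest_duration = rest_duration,
                 gesture_duration = gesture_duration, spec = spec,
                 quantize_16bit = isTRUE(quantize_16bit)),
            class = "generation_config")
}

#' Draw deterministic subject profiles with separated spectral peaks
#'
#' Channel-1 peak frequencies are drawn so that any two subjects differ by at
#' least `delta` Hz, which makes identities learnable by construction;
#' channel 2 gets an offset peak with the same separation structure.
#'
#' @param n_subjects number of profiles (>= 1).
#' @param seed integer seed (same seed, same profiles).
#' @param delta minimum pairwise separation of peak frequencies in Hz
#'   (default 10).
#' @param fs sampling rate the band constraint is checked against.
#' @return list of [subject_profile()]s.
#' @export
make_subject_profiles <- function(n_subjects, seed = 1L, delta = 10, fs = 2000) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  f_lo <- 60; f_hi <- 430   # leaves room for the widest bandwidth draw
  span <- f_hi - f_lo
  if ((n_subjects - 1) * delta > span)
    stop(sprintf(
      "cannot place %d peaks with %g Hz separation inside [%g, %g] Hz",
      n_subjects, delta, f_lo, f_hi))
  rng <- .new_rng(seed)
  # delta-separated draw: sort uniforms on the slack, then add back the gaps
  draw_peaks <- function() {
    slack <- span - (n_subjects - 1) * delta
    u <- sort(rng$runif(n_subjects, 0, slack))
    f_lo + u + delta * (seq_len(n_subjects) - 1)
  }
  p1 <- draw_peaks()
  p2 <- draw_peaks()
  ord2 <- rng$sample(n_subjects)   # decouple channel-2 ordering from channel 1
  lapply(seq_len(n_subjects), function(i) {
    subject_profile(
      subject_id = i,
      peak_freq = c(p1[i], p2[ord2[i]]),
      bandwidth = rng$runif(2, 15, 30),
      contraction_gain = rng$runif(2, 4, 8),
      rise_time = rng$runif(1, 0.1, 0.2),
      fall_time = rng$runif(1, 0.1, 0.2),
      rest_rms = rng$runif(1, 0.015, 0.03),
      session_gain = rng$runif(3, 0.85, 1.15),
      fs = fs)
  })
}

# Small closure-based RNG handle so generator draws are insulated from the
# caller's RNG state and occur in a documented order.
.new_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    runif = function(n, lo = 0, hi = 1) with_state(function() stats::runif(n, lo, hi)),
    rnorm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    sample = function(n) with_state(function() sample.int(n))
  )
}

# Independent, order-insensitive seed for one repetition's draws.
.repetition_seed <- function(seed, subject_id, gesture_id, session_id, repetition) {
  ((seed %% 1000003) * 2039 + subject_id * 12037 + gesture_id * 607 +
     session_id * 101 + repetition * 7) %% 2147483647L
}

# Smooth rest-contraction-rest envelope over n_total samples; raised-cosine
# ramps, per-gesture duty factor, slow sinusoidal modulation for "dynamic"
# gestures (ids 7..12).
.gesture_envelope <- function(n_total, start, end, fs, gesture_id,
                              rise_time, fall_time) {
  env <- numeric(n_total)
  n_b <- end - start
  t <- (seq_len(n_b) - 1) / fs
  dur <- n_b / fs
  n_r <- max(2L, round(rise_time * fs))
  n_f <- max(2L, round(fall_time * fs))
  shape <- rep(1, n_b)
  shape[1:n_r] <- (1 - cos(pi * (0:(n_r - 1)) / (n_r - 1))) / 2
  shape[(n_b - n_f + 1):n_b] <- (1 + cos(pi * (0:(n_f - 1)) / (n_f - 1))) / 2
  duty <- 0.55 + 0.45 * ((gesture_id - 1) %% 6) / 5   # plateau emphasis per gesture
  shape <- shape^(1.6 - duty)
  if (gesture_id > 6) {                               # dynamic gestures: slow tremor
    f_mod <- 1 + 0.5 * ((gesture_id - 7) %% 6)
    shape <- shape * (0.75 + 0.25 * cos(2 * pi * f_mod * t))
  }
  env[(start + 1):end] <- shape
  env
}

# Band-limited unit-RMS Gaussian noise, shaped in the frequency domain with a
# Gaussian magnitude profile centered on `peak` (sd = bandwidth/2, so ~95% of
# the power lies within peak +/- bandwidth). Frequency-domain shaping keeps
# the spectral mode exactly at the profile peak, which an IIR bandpass does
# not (its response is skewed toward the geometric band center).
.band_noise <- function(n, peak, bandwidth, fs, rng) {
  w <- rng$rnorm(n)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)             # two-sided spectrum
  g <- exp(-0.5 * ((freqs - peak) / (bandwidth / 2))^2)
  x <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Synthesize one repetition record
#'
#' Generates the rest-burst-rest structure described in [synth]: rest-level
#' white noise throughout, plus band-limited noise shaped by the gesture
#' envelope inside the contraction span, scaled by the session gain, plus any
#' mains / baseline-wander components the profile carries.
#'
#' @param profile a [subject_profile()].
#' @param gesture_id,session_id,repetition labels for the record.
#' @param config a [generation_config()].
#' @return a [semg_record()] whose `start_index`/`end_index` mark the burst.
#' @export
synthesize_repetition <- function(profile, gesture_id, session_id, repetition,
                                  config = generation_config()) {
  fs <- config$spec$fs
  n_rest <- round(config$rest_duration * fs)
  n_gest <- round(config$gesture_duration * fs)
  n_total <- 2L * n_rest + n_gest
  start <- n_rest; end <- n_rest + n_gest
  if (n_gest < 2 || n_rest < 1)
    stop("envelope durations inconsistent with record length")
  rng <- .new_rng(.repetition_seed(config$seed, profile$subject_id,
                                   gesture_id, session_id, repetition))
  env <- .gesture_envelope(n_total, start, end, fs, gesture_id,
                           profile$rise_time, profile$fall_time)
  g_sess <- profile$session_gain[session_id]
  t <- (seq_len(n_total) - 1) / fs
  samples <- matrix(0, nrow = 2L, ncol = n_total)
  for (ch in 1:2) {
    rest <- rng$rnorm(n_total, sd = profile$rest_rms)
    burst <- .band_noise(n_total, profile$peak_freq[ch],
                         profile$bandwidth[ch], fs, rng)
    x <- rest + burst * env * profile$rest_rms * profile$contraction_gain[ch] * g_sess
    if (profile$mains_amp > 0)
      x <- x + profile$mains_amp * sin(2 * pi * 60 * t + rng$runif(1, 0, 2 * pi))
    if (profile$wander_amp > 0)
      x <- x + profile$wander_amp * sin(2 * pi * profile$wander_freq * t +
                                          rng$runif(1, 0, 2 * pi))
    samples[ch, ] <- x
  }
  if (config$quantize_16bit) {
    full <- max(abs(samples)) * 1.05
    step <- 2 * full / (2^config$spec$adc_bits - 1)
    samples <- round(samples / step) * step
  }
  semg_record(samples, fs = fs, subject_id = profile$subject_id,
              gesture_id = gesture_id, session_id = session_id,
              repetition = repetition, start_index = start, end_index = end)
}

#' Generate the complete factorial dataset for a set of profiles
#'
#' One record per (subject, gesture, session, repetition) cell of the
#' layout in `config$spec`; byte-identical for identical seeds because each
#' repetition draws from its own derived substream.
#'
#' @param profiles non-empty list of [subject_profile()]s.
#' @param config a [generation_config()].
#' @param gestures,sessions optional integer subsets of the gesture/session
#'   ids to generate (defaults: all in the layout).
#' @return list of [semg_record()]s.
#' @export
generate_dataset <- function(profiles, config = generation_config(),
                             gestures = NULL, sessions = NULL) {
  if (length(profiles) == 0) stop("`profiles` is empty")
  spec <- config$spec
  gestures <- if (is.null(gestures)) seq_len(spec$n_gestures) else gestures
  sessions <- if (is.null(sessions)) seq_len(spec$n_sessions) else sessions
  out <- vector("list",
                length(profiles) * length(gestures) * length(sessions) * spec$n_repetitions)
  i <- 0L
  for (p in profiles) for (g in gestures) for (s in sessions)
    for (r in seq_len(spec$n_repetitions)) {
      i <- i + 1L
      out[[i]] <- synthesize_repetition(p, g, s, r, config)
    }
  out
}

.burst_peak <- function(record) {
  max(abs(record$samples[, (record$start_index + 1):record$end_index]))
}

#' Magnitude quality-control rule
#'
#' Applies the acquisition guideline that a repetition whose magnitude is 20%
#' higher than the others in its (subject, gesture, session) group is
#' rejected. "Magnitude" is realized as the burst peak amplitude over both
#' channels, and "the others" as the leave-one-out median: a record is
#' rejected iff its burst peak is strictly greater than 1.2 x the median
#' burst peak of the remaining records.
#'
#' @param records list of >= 2 [semg_record()]s from one group.
#' @return list with `kept` and `rejected` (each a list of records;
#'   their union is the input).
#' @export
qc_magnitude_filter <- function(records) {
  if (length(records) < 2) stop("magnitude QC needs >= 2 records in the group")
  peaks <- vapply(records, .burst_peak, numeric(1))
  reject <- vapply(seq_along(records), function(i)
    peaks[i] > 1.2 * stats::median(peaks[-i]), logical(1))
  list(kept = records[!reject], rejected = records[reject])
}

# Smoothed rectified envelope: moving average of |x| (channel mean), window
# in seconds.
.smoothed_envelope <- function(record, window_s = 0.1) {
  x <- colMeans(abs(record$samples))
  w <- max(1L, round(window_s * record$fs))
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2, circular = TRUE))
}

#' Envelope-shape quality-control rule
#'
#' Applies the guideline that a repetition whose envelope differs from the
#' others is rejected: each record's smoothed rectified envelope (100 ms
#' moving average of the rectified channel-mean signal) is correlated
#' (Pearson) with the mean envelope of the *other* records in the group, and
#' records falling below `threshold` are rejected.
#'
#' @param records list of >= 2 [semg_record()]s of equal length.
#' @param threshold correlation threshold in (0, 1) (default 0.8).
#' @return list with `kept`, `rejected`, and the per-record `correlation`.
#' @export
qc_envelope_filter <- function(records, threshold = 0.8) {
  if (length(records) < 2) stop("envelope QC needs >= 2 records in the group")
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  envs <- vapply(records, .smoothed_envelope, numeric(ncol(records[[1]]$samples)))
  sds <- apply(envs, 2, stats::sd)
  if (any(sds == 0))
    stop("constant envelope (zero variance) in record ", which(sds == 0)[1])
  cors <- vapply(seq_along(records), function(i)
    stats::cor(envs[, i], rowMeans(envs[, -i, drop = FALSE])), numeric(1))
  reject <- cors < threshold
  list(kept = records[!reject], rejected = records[reject], correlation = cors)
}

#' Periodogram band-power features of a record's burst
#'
#' Integrates the burst-segment periodogram (channel-wise) over `n_bands`
#' equal-width bands spanning `[f_min, f_max]`, normalized to sum to 1 per
#' channel. A compact spectral signature used for the generator's
#' separability check and for quick nearest-centroid baselines.
#'
#' @param record a [semg_record()].
#' @param n_bands number of bands (default 16).
#' @param f_min,f_max band range in Hz (defaults 10 and 500).
#' @return numeric vector of length `2 * n_bands`.
#' @export
band_power_features <- function(record, n_bands = 16L, f_min = 10, f_max = 500) {
  idx <- (record$start_index + 1):record$end_index
  edges <- seq(f_min, f_max, length.out = n_bands + 1L)
  feats <- lapply(1:2, function(ch) {
    x <- record$samples[ch, idx]
    n <- length(x)
    p <- Mod(stats::fft(x))^2 / n
    freqs <- (seq_len(n) - 1) * record$fs / n
    half <- freqs <= record$fs / 2
    band <- findInterval(freqs[half], edges, all.inside = FALSE)
    keep <- band >= 1 & band <= n_bands
    bp <- vapply(seq_len(n_bands), function(b) sum(p[half][keep & band == b]),
                 numeric(1))
    bp / sum(bp)
  })
  unlist(feats)
}

#' Empirical spectral peak of a record's burst
#'
#' Frequency (Hz) of the maximum of the burst-segment periodogram for one
#' channel; used to verify the generator's spectral fidelity.
#'
#' @param record a [semg_record()].
#' @param channel channel index (1 or 2).
#' @return peak frequency in Hz.
#' @export
spectral_peak <- function(record, channel = 1L) {
  x <- record$samples[channel, (record$start_index + 1):record$end_index]
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) * record$fs / n
  half <- which(freqs > 0 & freqs <= record$fs / 2)
  freqs[half][which.max(p[half])]
}
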