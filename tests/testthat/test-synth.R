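test_that("profiles are deterministic, delta-separated and inside the valid band", {
  p1 <- make_subject_profiles(5, seed = 3, delta = 10)
  p2 <- make_subject_profiles(5, seed = 3, delta = 10)
  expect_identical(p1, p2)
  for (ch in 1:2) {
    peaks <- sapply(p1, function(p) p$peak_freq[ch])
    gaps <- diff(sort(peaks))
    expect_true(all(gaps >= 10))
    bws <- sapply(p1, function(p) p$bandwidth[ch])
    expect_true(all(peaks - bws > 0 & peaks + bws < 1000))
  }
  expect_error(make_subject_profiles(100, seed = 1, delta = 10), "separation")
})

test_that("a repetition has the rest-burst-rest structure of the acquisition protocol", {
  cfg <- generation_config(seed = 2)
  p <- make_subject_profiles(2, seed = 2)[[1]]
  rec <- synthesize_repetition(p, 3, 1, 1, cfg)
  fs <- cfg$spec$fs
  expect_equal(ncol(rec$samples), (2 * cfg$rest_duration + cfg$gesture_duration) * fs)
  expect_gte((rec$end_index - rec$start_index) / fs, 1.0)
  expect_length(validate_record(rec), 0)
  for (ch in 1:2) {
    rest_head <- stats::sd(rec$samples[ch, 1:(rec$start_index - 100)])
    rest_tail <- stats::sd(rec$samples[ch, (rec$end_index + 100):ncol(rec$samples)])
    burst <- stats::sd(rec$samples[ch, (rec$start_index + 200):(rec$end_index - 200)])
    expect_lt(rest_head, burst)
    expect_lt(rest_tail, burst)
  }
  expect_error(generation_config(gesture_duration = 0.5), ">= 1 s")
})

test_that("generated bursts carry the profile's spectral signature", {
  p <- make_subject_profiles(3, seed = 7)
  cfg <- generation_config(seed = 7)
  for (prof in p) {
    # mean periodogram over 10 repetitions, then its peak (FFT oracle)
    for (ch in 1:2) {
      acc <- NULL
      for (r in 1:10) {
        rec <- synthesize_repetition(prof, 1, 1, r, cfg)
        x <- rec$samples[ch, (rec$start_index + 1):rec$end_index]
        pg <- Mod(stats::fft(x))^2
        acc <- if (is.null(acc)) pg else acc + pg
      }
      freqs <- (seq_along(acc) - 1) * cfg$spec$fs / length(acc)
      half <- freqs > 0 & freqs <= cfg$spec$fs / 2
      # light Daniell smoothing (+/- 2 Hz) before the argmax
      sm <- stats::filter(acc[half], rep(1 / 5, 5), sides = 2)
      peak_hat <- freqs[half][which.max(sm)]
      expect_lt(abs(peak_hat - prof$peak_freq[ch]), prof$bandwidth[ch] / 2)
    }
  }
})

test_that("mains contamination appears as a dominant 60 Hz line", {
  p <- make_subject_profiles(1, seed = 9)[[1]]
  p$mains_amp <- 0.2
  rec <- synthesize_repetition(p, 1, 1, 1, generation_config(seed = 9))
  x <- rec$samples[1, ]
  n <- length(x)
  pg <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) * rec$fs / n
  i60 <- which.min(abs(freqs - 60))
  neighbors <- pg[c(i60 - 8, i60 - 6, i60 + 6, i60 + 8)]
  expect_gt(pg[i60], 10 * max(neighbors))
})

test_that("the factorial design and determinism hold for full datasets", {
  p <- make_subject_profiles(1, seed = 4)
  cfg1 <- generation_config(seed = 4, spec = dataset_spec(n_gestures = 1))
  expect_length(generate_dataset(p, cfg1), 30)          # 10 reps x 3 sessions

  cfg2 <- generation_config(seed = 4, spec = dataset_spec(n_gestures = 2,
                                                          n_sessions = 2,
                                                          n_repetitions = 3))
  d1 <- generate_dataset(p, cfg2)
  d2 <- generate_dataset(p, cfg2)
  expect_length(d1, 12)
  expect_identical(lapply(d1, `[[`, "samples"), lapply(d2, `[[`, "samples"))
  keys <- sapply(d1, function(r) paste(r$gesture_id, r$session_id, r$repetition))
  expect_false(any(duplicated(keys)))
  expect_true(all(lengths(lapply(d1, validate_record)) == 0))
})

test_that("the 20%-magnitude rule rejects exactly the planted outlier", {
  base <- lapply(1:10, function(r) toy_record(repetition = r, amp = 1))
  res <- qc_magnitude_filter(base)
  expect_length(res$rejected, 0)

  outlier <- c(lapply(1:9, function(r) toy_record(repetition = r, amp = 1)),
               list(toy_record(repetition = 10L, amp = 1.3)))
  res <- qc_magnitude_filter(outlier)
  expect_length(res$rejected, 1)
  expect_equal(res$rejected[[1]]$repetition, 10L)
  expect_length(res$kept, 9)

  # boundary: exactly 1.2 x median is kept (strict inequality)
  boundary <- c(lapply(1:9, function(r) toy_record(repetition = r, amp = 1)),
                list(toy_record(repetition = 10L, amp = 1.2)))
  expect_length(qc_magnitude_filter(boundary)$rejected, 0)
  expect_error(qc_magnitude_filter(base[1]), ">= 2")
})

test_that("the envelope rule rejects a half-record time-shifted repetition", {
  grp <- lapply(1:6, function(r) toy_record(repetition = r))
  res <- qc_envelope_filter(grp, threshold = 0.8)
  expect_length(res$rejected, 0)

  # burst displaced by half the 1200-sample record (600 samples)
  mk <- function(r, off = 0L) toy_record(repetition = r, n_rest = 150L,
                                         n_burst = 300L, n_total = 1200L,
                                         burst_offset = off)
  shifted <- c(lapply(1:5, mk), list(mk(6L, off = 600L)))
  res <- qc_envelope_filter(shifted, threshold = 0.8)
  expect_length(res$rejected, 1)
  expect_equal(res$rejected[[1]]$repetition, 6L)

  # at threshold 0 only anti-correlated envelopes are rejected; the rejection
  # set must agree with the returned correlations
  res0 <- qc_envelope_filter(shifted, threshold = 0)
  expect_equal(length(res0$rejected), sum(res0$correlation < 0))

  flat <- toy_record()
  flat$samples[] <- 1
  expect_error(qc_envelope_filter(list(flat, toy_record(repetition = 2L))),
               "constant envelope")
})

test_that("delta-separated subjects are separable by band-power nearest centroid", {
  profiles <- make_subject_profiles(5, seed = 21, delta = 10)
  cfg <- generation_config(seed = 21, spec = dataset_spec(n_gestures = 1,
                                                          n_repetitions = 6))
  recs <- generate_dataset(profiles, cfg)
  subj <- sapply(recs, `[[`, "subject_id")
  sess <- sapply(recs, `[[`, "session_id")
  feats <- t(sapply(recs, band_power_features))
  train <- sess <= 2; test <- !train
  centroids <- t(sapply(sort(unique(subj)), function(s)
    colMeans(feats[train & subj == s, , drop = FALSE])))
  pred <- apply(feats[test, ], 1, function(f)
    which.min(colSums((t(centroids) - f)^2)))
  expect_gte(mean(pred == subj[test]), 0.9)
})
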