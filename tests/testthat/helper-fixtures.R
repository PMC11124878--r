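# Shared fixtures. The trained end-to-end pipeline is expensive (~2-3 min),
# so it is built lazily, once per seed, and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

# Canonical scaled study: 5 delta-separated subjects, gestures 1-3, full
# 3-session x 10-repetition design.
scaled_study_records <- function(seed) {
  key <- paste0("recs_", seed)
  if (is.null(.fixture_env[[key]])) {
    profiles <- make_subject_profiles(5, seed = seed, delta = 10)
    .fixture_env[[key]] <- generate_dataset(
      profiles, generation_config(seed = seed), gestures = 1:3)
  }
  .fixture_env[[key]]
}

trained_pipeline <- function(seed) {
  key <- paste0("pipe_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- identify_subjects(scaled_study_records(seed),
                                             seed = seed)
  }
  .fixture_env[[key]]
}

# Minimal hand-built record: sine burst between rests, amplitude `amp`.
toy_record <- function(subject_id = 1L, gesture_id = 1L, session_id = 1L,
                       repetition = 1L, amp = 1, n_rest = 200L,
                       n_burst = 400L, freq = 100, fs = 2000,
                       burst_offset = 0L, n_total = 2L * n_rest + n_burst) {
  n <- n_total
  stopifnot(n_rest + burst_offset + n_burst <= n)
  x <- matrix(1e-3 * sin(2 * pi * 7 * seq_len(n) / fs), 2, n, byrow = TRUE)
  t_burst <- seq_len(n_burst) / fs
  s0 <- n_rest + burst_offset
  x[, (s0 + 1):(s0 + n_burst)] <- amp * rbind(sin(2 * pi * freq * t_burst),
                                              cos(2 * pi * freq * t_burst))
  semg_record(x, fs = fs, subject_id = subject_id, gesture_id = gesture_id,
              session_id = session_id, repetition = repetition,
              start_index = n_rest, end_index = n_rest + n_burst,
              validate = FALSE)
}

# Independent per-item recount of precision/recall/F1/accuracy, used as the
# oracle against classification_metrics().
brute_force_metrics <- function(truth, predicted, labels) {
  per <- lapply(labels, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f, support = tp + fn)
  })
  m <- do.call(rbind, per)
  list(precision = m[, "precision"], recall = m[, "recall"], f1 = m[, "f1"],
       support = m[, "support"], accuracy = mean(truth == predicted))
}

reference_table <- function(name) {
  utils::read.table(system.file("extdata", name, package = "semgid"),
                    header = TRUE, sep = "\t")
}
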