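#' A single sEMG repetition record
#'
#' One record holds one rest-contraction-rest execution of a hand gesture:
#' a 2 x N sample matrix (one row per electrode channel, palmaris longus and
#' extensor digitorum in the reference acquisition), the sampling rate, the
#' subject / gesture / session / repetition labels, and the 0-based half-open
#' bounds of the active-gesture (contraction) span within the record.
#'
#' @param samples numeric matrix with exactly 2 rows (channels) and N columns
#'   (samples), in arbitrary amplitude units.
#' @param fs sampling rate in Hz (2000 for the reference protocol).
#' @param subject_id positive integer subject label.
#' @param gesture_id integer gesture label in 1..12.
#' @param session_id integer session label in 1..3.
#' @param repetition integer repetition label in 1..10.
#' @param start_index,end_index 0-based half-open bounds `[start, end)` of the
#'   contraction span, with `0 <= start < end <= N`.
#' @param validate if `TRUE` (default), stop when [validate_record()] reports
#'   any violation; set to `FALSE` to construct deliberately invalid records
#'   (e.g. to exercise validation itself).
#' @return an object of class `semg_record`.
#' @seealso [validate_record()], [amplitude_histogram()]
#' @export
semg_record <- function(samples, fs, subject_id, gesture_id, session_id,
                        repetition, start_index, end_index, validate = TRUE) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric matrix (channels x samples)")
  rec <- structure(
    list(
      samples = samples,
      fs = as.numeric(fs),
      subject_id = as.integer(subject_id),
      gesture_id = as.integer(gesture_id),
      session_id = as.integer(session_id),
      repetition = as.integer(repetition),
      start_index = as.integer(start_index),
      end_index = as.integer(end_index)
    ),
    class = "semg_record"
  )
  if (validate) {
    bad <- validate_record(rec)
    if (length(bad))
      stop("invalid semg_record: ", paste(bad, collapse = "; "))
  }
  rec
}

#' Validate an sEMG record against the data-model invariants
#'
#' Checks the structural invariants of the record (two channels, in-range
#' labels, consistent index bounds, positive sampling rate) and returns the
#' violations as a character vector instead of raising, so that callers can
#' aggregate quality reports over whole datasets.
#'
#' @param record a [semg_record()].
#' @param expected_fs optional sampling rate in Hz; when supplied, a mismatch
#'   is reported as a violation (the reference protocol uses 2000 Hz).
#' @return character vector of violation descriptions, each naming the field
#'   at fault; `character(0)` when every invariant holds.
#' @export
validate_record <- function(record, expected_fs = NULL) {
  v <- character(0)
  s <- record$samples
  n <- ncol(s)
  if (!is.matrix(s) || nrow(s) != 2L)
    v <- c(v, sprintf("samples: expected exactly 2 channels, found %s",
                      if (is.matrix(s)) nrow(s) else "a non-matrix"))
  if (anyNA(s))
    v <- c(v, "samples: contains NA values")
  if (!is.finite(record$fs) || record$fs <= 0)
    v <- c(v, sprintf("fs: must be a positive rate, found %s", record$fs))
  if (!is.null(expected_fs) && isTRUE(record$fs != expected_fs))
    v <- c(v, sprintf("fs: expected %g Hz, found %g Hz", expected_fs, record$fs))
  if (is.na(record$subject_id) || record$subject_id < 1L)
    v <- c(v, sprintf("subject_id: must be a positive integer, found %s",
                      record$subject_id))
  if (is.na(record$gesture_id) || !record$gesture_id %in% 1:12)
    v <- c(v, sprintf("gesture_id: must be in 1..12, found %s", record$gesture_id))
  if (is.na(record$session_id) || !record$session_id %in% 1:3)
    v <- c(v, sprintf("session_id: must be in 1..3, found %s", record$session_id))
  if (is.na(record$repetition) || !record$repetition %in% 1:10)
    v <- c(v, sprintf("repetition: must be in 1..10, found %s", record$repetition))
  si <- record$start_index; ei <- record$end_index
  if (is.na(si) || is.na(ei) || si < 0L || si >= ei || ei > n)
    v <- c(v, sprintf(
      "start_index/end_index: need 0 <= start < end <= N, found [%s, %s) with N = %d",
      si, ei, n))
  v
}

#' @export
print.semg_record <- function(x, ...) {
  cat(sprintf(
    "<semg_record> subject %d, gesture %d, session %d, repetition %d\n",
    x$subject_id, x$gesture_id, x$session_id, x$repetition))
  cat(sprintf("  2 x %d samples at %g Hz; contraction span [%d, %d)\n",
              ncol(x$samples), x$fs, x$start_index, x$end_index))
  invisible(x)
}

#' Dataset design parameters
#'
#' Describes the factorial layout of a multi-session sEMG dataset. The
#' defaults reproduce the reference acquisition design: 12 gestures x 3
#' sessions x 10 repetitions per subject at 2000 Hz with 16-bit quantization,
#' i.e. 360 records per subject.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_gestures number of gestures (default 12).
#' @param n_sessions number of sessions (default 3).
#' @param n_repetitions repetitions per gesture per session (default 10).
#' @param fs sampling rate in Hz (default 2000).
#' @param adc_bits ADC resolution in bits (default 16).
#' @return an object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_subjects = 1L, n_gestures = 12L, n_sessions = 3L,
                         n_repetitions = 10L, fs = 2000, adc_bits = 16L) {
  counts <- c(n_subjects = n_subjects, n_gestures = n_gestures,
              n_sessions = n_sessions, n_repetitions = n_repetitions)
  if (any(counts < 1))
    stop("all dataset counts must be >= 1; offending: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  if (fs <= 0) stop("fs must be positive")
  if (adc_bits < 1) stop("adc_bits must be >= 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_gestures = as.integer(n_gestures),
                 n_sessions = as.integer(n_sessions),
                 n_repetitions = as.integer(n_repetitions),
                 fs = as.numeric(fs), adc_bits = as.integer(adc_bits)),
            class = "dataset_spec")
}

#' Per-channel amplitude histogram of a record
#'
#' Bins each channel's sample amplitudes into `n_bins` equal-width bins
#' spanning that channel's `[min, max]` range, the summary used to profile a
#' subject's signal amplitude distribution.
#'
#' @param record a [semg_record()].
#' @param n_bins number of bins (>= 1).
#' @return a list with one element per channel, each a list with `edges`
#'   (length `n_bins + 1`) and `counts` (length `n_bins`, summing to N).
#' @export
amplitude_histogram <- function(record, n_bins) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  n_bins <- as.integer(n_bins)
  lapply(seq_len(nrow(record$samples)), function(ch) {
    x <- record$samples[ch, ]
    lo <- min(x); hi <- max(x)
    if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }  # constant channel: one occupied bin
    edges <- seq(lo, hi, length.out = n_bins + 1L)
    idx <- findInterval(x, edges, all.inside = TRUE)
    list(channel = ch, edges = edges, counts = tabulate(idx, nbins = n_bins))
  })
}
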