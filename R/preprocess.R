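#' Signal-conditioning parameters
#'
#' The reference conditioning chain: an order-3 Butterworth bandpass keeping
#' 5-500 Hz (removing sub-5 Hz baseline wander and out-of-band noise)
#' cascaded with a narrow 60 Hz notch removing mains interference, designed
#' for a 2000 Hz sampling rate.
#'
#' @param low_cut,high_cut bandpass edges in Hz (defaults 5 and 500);
#'   `0 < low_cut < high_cut < fs/2`.
#' @param order Butterworth order (default 3).
#' @param notch_freq mains frequency in Hz (default 60).
#' @param notch_quality notch quality factor Q (default 30); the -3 dB notch
#'   width is `notch_freq / Q`.
#' @param fs sampling rate in Hz (default 2000).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 5, high_cut = 500, order = 3L,
                        notch_freq = 60, notch_quality = 30, fs = 2000) {
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < fs / 2))
    stop("need 0 < low_cut < high_cut < fs/2")
  if (order < 1) stop("order must be >= 1")
  if (!(notch_freq > 0 && notch_freq < fs / 2))
    stop("notch_freq must lie in (0, fs/2)")
  structure(list(low_cut = low_cut, high_cut = high_cut, order = as.integer(order),
                 notch_freq = notch_freq, notch_quality = notch_quality, fs = fs),
            class = "filter_spec")
}

# RBJ second-order IIR notch; no installed package designs one.
.design_notch <- function(f0, q, fs) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Design the conditioning filters
#'
#' Returns realizable coefficients for the Butterworth bandpass and the
#' 60 Hz biquad notch of a [filter_spec()], checking stability (all poles
#' strictly inside the unit circle).
#'
#' @param spec a [filter_spec()].
#' @return an object of class `semg_filters` with elements `bandpass` and
#'   `notch` (each `list(b, a)`) and the spec; see [filter_response()].
#' @export
design_filters <- function(spec = filter_spec()) {
  bw <- signal::butter(spec$order,
                       c(spec$low_cut, spec$high_cut) / (spec$fs / 2),
                       type = "pass")
  bp <- list(b = as.numeric(bw$b), a = as.numeric(bw$a))
  nt <- .design_notch(spec$notch_freq, spec$notch_quality, spec$fs)
  for (f in list(bp, nt)) {
    poles <- polyroot(rev(f$a))
    if (any(Mod(poles) >= 1))
      stop("unstable filter design (pole magnitude >= 1); adjust the spec")
  }
  structure(list(bandpass = bp, notch = nt, spec = spec), class = "semg_filters")
}

#' Frequency response of the conditioning chain
#'
#' Evaluates the combined (cascaded notch x bandpass) magnitude response at
#' the requested frequencies. Because application is zero-phase
#' (forward-backward), the effective magnitude response is the square of the
#' single-pass response; `squared = TRUE` (default) returns that effective
#' response.
#'
#' @param filters a `semg_filters` object from [design_filters()].
#' @param freqs frequencies in Hz.
#' @param squared return the zero-phase (two-pass) magnitude (default).
#' @return numeric vector of magnitude gains (linear units).
#' @export
filter_response <- function(filters, freqs, squared = TRUE) {
  fs <- filters$spec$fs
  h_of <- function(f, w) {
    z <- exp(-1i * 2 * pi * w / fs)
    num <- vapply(seq_along(f$b), function(k) f$b[k] * z^(k - 1), complex(length(w)))
    den <- vapply(seq_along(f$a), function(k) f$a[k] * z^(k - 1), complex(length(w)))
    if (length(w) == 1L) sum(num) / sum(den)
    else rowSums(num) / rowSums(den)
  }
  h <- Mod(h_of(filters$bandpass, freqs)) * Mod(h_of(filters$notch, freqs))
  if (squared) h^2 else h
}

# Zero-phase IIR application: reflective padding of 3 x the filter length,
# filter forward, reverse, filter again, reverse, trim.
.filtfilt_reflect <- function(b, a, x) {
  npad <- 3L * max(length(a), length(b))
  n <- length(x)
  if (n <= npad)
    stop(sprintf("signal too short for zero-phase filtering (%d <= %d padding samples)",
                 n, npad))
  # odd reflection about the end points removes step discontinuities
  head_pad <- 2 * x[1] - x[(npad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
  xp <- c(head_pad, x, tail_pad)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(as.numeric(y))))
  as.numeric(y)[(npad + 1):(npad + n)]
}

#' Apply the conditioning chain to a record
#'
#' Zero-phase (forward-backward) application of the notch and then the
#' bandpass to each channel. Output length equals input length; labels and
#' index bounds are preserved.
#'
#' @param record a [semg_record()] with `fs` matching the spec.
#' @param spec a [filter_spec()] (or a prebuilt `semg_filters`).
#' @return the filtered [semg_record()].
#' @export
preprocess_record <- function(record, spec = filter_spec()) {
  filters <- if (inherits(spec, "semg_filters")) spec else design_filters(spec)
  if (record$fs != filters$spec$fs)
    stop(sprintf("record fs (%g) does not match filter spec fs (%g)",
                 record$fs, filters$spec$fs))
  out <- record
  for (ch in seq_len(nrow(record$samples))) {
    x <- record$samples[ch, ]
    x <- .filtfilt_reflect(filters$notch$b, filters$notch$a, x)
    x <- .filtfilt_reflect(filters$bandpass$b, filters$bandpass$a, x)
    out$samples[ch, ] <- x
  }
  out
}

#' Z-score normalization per channel
#'
#' Centers and scales each channel to mean 0, standard deviation 1. Affine
#' transforms of the input (`a * x + b`, `a > 0`) normalize to the same
#' output.
#'
#' @param x a channels-x-samples numeric matrix or a [semg_record()].
#' @return object of the same type with normalized samples.
#' @export
zscore_normalize <- function(x) {
  if (inherits(x, "semg_record")) {
    x$samples <- zscore_normalize(x$samples)
    return(x)
  }
  m <- rowMeans(x)
  s <- apply(x, 1L, stats::sd)
  if (any(s == 0))
    stop("zero-variance channel ", which(s == 0)[1], "; cannot z-score")
  (x - m) / s
}

#' Fixed-length windowing parameters
#'
#' @param window_length window length in samples (default 2000, i.e. 1 s at
#'   2000 Hz).
#' @param stride hop between window starts in samples (default 1000);
#'   `1 <= stride <= window_length`.
#' @param restrict_to_burst if `TRUE` (default) windows are drawn from the
#'   contraction span `[start_index, end_index)` only.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(window_length = 2000L, stride = 1000L,
                        restrict_to_burst = TRUE) {
  if (stride < 1 || stride > window_length)
    stop("need 1 <= stride <= window_length")
  structure(list(window_length = as.integer(window_length),
                 stride = as.integer(stride),
                 restrict_to_burst = isTRUE(restrict_to_burst)),
            class = "window_spec")
}

#' Cut a record into fixed-length model-input windows
#'
#' Yields `floor((M - L) / stride) + 1` windows of the selected region
#' (contraction span or whole record), each carrying the record's labels. A
#' region shorter than one window yields an empty list with a warning.
#'
#' @param record a [semg_record()].
#' @param wspec a [window_spec()].
#' @return list of windows, each `list(window, subject_id, gesture_id,
#'   session_id, repetition)` with `window` a 2 x L matrix.
#' @export
segment_windows <- function(record, wspec = window_spec()) {
  region <- if (wspec$restrict_to_burst)
    (record$start_index + 1):record$end_index else seq_len(ncol(record$samples))
  m <- length(region)
  L <- wspec$window_length
  if (m < L) {
    warning(sprintf(
      "region of %d samples shorter than window length %d; no windows", m, L))
    return(list())
  }
  n_win <- (m - L) %/% wspec$stride + 1L
  lapply(seq_len(n_win), function(k) {
    off <- (k - 1L) * wspec$stride
    list(window = record$samples[, region[(off + 1):(off + L)], drop = FALSE],
         subject_id = record$subject_id, gesture_id = record$gesture_id,
         session_id = record$session_id, repetition = record$repetition)
  })
}

#' Decimate a record by an integer factor
#'
#' Anti-alias lowpass plus subsampling (via [signal::decimate()]); sampling
#' rate and index bounds are rescaled. Used as the optional
#' dimensionality-reduction step before windowing: a factor of 2 halves the
#' model input length while keeping the full 5-500 Hz analysis band below
#' the new Nyquist frequency.
#'
#' @param record a [semg_record()].
#' @param factor integer decimation factor >= 1 (1 is a no-op).
#' @return the decimated [semg_record()].
#' @export
decimate_record <- function(record, factor = 1L) {
  factor <- as.integer(factor)
  if (factor < 1) stop("decimation factor must be >= 1")
  if (factor == 1L) return(record)
  out <- record
  dec <- t(vapply(seq_len(nrow(record$samples)), function(ch)
    as.numeric(signal::decimate(record$samples[ch, ], factor, ftype = "fir")),
    numeric(ceiling(ncol(record$samples) / factor))))
  out$samples <- dec
  out$fs <- record$fs / factor
  out$start_index <- as.integer(record$start_index %/% factor)
  out$end_index <- as.integer(min(ncol(dec), ceiling(record$end_index / factor)))
  out
}
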