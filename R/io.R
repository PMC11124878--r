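#' @name semg_io
#' @title Plain-text dataset layout
#' @description
#' Datasets are stored as one raw two-column tab-separated signal file per
#' repetition (channel 1, channel 2; one row per sample; no header) plus a
#' single header-bearing manifest, `manifest.tsv`, whose columns are
#' `file`, `start_index`, `end_index`, `subject_id`, `gesture_id`,
#' `session_id`, `repetition`. All metadata lives in the manifest so the
#' signal files stay raw. Indices are 0-based half-open.
NULL

.manifest_cols <- c("file", "start_index", "end_index",
                    "subject_id", "gesture_id", "session_id", "repetition")

.record_key <- function(subject_id, gesture_id, session_id, repetition) {
  sprintf("s%d.g%d.sess%d.rep%d", subject_id, gesture_id, session_id, repetition)
}

#' Write a collection of sEMG records to a plain-text dataset
#'
#' Writes one two-column TSV signal file per record plus a `manifest.tsv`
#' carrying all labels and index bounds (see [semg_io]).
#'
#' @param records non-empty list of [semg_record()]s sharing one sampling
#'   rate; `(subject, gesture, session, repetition)` tuples must be unique.
#' @param root directory to write into (created if absent).
#' @return invisibly, the manifest as a data.frame (also written to
#'   `file.path(root, "manifest.tsv")`).
#' @export
write_dataset <- function(records, root) {
  if (length(records) == 0) stop("`records` is empty; nothing to write")
  fss <- vapply(records, function(r) r$fs, numeric(1))
  if (length(unique(fss)) != 1L)
    stop("all records must share one sampling rate; found: ",
         paste(unique(fss), collapse = ", "))
  keys <- vapply(records, function(r)
    .record_key(r$subject_id, r$gesture_id, r$session_id, r$repetition),
    character(1))
  dup <- duplicated(keys)
  if (any(dup))
    stop("duplicate (subject, gesture, session, repetition) tuple: ",
         keys[which(dup)[1]])
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) stop("cannot create directory: ", root)

  files <- vapply(records, function(r)
    sprintf("s%03d_g%02d_sess%d_rep%02d.txt",
            r$subject_id, r$gesture_id, r$session_id, r$repetition),
    character(1))
  for (i in seq_along(records)) {
    utils::write.table(
      t(records[[i]]$samples), file.path(root, files[i]),
      sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  manifest <- data.frame(
    file = files,
    start_index = vapply(records, function(r) r$start_index, integer(1)),
    end_index = vapply(records, function(r) r$end_index, integer(1)),
    subject_id = vapply(records, function(r) r$subject_id, integer(1)),
    gesture_id = vapply(records, function(r) r$gesture_id, integer(1)),
    session_id = vapply(records, function(r) r$session_id, integer(1)),
    repetition = vapply(records, function(r) r$repetition, integer(1)),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(root, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  attr(manifest, "fs") <- fss[1]
  # fs travels in a sidecar so the manifest stays exactly the 7 documented columns
  writeLines(as.character(fss[1]), file.path(root, "fs.txt"))
  invisible(manifest)
}

.read_signal_file <- function(path) {
  nf <- utils::count.fields(path, sep = "\t")
  bad <- which(nf != 2L)
  if (length(bad))
    stop(sprintf("signal file %s: line %d has %d columns, expected 2",
                 path, bad[1], nf[bad[1]]))
  x <- tryCatch(
    scan(path, what = double(), sep = "\t", quiet = TRUE),
    error = function(e) {
      # locate the offending line for the error message
      raw <- utils::read.table(path, sep = "\t", colClasses = "character")
      num <- suppressWarnings(matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw)))
      line <- which(apply(is.na(num), 1L, any))[1]
      stop(sprintf("signal file %s: non-numeric sample on line %d", path, line))
    })
  matrix(x, nrow = 2L)  # scan reads row-major pairs (ch1, ch2) per line
}

#' Read a plain-text sEMG dataset back into records
#'
#' @param manifest_path path to a `manifest.tsv` written by [write_dataset()]
#'   (or following the same layout).
#' @param fs sampling rate of the signal files; defaults to the value stored
#'   in the `fs.txt` sidecar next to the manifest, or 2000 Hz if absent.
#' @return list of [semg_record()]s, one per manifest row.
#' @export
read_dataset <- function(manifest_path, fs = NULL) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  manifest <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  missing_cols <- setdiff(.manifest_cols, names(manifest))
  if (length(missing_cols))
    stop("manifest ", manifest_path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  root <- dirname(manifest_path)
  if (is.null(fs)) {
    sidecar <- file.path(root, "fs.txt")
    fs <- if (file.exists(sidecar)) as.numeric(readLines(sidecar, n = 1L)) else 2000
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    path <- file.path(root, row$file)
    if (!file.exists(path))
      stop(sprintf("manifest row %d: signal file not found: %s", i, path))
    samples <- .read_signal_file(path)
    rec <- semg_record(samples, fs = fs,
                       subject_id = row$subject_id, gesture_id = row$gesture_id,
                       session_id = row$session_id, repetition = row$repetition,
                       start_index = row$start_index, end_index = row$end_index,
                       validate = FALSE)
    bad <- validate_record(rec)
    if (length(bad))
      stop(sprintf("manifest row %d (%s): %s", i, row$file,
                   paste(bad, collapse = "; ")))
    rec
  })
}
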