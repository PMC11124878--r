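#' @name auth
#' @title Enrollment, verification and access modes
#' @description
#' The access-control layer stores one template per subject: the centroid of
#' the subject's enrollment window embeddings plus a cosine-similarity
#' decision threshold. Verification embeds a probe record with the trained
#' network, averages its window embeddings, and accepts when the cosine
#' similarity to the claimed template reaches the threshold. Two access
#' modes are provided: *general* access requires the username/password
#' credential check AND the biometric check, in that order; *emergency*
#' access relies on the biometric check alone.
NULL

# Shared record -> mean-window-embedding pipeline.
.embed_record <- function(record, model, fspec = NULL, wspec = window_spec(),
                          decimation = 1L) {
  if (!is.null(fspec)) record <- preprocess_record(record, fspec)
  if (decimation > 1L) record <- decimate_record(record, decimation)
  wins <- segment_windows(record, wspec)
  if (length(wins) == 0) stop("record yields no usable windows")
  x <- array(unlist(lapply(wins, function(w) zscore_normalize(w$window))),
             c(2L, wspec$window_length, length(wins)))
  colMeans(extract_embedding(model, x))
}

#' Enroll a subject from sEMG records
#'
#' The template centroid is the arithmetic mean of the per-window embeddings
#' across all enrollment records; it is therefore invariant to enrollment
#' order. The decision threshold starts at the conservative floor -1 and is
#' normally set afterwards with [calibrate_threshold()].
#'
#' @param subject_id subject being enrolled.
#' @param records non-empty list of that subject's [semg_record()]s.
#' @param model trained `resnet1d_model`.
#' @param fspec optional [filter_spec()] applied to each record.
#' @param wspec a [window_spec()].
#' @param decimation integer decimation factor matching the training
#'   pipeline.
#' @param threshold initial cosine decision threshold in [-1, 1].
#' @return an object of class `subject_template`: list with `subject_id`,
#'   `centroid`, `n_enrolled` (window count), `threshold`.
#' @export
enroll_subject <- function(subject_id, records, model, fspec = NULL,
                           wspec = window_spec(), decimation = 1L,
                           threshold = -1) {
  if (length(records) == 0) stop("no records supplied for enrollment")
  embs <- lapply(records, .embed_record, model = model, fspec = fspec,
                 wspec = wspec, decimation = decimation)
  n_wins <- length(records)      # per-record means weighted equally
  centroid <- Reduce(`+`, embs) / length(embs)
  structure(list(subject_id = as.integer(subject_id), centroid = centroid,
                 n_enrolled = n_wins,
                 threshold = max(-1, min(1, threshold))),
            class = "subject_template")
}

#' Cosine similarity of two vectors
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return `sum(u * v) / (|u| |v|)`, in [-1, 1].
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity is undefined for zero vectors")
  sum(u * v) / (nu * nv)
}

#' Calibrate a verification threshold at the equal-error point
#'
#' Sweeps every observed score as a candidate threshold `t` (accept iff
#' score >= t), computing the false accept rate FAR(t) (impostor scores
#' >= t) and false reject rate FRR(t) (genuine scores < t), and returns the
#' candidate minimizing |FAR - FRR|, ties broken toward the lower threshold.
#' The reported EER is the mean of FAR and FRR at that operating point.
#'
#' @param genuine,impostor non-empty numeric score vectors.
#' @return list with `threshold`, `eer`, `far`, `frr`.
#' @export
calibrate_threshold <- function(genuine, impostor) {
  if (length(genuine) == 0 || length(impostor) == 0)
    stop("both genuine and impostor score lists must be non-empty")
  cand <- sort(unique(c(genuine, impostor)))
  far <- vapply(cand, function(t) mean(impostor >= t), numeric(1))
  frr <- vapply(cand, function(t) mean(genuine < t), numeric(1))
  i <- which.min(abs(far - frr))   # which.min takes the first (lowest) tie
  list(threshold = cand[i], eer = (far[i] + frr[i]) / 2,
       far = far[i], frr = frr[i])
}

.auth_decision <- function(mode, accepted, similarity = NA_real_,
                           reason = c("none", "credential", "biometric")) {
  reason <- match.arg(reason)
  stopifnot(!accepted || reason == "none")
  structure(list(mode = mode, accepted = accepted, similarity = similarity,
                 reason = reason),
            class = "auth_decision")
}

#' @export
print.auth_decision <- function(x, ...) {
  cat(sprintf("<auth_decision> mode %s: %s (similarity %s, reason %s)\n",
              x$mode, if (x$accepted) "ACCEPTED" else "REJECTED",
              ifelse(is.na(x$similarity), "-", sprintf("%.3f", x$similarity)),
              x$reason))
  invisible(x)
}

#' Biometric verification of a record against a stored template
#'
#' @param record the probe [semg_record()].
#' @param template a [enroll_subject()] template.
#' @param model trained `resnet1d_model`.
#' @inheritParams enroll_subject
#' @return an `auth_decision` (mode `"biometric"`): accepted iff the cosine
#'   similarity of the probe's mean window embedding to the template centroid
#'   reaches the template threshold.
#' @export
verify_semg <- function(record, template, model, fspec = NULL,
                        wspec = window_spec(), decimation = 1L) {
  emb <- .embed_record(record, model, fspec, wspec, decimation)
  s <- cosine_similarity(emb, template$centroid)
  ok <- s >= template$threshold
  .auth_decision("biometric", ok, s, if (ok) "none" else "biometric")
}

## ---- credential store ----

#' Create / extend a credential store
#'
#' Stores only salted SHA-256 password hashes, never plaintext.
#'
#' @param store an existing store (default: empty).
#' @return `credential_store()` returns an empty store;
#'   `add_credential()` the extended store; `check_credential()` a logical.
#' @export
credential_store <- function(store = list()) structure(store,
                                                       class = "credential_store")

#' @rdname credential_store
#' @param username,password credential pair; `add_credential` overwrites an
#'   existing username.
#' @export
add_credential <- function(store, username, password) {
  salt <- paste(as.character(openssl::rand_bytes(16)), collapse = "")
  store[[username]] <- list(
    salt = salt,
    hash = digest::digest(paste0(salt, password), algo = "sha256",
                          serialize = FALSE))
  store
}

#' @rdname credential_store
#' @export
check_credential <- function(store, username, password) {
  entry <- store[[username]]
  if (is.null(entry)) return(FALSE)
  identical(digest::digest(paste0(entry$salt, password), algo = "sha256",
                           serialize = FALSE), entry$hash)
}

#' Authenticate an access request
#'
#' General access performs the credential check and then the biometric
#' check; both must pass, and the decision reports which step failed.
#' Emergency access performs the biometric check only.
#'
#' @param mode `"general"` or `"emergency"`.
#' @param record the probe [semg_record()].
#' @param template the claimed subject's [enroll_subject()] template.
#' @param model trained `resnet1d_model`.
#' @param credentials for general access, `list(username =, password =)`.
#' @param store a [credential_store()] (general access only).
#' @inheritParams enroll_subject
#' @return an `auth_decision`.
#' @export
authenticate <- function(mode = c("general", "emergency"), record, template,
                         model, credentials = NULL, store = NULL,
                         fspec = NULL, wspec = window_spec(), decimation = 1L) {
  mode <- match.arg(mode)
  if (missing(record) || is.null(record)) stop("an sEMG record is required")
  if (mode == "general") {
    if (is.null(credentials) || is.null(credentials$username) ||
        is.null(credentials$password))
      stop("general access requires username and password credentials")
    if (is.null(store) || is.null(store[[credentials$username]]))
      stop("unknown username: ", credentials$username)
    if (!check_credential(store, credentials$username, credentials$password))
      return(.auth_decision("general", FALSE, NA_real_, "credential"))
  }
  bio <- verify_semg(record, template, model, fspec, wspec, decimation)
  .auth_decision(mode, bio$accepted, bio$similarity,
                 if (bio$accepted) "none" else "biometric")
}

#' Write / read a template store as JSON
#'
#' @param templates list of [enroll_subject()] templates.
#' @param path JSON file path.
#' @return `write_templates` returns `path` invisibly; `read_templates` the
#'   list of templates.
#' @export
write_templates <- function(templates, path) {
  payload <- lapply(templates, function(tp)
    list(subject_id = tp$subject_id, centroid = tp$centroid,
         n_enrolled = tp$n_enrolled, threshold = tp$threshold))
  names(payload) <- vapply(templates, function(tp)
    as.character(tp$subject_id), character(1))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(payload, function(tp)
    structure(list(subject_id = as.integer(tp$subject_id),
                   centroid = as.numeric(tp$centroid),
                   n_enrolled = as.integer(tp$n_enrolled),
                   threshold = as.numeric(tp$threshold)),
              class = "subject_template"))
}
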