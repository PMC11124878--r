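#' End-to-end subject identification from a set of records
#'
#' The canonical pipeline: condition every record (notch + bandpass),
#' optionally decimate, cut contraction-span windows, z-score them, split by
#' repetition into 60:20:20 train/validation/test, train the residual
#' network, and evaluate with repetition-level majority voting.
#'
#' The default network is the scaled configuration used throughout the
#' package's examples and checks: 4 residual blocks, 16 base filters,
#' pooling every other block, on 1 s windows decimated to 1000 Hz (the full
#' 5-500 Hz analysis band stays below the decimated Nyquist frequency).
#'
#' @param records list of [semg_record()]s (>= 5 repetitions per subject).
#' @param seed integer seed covering the split, weight initialization and
#'   training.
#' @param fspec a [filter_spec()].
#' @param decimation integer decimation factor (default 2).
#' @param window_length window length in decimated samples; default: the
#'   shortest contraction span after decimation.
#' @param n_blocks,base_filters,pool_every,dropout_rate network scale
#'   parameters, see [resnet_config()].
#' @param epochs,batch_size,learning_rate,patience training parameters, see
#'   [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model`, `history`, `evaluation` (repetition-level, see
#'   [evaluate()]), `splits` (record indices), `sets` (the three
#'   window sets), and the specs used.
#' @export
identify_subjects <- function(records, seed = 1L, fspec = filter_spec(),
                              decimation = 2L, window_length = NULL,
                              n_blocks = 4L, base_filters = 16L,
                              pool_every = 2L, dropout_rate = 0.3,
                              epochs = 15L, batch_size = 32L,
                              learning_rate = 1e-3, patience = 10L,
                              verbose = FALSE) {
  spans <- vapply(records, function(r) r$end_index - r$start_index, integer(1))
  if (is.null(window_length))
    window_length <- min(spans) %/% decimation
  wspec <- window_spec(window_length = window_length,
                       stride = max(1L, window_length %/% 2L))
  splits <- split_dataset(records, split_spec(seed = seed))
  sets <- lapply(splits, function(idx)
    make_window_set(records[idx], wspec, fspec = fspec, decimation = decimation))
  n_classes <- length(sets$train$classes)
  cfg <- resnet_config(n_classes = n_classes, input_length = window_length,
                       n_blocks = n_blocks, base_filters = base_filters,
                       pool_every = pool_every, dropout_rate = dropout_rate)
  model <- build_model(cfg, seed = seed)
  fit <- train_model(model, sets$train, sets$val,
                     train_config(epochs = epochs, batch_size = batch_size,
                                  learning_rate = learning_rate,
                                  patience = patience, seed = seed),
                     verbose = verbose)
  ev <- evaluate(fit$model, sets$test, aggregation = "repetition")
  list(model = fit$model, history = fit$history, evaluation = ev,
       splits = splits, sets = sets, wspec = wspec, fspec = fspec,
       decimation = decimation, config = cfg)
}

#' Genuine and impostor verification scores over a record set
#'
#' Enrolls every subject from the given enrollment records, then scores the
#' probe records against every template: scores against the matching
#' subject's template are genuine, all others impostor. Used to calibrate
#' verification thresholds at the equal-error point.
#'
#' @param enroll_records,probe_records lists of [semg_record()]s; enrollment
#'   and probe sets should be disjoint.
#' @param model trained `resnet1d_model`.
#' @param fspec,wspec,decimation the pipeline specs used in training.
#' @return list with `templates` (by subject), and a data.frame `scores`
#'   with columns `subject`, `claimed`, `score`, `genuine`.
#' @export
verification_scores <- function(enroll_records, probe_records, model,
                                fspec = NULL, wspec = window_spec(),
                                decimation = 1L) {
  subj_of <- function(rs) vapply(rs, function(r) r$subject_id, integer(1))
  es <- subj_of(enroll_records)
  templates <- lapply(sort(unique(es)), function(sid)
    enroll_subject(sid, enroll_records[es == sid], model, fspec, wspec,
                   decimation))
  names(templates) <- as.character(sort(unique(es)))
  rows <- list()
  for (rec in probe_records) {
    emb <- .embed_record(rec, model, fspec, wspec, decimation)
    for (tp in templates) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = rec$subject_id, claimed = tp$subject_id,
        score = cosine_similarity(emb, tp$centroid),
        genuine = rec$subject_id == tp$subject_id)
    }
  }
  list(templates = templates, scores = do.call(rbind, rows))
}
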