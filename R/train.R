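#' Dataset split parameters
#'
#' Splits follow the 60:20:20 train/validation/test design, stratified per
#' subject. The default splitting unit is the repetition: all windows cut
#' from one repetition land in the same partition, preventing
#' within-repetition leakage between train and test.
#'
#' @param train,val,test positive fractions summing to 1 (defaults
#'   0.6/0.2/0.2).
#' @param unit `"repetition"` (default) or `"window"`.
#' @param seed integer seed for the shuffle.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(train = 0.6, val = 0.2, test = 0.2,
                       unit = c("repetition", "window"), seed = 1L) {
  if (any(c(train, val, test) <= 0)) stop("split fractions must be positive")
  if (abs(train + val + test - 1) > 1e-9) stop("split fractions must sum to 1")
  structure(list(train = train, val = val, test = test,
                 unit = match.arg(unit), seed = as.integer(seed)),
            class = "split_spec")
}

# Largest-remainder apportionment of n units into the three fractions.
.apportion <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    order_rem <- order(exact - base, decreasing = TRUE)
    base[order_rem[seq_len(short)]] <- base[order_rem[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Split records into train/validation/test index sets
#'
#' Units (repetitions) are shuffled and apportioned within each
#' subject-by-gesture cell, so per-subject proportions stay within one unit
#' of the requested fractions and every subject appears in every partition.
#'
#' @param records list of [semg_record()]s.
#' @param spec a [split_spec()].
#' @return list of integer index vectors `train`, `val`, `test`; disjoint and
#'   exhaustive over `seq_along(records)`.
#' @export
split_dataset <- function(records, spec = split_spec()) {
  subj <- vapply(records, function(r) r$subject_id, integer(1))
  gest <- vapply(records, function(r) r$gesture_id, integer(1))
  per_subject <- table(subj)
  too_few <- per_subject < 5
  if (any(too_few))
    stop("subject(s) with fewer than 5 units: ",
         paste(names(per_subject)[too_few], collapse = ", "))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  fr <- c(spec$train, spec$val, spec$test)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cell in split(seq_along(records), interaction(subj, gest, drop = TRUE))) {
    idx <- cell[sample.int(length(cell))]
    counts <- .apportion(length(idx), fr)
    out$train <- c(out$train, idx[seq_len(counts[1])])
    out$val <- c(out$val, idx[counts[1] + seq_len(counts[2])])
    out$test <- c(out$test, idx[counts[1] + counts[2] + seq_len(counts[3])])
  }
  lapply(out, sort)
}

#' Assemble model-input windows from records
#'
#' Runs the per-record pipeline (optional filtering, optional decimation,
#' windowing, per-window per-channel z-scoring) and stacks the result into a
#' `channels x length x n_windows` array with labels, ready for
#' [train_model()] / [evaluate()].
#'
#' @param records list of [semg_record()]s.
#' @param wspec a [window_spec()] (applied after any decimation, so lengths
#'   are in decimated samples).
#' @param fspec optional [filter_spec()]; when supplied each record is
#'   filtered first.
#' @param decimation integer decimation factor (default 1 = off).
#' @param label which label becomes the class: `"subject"` (default) or
#'   `"gesture"`.
#' @return an object of class `window_set`: list with `x` (array), `y`
#'   (integer class indices), `classes` (sorted original labels), `rep_key`
#'   (character repetition identity per window).
#' @export
make_window_set <- function(records, wspec = window_spec(), fspec = NULL,
                            decimation = 1L,
                            label = c("subject", "gesture")) {
  label <- match.arg(label)
  wins <- list(); lab <- integer(0); keys <- character(0)
  for (rec in records) {
    if (!is.null(fspec)) rec <- preprocess_record(rec, fspec)
    if (decimation > 1L) rec <- decimate_record(rec, decimation)
    ws <- segment_windows(rec, wspec)
    for (w in ws) {
      wins[[length(wins) + 1L]] <- zscore_normalize(w$window)
      lab <- c(lab, if (label == "subject") w$subject_id else w$gesture_id)
      keys <- c(keys, .record_key(w$subject_id, w$gesture_id, w$session_id,
                                  w$repetition))
    }
  }
  if (length(wins) == 0) stop("no usable windows in `records`")
  classes <- sort(unique(lab))
  x <- array(unlist(wins), c(nrow(wins[[1]]), ncol(wins[[1]]), length(wins)))
  structure(list(x = x, y = match(lab, classes), classes = classes,
                 rep_key = keys), class = "window_set")
}

#' Training hyperparameters
#'
#' @param epochs maximum epochs (default 100).
#' @param batch_size mini-batch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param patience early-stopping patience on validation loss, in epochs
#'   (default 10).
#' @param seed integer seed covering shuffling, dropout and weight
#'   initialization restarts.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L, learning_rate = 1e-3,
                         patience = 10L, seed = 1L) {
  vals <- c(epochs = epochs, batch_size = batch_size,
            learning_rate = learning_rate, patience = patience)
  if (any(vals <= 0)) stop("all training hyperparameters must be positive")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

## ---- structured-parameter arithmetic for Adam ----

.map2_params <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (n in seq_along(a)) out[[n]] <- .map2_params(f, a[[n]], b[[n]])
    out
  } else if (is.numeric(a)) f(a, b) else a
}

.zeros_like <- function(p) {
  if (is.list(p)) lapply(p, .zeros_like)
  else if (is.numeric(p)) p * 0 else p
}

.adam_update <- function(params, grads, state, lr, t, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  state$m <- .map2_params(function(m, g) beta1 * m + (1 - beta1) * g,
                          state$m, grads)
  state$v <- .map2_params(function(v, g) beta2 * v + (1 - beta2) * g^2,
                          state$v, grads)
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  step <- .map2_params(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                       state$m, state$v)
  params <- .map2_params(`-`, params, step)
  list(params = params, state = state)
}

.ce_loss_grad <- function(probs, y) {
  B <- ncol(probs)
  p_true <- probs[cbind(y, seq_len(B))]
  loss <- -mean(log(pmax(p_true, 1e-12)))
  dlogits <- probs
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  list(loss = loss, dlogits = dlogits / B)
}

.predict_probs <- function(model, x, batch_size = 64L) {
  B <- dim(x)[3]
  out <- matrix(0, B, model$config$n_classes)
  for (s in seq(1L, B, by = batch_size)) {
    e <- min(s + batch_size - 1L, B)
    out[s:e, ] <- t(.forward_full(model, x[, , s:e, drop = FALSE])$probs)
  }
  out
}

#' Train the identification network
#'
#' Mini-batch Adam on categorical cross-entropy, with per-epoch training and
#' validation loss/accuracy history, early stopping on validation loss, and
#' restoration of the best-validation-loss weights. Fully reproducible given
#' the seed in `config`.
#'
#' @param model a [build_model()] result whose `n_classes` matches the label
#'   space of `train_set`.
#' @param train_set,val_set [make_window_set()] objects.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `model` (trained, eval mode) and `history` (data.frame
#'   with per-epoch `train_loss`, `train_acc`, `val_loss`, `val_acc`).
#' @export
train_model <- function(model, train_set, val_set, config = train_config(),
                        verbose = FALSE) {
  n_classes <- model$config$n_classes
  if (length(train_set$classes) < 2)
    stop("training set has a single class; identification needs >= 2")
  if (length(train_set$classes) != n_classes)
    stop(sprintf("label space (%d classes) does not match model n_classes (%d)",
                 length(train_set$classes), n_classes))
  if (dim(train_set$x)[3] == 0) stop("empty training set")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  n <- dim(train_set$x)[3]
  adam <- list(m = .zeros_like(model$params), v = .zeros_like(model$params))
  t_step <- 0L
  best <- list(loss = Inf, params = model$params, stats = model$stats, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L
    for (s in seq(1L, n, by = config$batch_size)) {
      ids <- ord[s:min(s + config$batch_size - 1L, n)]
      xb <- train_set$x[, , ids, drop = FALSE]
      yb <- train_set$y[ids]
      fw <- .forward_full(model, xb, train = TRUE, keep_cache = TRUE)
      model <- fw$model                       # BN running stats advanced
      lg <- .ce_loss_grad(fw$probs, yb)
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite training loss at epoch %d; try a lower learning rate",
                     epoch))
      grads <- .backward_full(model, fw$cache, lg$dlogits)
      t_step <- t_step + 1L
      upd <- .adam_update(model$params, grads, adam, config$learning_rate, t_step)
      model$params <- upd$params; adam <- upd$state
      ep_loss <- ep_loss + lg$loss * length(ids)
      ep_correct <- ep_correct + sum(max.col(t(fw$probs), ties.method = "first") == yb)
    }
    val_probs <- .predict_probs(model, val_set$x)
    vl <- -mean(log(pmax(val_probs[cbind(seq_len(nrow(val_probs)), val_set$y)],
                         1e-12)))
    va <- mean(max.col(val_probs, ties.method = "first") == val_set$y)
    hist <- rbind(hist, data.frame(
      epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
      val_loss = vl, val_acc = va))
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, ep_loss / n, ep_correct / n, vl, va))
    if (vl < best$loss - 1e-9)
      best <- list(loss = vl, params = model$params, stats = model$stats,
                   epoch = epoch)
    if (epoch - best$epoch >= config$patience) break
  }
  model$params <- best$params
  model$stats <- best$stats
  model$mode <- "eval"
  list(model = model, history = hist)
}
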