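#' Residual 1D network configuration
#'
#' Describes the identification network: a stack of residual blocks acting on
#' channels-x-length signal windows, followed by a classification head
#' (global average pooling, linear layer, softmax). Each block contains
#' `sub_blocks_per_block` sub-blocks applying, in order, batch
#' normalization, ReLU, dropout and a 1D convolution (pre-activation
#' arrangement); the first sub-block of a pooling block additionally halves
#' the temporal length with a MaxPool. The block's output adds a shortcut
#' copy of its input (identity when shapes match, max-pooled and/or
#' 1x1-convolved otherwise).
#'
#' With the default cadence `pool_every = 1` every block pools, which is the
#' canonical arrangement but shrinks a 2000-sample window below one sample
#' before 12 blocks complete; [build_model()] then fails fast, stating the
#' maximum feasible depth. Setting `pool_every = 2` (pool in blocks 1, 3,
#' 5, ...) makes the full 12-block network runnable on 1 s windows.
#'
#' @param n_classes number of identity classes (>= 2).
#' @param input_length window length in samples.
#' @param input_channels input channels (default 2).
#' @param n_blocks residual blocks (default 12; 0 gives a head-only model).
#' @param sub_blocks_per_block sub-blocks per block (default 2).
#' @param base_filters filters in the first block group (default 32).
#' @param filter_doubling_interval blocks between filter doublings (default 4).
#' @param kernel_size_first kernel of the network's first convolution
#'   (default 7).
#' @param kernel_size kernel of all later convolutions (default 5).
#' @param dropout_rate dropout fraction in [0, 1) (default 0.3).
#' @param pool_size MaxPool width (default 2).
#' @param pool_every pooling cadence in blocks (default 1 = every block).
#' @return an object of class `resnet_config`.
#' @export
resnet_config <- function(n_classes, input_length, input_channels = 2L,
                          n_blocks = 12L, sub_blocks_per_block = 2L,
                          base_filters = 32L, filter_doubling_interval = 4L,
                          kernel_size_first = 7L, kernel_size = 5L,
                          dropout_rate = 0.3, pool_size = 2L, pool_every = 1L) {
  if (n_classes < 2) stop("n_classes must be >= 2 for identification")
  if (n_blocks < 0) stop("n_blocks must be >= 0")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (input_length < 1) stop("input_length must be >= 1")
  if (pool_every < 1) stop("pool_every must be >= 1")
  if (kernel_size %% 2 == 0 || kernel_size_first %% 2 == 0)
    stop("kernel sizes must be odd ('same' padding)")
  structure(list(
    n_classes = as.integer(n_classes), input_length = as.integer(input_length),
    input_channels = as.integer(input_channels), n_blocks = as.integer(n_blocks),
    sub_blocks_per_block = as.integer(sub_blocks_per_block),
    base_filters = as.integer(base_filters),
    filter_doubling_interval = as.integer(filter_doubling_interval),
    kernel_size_first = as.integer(kernel_size_first),
    kernel_size = as.integer(kernel_size), dropout_rate = dropout_rate,
    pool_size = as.integer(pool_size), pool_every = as.integer(pool_every)),
    class = "resnet_config")
}

# Static per-block plan: channels in/out, kernel per sub-block, pooling flag,
# input/output lengths. Stops (naming the maximum feasible depth) when
# pooling would shrink the signal below one sample.
.block_plan <- function(config) {
  L <- config$input_length
  c_in <- config$input_channels
  plan <- vector("list", config$n_blocks)
  for (i in seq_len(config$n_blocks)) {
    pool <- ((i - 1L) %% config$pool_every) == 0L
    L_out <- if (pool) L %/% config$pool_size else L
    if (L_out < 1L) {
      max_feasible <- i - 1L
      stop(sprintf(paste0(
        "input_length %d shrinks below 1 sample at block %d ",
        "(pool %d every %d blocks); maximum feasible n_blocks is %d"),
        config$input_length, i, config$pool_size, config$pool_every,
        max_feasible))
    }
    c_out <- config$base_filters *
      2L^((i - 1L) %/% config$filter_doubling_interval)
    kernels <- rep(config$kernel_size, config$sub_blocks_per_block)
    if (i == 1L) kernels[1] <- config$kernel_size_first
    plan[[i]] <- list(c_in = c_in, c_out = c_out, kernels = kernels,
                      pool = pool, l_in = L, l_out = L_out)
    L <- L_out
    c_in <- c_out
  }
  plan
}

.he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

.init_conv <- function(f, c, k) list(W = .he_uniform(c(f, c, k), c * k),
                                     b = numeric(f))
.init_bn <- function(c) list(gamma = rep(1, c), beta = numeric(c))
.init_bn_stats <- function(c) list(mean = numeric(c), var = rep(1, c))

#' Build a residual 1D identification network
#'
#' Instantiates the layer graph of a [resnet_config()] with seeded
#' He-uniform weight initialization. Fails at build time, naming the maximum
#' feasible depth, if the pooling cadence would shrink the input below one
#' sample.
#'
#' @param config a [resnet_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `resnet1d_model` (starts in eval mode).
#' @export
build_model <- function(config, seed = 1L) {
  plan <- .block_plan(config)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  params <- list(blocks = vector("list", config$n_blocks))
  stats <- list(blocks = vector("list", config$n_blocks))
  for (i in seq_along(plan)) {
    p <- plan[[i]]
    nb <- length(p$kernels)
    bn <- vector("list", nb); conv <- vector("list", nb); bs <- vector("list", nb)
    c_prev <- p$c_in
    for (j in seq_len(nb)) {
      bn[[j]] <- .init_bn(c_prev)
      bs[[j]] <- .init_bn_stats(c_prev)
      conv[[j]] <- .init_conv(p$c_out, c_prev, p$kernels[j])
      c_prev <- p$c_out
    }
    shortcut <- if (p$c_in != p$c_out) .init_conv(p$c_out, p$c_in, 1L) else NULL
    params$blocks[[i]] <- list(bn = bn, conv = conv, shortcut = shortcut)
    stats$blocks[[i]] <- list(bn = bs)
  }
  c_head <- if (config$n_blocks > 0) plan[[config$n_blocks]]$c_out
            else config$input_channels
  params$head <- list(W = .he_uniform(c(config$n_classes, c_head), c_head),
                      b = numeric(config$n_classes))
  structure(list(config = config, params = params, stats = stats,
                 embedding_dim = c_head, mode = "eval"),
            class = "resnet1d_model")
}

## ---- primitive layers (forward + backward), batch layout [C, L, B] ----

.conv1d_fwd <- function(X, W, b) {
  d <- dim(X); C <- d[1]; L <- d[2]; B <- d[3]
  K <- dim(W)[3]; F_ <- dim(W)[1]
  pl <- (K - 1L) %/% 2L
  Xp <- array(0, c(C, L + K - 1L, B))
  Xp[, pl + seq_len(L), ] <- X
  Y <- matrix(0, F_, L * B)
  for (k in seq_len(K)) {
    Xk <- Xp[, k:(k + L - 1L), , drop = FALSE]
    dim(Xk) <- c(C, L * B)
    Y <- Y + matrix(W[, , k], F_, C) %*% Xk
  }
  Y <- Y + b
  dim(Y) <- c(F_, L, B)
  list(Y = Y, cache = list(Xp = Xp, L = L, pl = pl))
}

.conv1d_bwd <- function(dY, W, cache) {
  d <- dim(dY); F_ <- d[1]; L <- d[2]; B <- d[3]
  K <- dim(W)[3]; C <- dim(W)[2]
  dYm <- dY; dim(dYm) <- c(F_, L * B)
  db <- rowSums(dYm)
  dW <- array(0, dim(W))
  dXp <- array(0, dim(cache$Xp))
  for (k in seq_len(K)) {
    Xk <- cache$Xp[, k:(k + L - 1L), , drop = FALSE]
    dim(Xk) <- c(C, L * B)
    dW[, , k] <- dYm %*% t(Xk)
    dXk <- crossprod(matrix(W[, , k], F_, C), dYm)
    dim(dXk) <- c(C, L, B)
    dXp[, k:(k + L - 1L), ] <- dXp[, k:(k + L - 1L), , drop = FALSE] + dXk
  }
  dX <- dXp[, cache$pl + seq_len(L), , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

.bn_fwd <- function(X, bn, st, train, momentum = 0.9, eps = 1e-5) {
  d <- dim(X); N <- d[2] * d[3]
  Xm <- X; dim(Xm) <- c(d[1], N)
  if (train) {
    m <- rowMeans(Xm)
    v <- rowMeans((Xm - m)^2)
    st$mean <- momentum * st$mean + (1 - momentum) * m
    st$var <- momentum * st$var + (1 - momentum) * v
  } else {
    m <- st$mean; v <- st$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (Xm - m) * inv
  Y <- bn$gamma * xhat + bn$beta
  dim(Y) <- d
  list(Y = Y, st = st, cache = list(xhat = xhat, inv = inv, gamma = bn$gamma,
                                    dims = d, train = train))
}

.bn_bwd <- function(dY, cache) {
  d <- cache$dims; N <- d[2] * d[3]
  dYm <- dY; dim(dYm) <- c(d[1], N)
  dgamma <- rowSums(dYm * cache$xhat)
  dbeta <- rowSums(dYm)
  dxhat <- dYm * cache$gamma
  if (cache$train) {
    dX <- (cache$inv / N) *
      (N * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  } else {
    dX <- dxhat * cache$inv
  }
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

.relu_fwd <- function(X) {
  mask <- X > 0
  X[!mask] <- 0
  list(Y = X, cache = mask)
}

.dropout_fwd <- function(X, rate, train) {
  if (!train || rate == 0) return(list(Y = X, cache = NULL))
  keep <- array(stats::runif(length(X)) >= rate, dim(X)) / (1 - rate)
  list(Y = X * keep, cache = keep)
}

.maxpool_fwd <- function(X, size = 2L) {
  d <- dim(X); L <- d[2]; Lp <- L %/% size
  idx <- lapply(seq_len(size), function(s) seq.int(s, by = size, length.out = Lp))
  slabs <- lapply(idx, function(ii) X[, ii, , drop = FALSE])
  Y <- slabs[[1]]; which_max <- array(1L, dim(Y))
  for (s in seq_len(size)[-1]) {
    better <- slabs[[s]] > Y
    Y[better] <- slabs[[s]][better]
    which_max[better] <- s
  }
  list(Y = Y, cache = list(which_max = which_max, idx = idx, dims = d))
}

.maxpool_bwd <- function(dY, cache) {
  dX <- array(0, cache$dims)
  for (s in seq_along(cache$idx)) {
    sel <- cache$which_max == s
    slab <- array(0, dim(dY))
    slab[sel] <- dY[sel]
    dX[, cache$idx[[s]], ] <- slab
  }
  dX
}

.gap_fwd <- function(X) {
  d <- dim(X)
  Y <- colSums(aperm(X, c(2, 1, 3))) / d[2]   # [C, B]
  list(Y = Y, cache = d)
}

.gap_bwd <- function(dY, dims) {
  tmp <- array(rep(as.numeric(dY), each = dims[2]), c(dims[2], dims[1], dims[3]))
  aperm(tmp, c(2, 1, 3)) / dims[2]
}

.softmax_cols <- function(logits) {
  z <- exp(sweep(logits, 2L, apply(logits, 2L, max)))
  sweep(z, 2L, colSums(z), "/")
}

## ---- full forward / backward over the residual graph ----

.forward_full <- function(model, X, train = FALSE, keep_cache = FALSE) {
  config <- model$config
  plan <- if (config$n_blocks > 0) .block_plan(config) else list()
  caches <- if (keep_cache) vector("list", config$n_blocks) else NULL
  for (i in seq_along(plan)) {
    p <- plan[[i]]
    bp <- model$params$blocks[[i]]
    bs <- model$stats$blocks[[i]]
    cb <- list(sub = vector("list", length(p$kernels)))
    X_in <- X
    out <- X
    for (j in seq_along(p$kernels)) {
      cs <- list()
      r1 <- .bn_fwd(out, bp$bn[[j]], bs$bn[[j]], train)
      bs$bn[[j]] <- r1$st; cs$bn <- r1$cache
      r2 <- .relu_fwd(r1$Y); cs$relu <- r2$cache
      r3 <- .dropout_fwd(r2$Y, config$dropout_rate, train); cs$drop <- r3$cache
      r4 <- .conv1d_fwd(r3$Y, bp$conv[[j]]$W, bp$conv[[j]]$b); cs$conv <- r4$cache
      out <- r4$Y
      if (j == 1L && p$pool) {
        r5 <- .maxpool_fwd(out, config$pool_size); cs$pool <- r5$cache
        out <- r5$Y
      }
      cb$sub[[j]] <- cs
    }
    short <- X_in
    if (p$pool) {
      r6 <- .maxpool_fwd(short, config$pool_size)
      cb$short_pool <- r6$cache
      short <- r6$Y
    }
    if (!is.null(bp$shortcut)) {
      r7 <- .conv1d_fwd(short, bp$shortcut$W, bp$shortcut$b)
      cb$short_conv <- r7$cache
      short <- r7$Y
    }
    X <- out + short
    model$stats$blocks[[i]] <- bs
    if (keep_cache) caches[[i]] <- cb
  }
  g <- .gap_fwd(X)
  emb <- g$Y                                   # [C, B]
  logits <- model$params$head$W %*% emb + model$params$head$b
  probs <- .softmax_cols(logits)
  list(probs = probs, emb = emb, logits = logits, model = model,
       cache = list(blocks = caches, gap = g$cache, emb = emb, plan = plan))
}

.backward_full <- function(model, cache, dlogits) {
  config <- model$config
  grads <- list(blocks = vector("list", config$n_blocks))
  grads$head <- list(W = dlogits %*% t(cache$emb), b = rowSums(dlogits))
  dEmb <- crossprod(model$params$head$W, dlogits)
  dX <- .gap_bwd(dEmb, cache$gap)
  for (i in rev(seq_len(config$n_blocks))) {
    p <- cache$plan[[i]]
    bp <- model$params$blocks[[i]]
    cb <- cache$blocks[[i]]
    g <- list(bn = vector("list", length(p$kernels)),
              conv = vector("list", length(p$kernels)), shortcut = NULL)
    # shortcut branch
    dShort <- dX
    if (!is.null(bp$shortcut)) {
      r <- .conv1d_bwd(dShort, bp$shortcut$W, cb$short_conv)
      g$shortcut <- list(W = r$dW, b = r$db)
      dShort <- r$dX
    }
    if (p$pool) dShort <- .maxpool_bwd(dShort, cb$short_pool)
    # transform branch
    dOut <- dX
    for (j in rev(seq_along(p$kernels))) {
      cs <- cb$sub[[j]]
      if (j == 1L && p$pool) dOut <- .maxpool_bwd(dOut, cs$pool)
      r <- .conv1d_bwd(dOut, bp$conv[[j]]$W, cs$conv)
      g$conv[[j]] <- list(W = r$dW, b = r$db)
      dOut <- r$dX
      if (!is.null(cs$drop)) dOut <- dOut * cs$drop
      dOut[!cs$relu] <- 0
      rb <- .bn_bwd(dOut, cs$bn)
      g$bn[[j]] <- list(gamma = rb$dgamma, beta = rb$dbeta)
      dOut <- rb$dX
    }
    dX <- dOut + dShort
    grads$blocks[[i]] <- g
  }
  grads
}

.as_batch <- function(batch, config) {
  if (is.matrix(batch)) {
    batch <- array(batch, c(dim(batch), 1L))
  }
  d <- dim(batch)
  if (length(d) != 3L || d[1] != config$input_channels || d[2] != config$input_length)
    stop(sprintf("expected windows of %d x %d (channels x samples), received %s",
                 config$input_channels, config$input_length,
                 paste(d, collapse = " x ")))
  batch
}

#' Forward pass: class probabilities for a batch of windows
#'
#' Deterministic in eval mode (the default for a built or trained model):
#' dropout is disabled and batch normalization uses its running statistics.
#'
#' @param model a [build_model()] result (possibly trained).
#' @param batch a `channels x length x batch` array, or a single
#'   `channels x length` matrix.
#' @return a `batch x n_classes` matrix of probabilities (rows sum to 1).
#' @export
forward <- function(model, batch) {
  X <- .as_batch(batch, model$config)
  t(.forward_full(model, X, train = FALSE)$probs)
}

#' Embeddings for a batch of windows
#'
#' Returns the post-global-average-pool, pre-head activations: the feature
#' vector the verification layer compares against stored templates.
#'
#' @inheritParams forward
#' @return a `batch x embedding_dim` matrix.
#' @export
extract_embedding <- function(model, batch) {
  X <- .as_batch(batch, model$config)
  t(.forward_full(model, X, train = FALSE)$emb)
}

#' Count trainable parameters
#'
#' @param model a `resnet1d_model`.
#' @return integer total of trainable scalars (convolution and head weights
#'   and biases, batch-norm scales and shifts; running statistics excluded).
#' @export
count_parameters <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else if (is.numeric(x)) n <<- n + length(x)
    invisible(NULL)
  }
  walk(model$params)
  n
}

#' @export
print.resnet1d_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<resnet1d_model> %d residual block(s), %d classes, input %d x %d\n",
    cfg$n_blocks, cfg$n_classes, cfg$input_channels, cfg$input_length))
  cat(sprintf("  embedding dim %d; %d trainable parameters; mode: %s\n",
              x$embedding_dim, count_parameters(x), x$mode))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file serialized weights plus the exact configuration used, with the
#' configuration mirrored as structured JSON text in the attribute
#' `config_json` for portability.
#'
#' @param model a `resnet1d_model`.
#' @param path checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  attr(model, "config_json") <-
    jsonlite::toJSON(unclass(model$config), auto_unbox = TRUE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
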