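test_that("build-time length propagation rejects infeasible pooling cadences", {
  cfg_full <- resnet_config(n_classes = 5, input_length = 2000)
  expect_error(build_model(cfg_full), "maximum feasible n_blocks is 10")
  # the documented fallback cadence makes the printed 12-block depth runnable
  cfg_ok <- resnet_config(n_classes = 5, input_length = 2000, pool_every = 2)
  m <- build_model(cfg_ok, seed = 1)
  expect_s3_class(m, "resnet1d_model")
  expect_length(m$params$blocks, 12)
})

test_that("a head-only model maps any window straight to class probabilities", {
  cfg <- resnet_config(n_classes = 4, input_length = 50, n_blocks = 0)
  m <- build_model(cfg, seed = 2)
  p <- forward(m, matrix(rnorm(100), 2, 50))
  expect_equal(dim(p), c(1L, 4L))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_equal(m$embedding_dim, 2L)
  # head-only parameter count: dense W (4 x 2) + bias (4)
  expect_identical(count_parameters(m), 12L)
})

test_that("parameter count matches the hand-computed closed form for a tiny config", {
  cfg <- resnet_config(n_classes = 2, input_length = 16, input_channels = 2,
                       n_blocks = 1, base_filters = 4, kernel_size_first = 3,
                       kernel_size = 3)
  m <- build_model(cfg, seed = 3)
  # independent closed form: conv = F*C*K + F; bn = 2C; dense = K*C + K
  bn1 <- 2 * 2; conv1 <- 4 * 2 * 3 + 4
  bn2 <- 2 * 4; conv2 <- 4 * 4 * 3 + 4
  shortcut <- 4 * 2 * 1 + 4
  head <- 2 * 4 + 2
  expect_identical(count_parameters(m),
                   as.integer(bn1 + conv1 + bn2 + conv2 + shortcut + head))
  # widening strictly increases the count
  cfg_wide <- resnet_config(n_classes = 2, input_length = 16, n_blocks = 1,
                            base_filters = 8, kernel_size_first = 3,
                            kernel_size = 3)
  expect_gt(count_parameters(build_model(cfg_wide)), count_parameters(m))
})

test_that("eval-mode forward is a deterministic, normalized, batch-equivariant map", {
  cfg <- resnet_config(n_classes = 3, input_length = 64, n_blocks = 2,
                       base_filters = 4, kernel_size_first = 3, kernel_size = 3)
  m <- build_model(cfg, seed = 4)
  set.seed(10)
  x <- array(rnorm(2 * 64 * 6), c(2, 64, 6))
  p1 <- forward(m, x)
  expect_equal(rowSums(p1), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  expect_identical(p1, forward(m, x))                  # determinism
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(forward(m, x[, , perm]), p1[perm, ], tolerance = 1e-12)
  expect_error(forward(m, array(rnorm(2 * 32 * 2), c(2, 32, 2))), "expected windows")
})

test_that("embeddings are repeatable, sized by the head width, and input-sensitive", {
  cfg <- resnet_config(n_classes = 3, input_length = 64, n_blocks = 2,
                       base_filters = 4, kernel_size_first = 3, kernel_size = 3)
  m <- build_model(cfg, seed = 5)
  set.seed(11)
  x <- array(rnorm(2 * 64 * 2), c(2, 64, 2))
  e1 <- extract_embedding(m, x)
  expect_identical(e1, extract_embedding(m, x))
  expect_equal(dim(e1), c(2L, m$embedding_dim))
  expect_gt(sqrt(sum((e1[1, ] - e1[2, ])^2)), 0)
})

test_that("zeroing the transform branch's final convolution leaves only the shortcut", {
  cfg <- resnet_config(n_classes = 2, input_length = 32, n_blocks = 2,
                       base_filters = 4, kernel_size_first = 3, kernel_size = 3,
                       dropout_rate = 0)
  m <- build_model(cfg, seed = 6)
  for (i in seq_along(m$params$blocks)) {
    m$params$blocks[[i]]$conv[[2]]$W[] <- 0
    m$params$blocks[[i]]$conv[[2]]$b[] <- 0
  }
  set.seed(12)
  x <- array(rnorm(2 * 32 * 3), c(2, 32, 3))
  out <- semgid:::.forward_full(m, x, train = FALSE)
  # independent composition of the shortcut path only:
  # block 1 pools then projects 2->4 channels; block 2 pools (identity channels)
  s <- semgid:::.maxpool_fwd(x, 2L)$Y
  s <- semgid:::.conv1d_fwd(s, m$params$blocks[[1]]$shortcut$W,
                            m$params$blocks[[1]]$shortcut$b)$Y
  s <- semgid:::.maxpool_fwd(s, 2L)$Y
  emb_expected <- colSums(aperm(s, c(2, 1, 3))) / dim(s)[2]
  expect_equal(out$emb, emb_expected, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences through the full graph", {
  cfg <- resnet_config(n_classes = 3, input_length = 16, n_blocks = 2,
                       base_filters = 4, kernel_size_first = 3, kernel_size = 3,
                       dropout_rate = 0)
  m <- build_model(cfg, seed = 7)
  set.seed(13)
  x <- array(rnorm(2 * 16 * 4), c(2, 16, 4)); y <- c(1L, 2L, 3L, 1L)
  fw <- semgid:::.forward_full(m, x, train = TRUE, keep_cache = TRUE)
  lg <- semgid:::.ce_loss_grad(fw$probs, y)
  gr <- semgid:::.backward_full(m, fw$cache, lg$dlogits)
  loss_of <- function(mm)
    semgid:::.ce_loss_grad(semgid:::.forward_full(mm, x, train = TRUE)$probs, y)$loss
  eps <- 1e-5
  probes <- list(
    list(get = function(m) m$params$blocks[[1]]$conv[[1]]$W,
         set = function(m, w) { m$params$blocks[[1]]$conv[[1]]$W[] <- w; m },
         grad = gr$blocks[[1]]$conv[[1]]$W),
    list(get = function(m) m$params$blocks[[2]]$bn[[1]]$gamma,
         set = function(m, w) { m$params$blocks[[2]]$bn[[1]]$gamma[] <- w; m },
         grad = gr$blocks[[2]]$bn[[1]]$gamma),
    list(get = function(m) m$params$head$W,
         set = function(m, w) { m$params$head$W[] <- w; m },
         grad = gr$head$W))
  for (pr in probes) {
    w <- pr$get(m)
    for (k in c(1L, length(w))) {
      wp <- w; wp[k] <- wp[k] + eps
      wm <- w; wm[k] <- wm[k] - eps
      num <- (loss_of(pr$set(m, wp)) - loss_of(pr$set(m, wm))) / (2 * eps)
      expect_equal(pr$grad[k], num, tolerance = 1e-5)
    }
  }
})

test_that("a small network learns a separable two-class problem quickly", {
  # class 0: low-frequency sine windows; class 1: high-frequency
  set.seed(20)
  n_per <- 30L; L <- 64L
  mk <- function(freq) {
    t(replicate(n_per, {
      ph <- runif(2, 0, 2 * pi)
      as.numeric(rbind(sin(2 * pi * freq * (1:L) / L + ph[1]) + rnorm(L, sd = .2),
                       sin(2 * pi * freq * (1:L) / L + ph[2]) + rnorm(L, sd = .2)))
    }))
  }
  xmat <- rbind(mk(2), mk(11))
  x <- array(t(xmat), c(2, L, 2 * n_per))
  y <- rep(1:2, each = n_per)
  idx_tr <- c(1:20, 31:50); idx_va <- setdiff(1:60, idx_tr)
  set_of <- function(idx) structure(list(
    x = x[, , idx, drop = FALSE], y = y[idx], classes = 1:2,
    rep_key = as.character(idx)), class = "window_set")
  cfg <- resnet_config(n_classes = 2, input_length = L, n_blocks = 2,
                       base_filters = 4, kernel_size_first = 5, kernel_size = 3,
                       dropout_rate = 0.1)
  fit <- train_model(build_model(cfg, seed = 8), set_of(idx_tr), set_of(idx_va),
                     train_config(epochs = 30, batch_size = 16, seed = 8))
  expect_gte(max(fit$history$train_acc), 0.95)
  expect_lte(nrow(fit$history), 30)
})
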