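test_that("separable convolution reproduces identity and summation kernels", {
  set.seed(61)
  x <- matrix(runif(25), 5, 5)
  idk <- matrix(0, 3, 3); idk[2, 2] <- 1
  out <- depthwise_separable_conv(x, idk, matrix(1, 1, 1))
  expect_equal(out[, , 1], x)
  ones <- depthwise_separable_conv(matrix(1:9 / 9, 3, 3), matrix(1, 3, 3),
                                   matrix(1, 1, 1))
  expect_equal(ones[2, 2, 1], sum(1:9 / 9))
  expect_error(depthwise_separable_conv(array(runif(18), c(3, 3, 2)),
                                        idk, matrix(1, 1, 1)), "channel")
  # parameter budget: K*k^2 + K*L < K*L*k^2 whenever L > 1, k > 1
  K <- 4; L <- 8; k <- 3
  expect_lt(K * k^2 + K * L, K * L * k^2)
})

test_that("CBAM attenuates with channel and spatial attention in (0,1)", {
  set.seed(62)
  x <- array(runif(8 * 8 * 4), c(8, 8, 4))
  res <- cbam(x, seed = 3)
  expect_true(all(res$Mc > 0 & res$Mc < 1))
  expect_true(all(res$Ms > 0 & res$Ms < 1))
  expect_true(all(abs(res$output) <= abs(x)))
  # zero weights: Mc = Ms = sigmoid(0) = 0.5, output = x/4
  zw <- fasftle:::cbam_init(4, seed = 1)
  zw <- lapply(zw, function(w) w * 0)
  rz <- cbam(x, weights = zw)
  expect_equal(rz$output, 0.25 * x, tolerance = 1e-12)
})

test_that("BiLSTM attention weights are a proper convex pooling", {
  set.seed(63)
  s <- matrix(rnorm(20), 5, 4)
  r <- bilstm_attention(s, hidden = 3, seed = 2)
  expect_equal(sum(r$weights), 1, tolerance = 1e-6)
  expect_equal(dim(r$context), c(1, 6))
  # T = 1: all attention on the single step, context = its state
  r1 <- bilstm_attention(s[1, , drop = FALSE], hidden = 3, seed = 2)
  expect_equal(r1$weights, 1)
  expect_equal(r1$context, r1$states)
  # symmetry of the pooling: identical hidden states draw uniform weights
  # (the LSTM's own state transient makes full-path states differ, so the
  # property is asserted at the attention stage where it actually holds)
  set.seed(2)
  aw <- lapply(fasftle:::attn_init(6, 3), fasftle:::ad_leaf)
  H <- matrix(rep(rnorm(6), each = 5), 5, 6)
  pool <- fasftle:::nn_attention_pool(fasftle:::ad_leaf(H), aw)
  expect_equal(as.numeric(fasftle:::ad_val(pool$alpha)), rep(0.2, 5),
               tolerance = 1e-9)
  expect_error(bilstm_attention(s[0, , drop = FALSE]), "empty")
})

test_that("positional encoding matches the sinusoidal formula", {
  pe <- positional_encoding(6, 8)
  expect_equal(pe[1, ], rep(c(0, 1), 4))      # sin(0), cos(0) interleaved
  expect_true(all(pe >= -1 & pe <= 1))
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12)
  expect_equal(pe[2, 3], sin(1 / 10000^(2 / 8)), tolerance = 1e-12)
  expect_error(positional_encoding(4, 5), "even")
})

test_that("multi-head attention rows are convex and split identical keys", {
  set.seed(64)
  X <- matrix(rnorm(12), 3, 4)
  r <- multi_head_attention(X, X, X, heads = 2)
  for (A in r$attention) {
    expect_equal(rowSums(A), rep(1, 3), tolerance = 1e-9)
  }
  # two identical keys with identity projections share the weight equally
  K <- matrix(rep(c(1, 0, 0, 0), each = 2), 2, 4)
  q <- matrix(c(1, 0, 0, 0), 1, 4)
  r2 <- multi_head_attention(q, K, K, heads = 1)
  expect_equal(as.vector(r2$attention[[1]]), c(0.5, 0.5))
  # T = 1: the attention matrix is exactly [[1]]
  r3 <- multi_head_attention(q, q, q, heads = 2)
  expect_equal(unlist(r3$attention), c(1, 1))
  expect_error(multi_head_attention(X, X, X, heads = 3), "divisible")
})

test_that("transformer block preserves shape and normalises rows", {
  set.seed(65)
  X <- matrix(rnorm(24), 4, 6)
  out <- transformer_block(X, heads = 2, ffn_hidden = 10, seed = 4)
  expect_equal(dim(out), dim(X))
  out2 <- transformer_block(X, heads = 2, ffn_hidden = 10, seed = 4)
  expect_identical(out, out2)  # deterministic without dropout
  # with unit gain / zero shift, each row is standardised pre-affine
  w <- fasftle:::transformer_init(6, 10)
  o <- transformer_block(X, heads = 2, ffn_hidden = 10, weights = w)
  expect_equal(rowMeans(o), rep(0, 4), tolerance = 1e-6)
  expect_equal(apply(o, 1, stats::sd) * sqrt(5 / 6), rep(1, 4),
               tolerance = 1e-3)
})

test_that("forward pass yields proper probabilities, symmetric in classes", {
  set.seed(66)
  cfg <- haetn_config(conv_filters = 4, lstm_hidden = 4, attn_heads = 2,
                      ffn_hidden = 8, dense_units = 6, seed = 66)
  m <- haetn_new(cfg, c(12, 12, 3), seed = 66)
  x <- array(runif(12 * 12 * 3), c(12, 12, 3))
  p <- haetn_forward(m, x)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, haetn_forward(m, x))  # eval-mode determinism
  # permuting the output head permutes the probabilities identically
  m2 <- m
  m2$params$out$W <- m$params$out$W[, 2:1]
  m2$params$out$b <- m$params$out$b[2:1]
  expect_equal(haetn_forward(m2, x), p[2:1], tolerance = 1e-12)
  expect_error(haetn_forward(m, array(0, c(9, 9, 3))), "slice size")
})

test_that("training separates the planted-blob dataset and is bit-identical", {
  ds <- make_slice_dataset(n_per_class = 10, shape = c(12, 12, 3), seed = 2)
  cfg <- haetn_config(conv_filters = 4, lstm_hidden = 6, attn_heads = 2,
                      ffn_hidden = 12, dense_units = 6, epochs = 8,
                      batch_size = 5, seed = 8)
  m <- train_haetn(ds, cfg, val_fraction = 0)
  expect_equal(nrow(m$history), 8)
  expect_true(all(is.finite(m$history$loss)))
  expect_gte(max(m$history$accuracy), 0.9)
  m2 <- train_haetn(ds, cfg, val_fraction = 0)
  expect_identical(m$params, m2$params)
  one <- list(x = ds$x[1:3], y = c(0L, 0L, 0L))
  expect_error(train_haetn(one, cfg), "2 classes")
})

test_that("checkpoints restore bit-identical outputs", {
  dir <- withr::local_tempdir()
  ds <- make_slice_dataset(n_per_class = 5, shape = c(12, 12, 3), seed = 4)
  cfg <- haetn_config(conv_filters = 4, lstm_hidden = 4, attn_heads = 2,
                      ffn_hidden = 8, dense_units = 4, epochs = 2,
                      batch_size = 5, seed = 4)
  m <- train_haetn(ds, cfg, val_fraction = 0)
  p <- file.path(dir, "model.ckpt")
  save_haetn(m, p)
  back <- load_haetn(p)
  expect_identical(haetn_forward(back, ds$x[[1]]),
                   haetn_forward(m, ds$x[[1]]))
})

test_that("grad-cam maps live in [0,1] and degrade gracefully on zeros", {
  ds <- make_slice_dataset(n_per_class = 5, shape = c(12, 12, 3), seed = 6)
  cfg <- haetn_config(conv_filters = 4, lstm_hidden = 4, attn_heads = 2,
                      ffn_hidden = 8, dense_units = 4, epochs = 2,
                      batch_size = 5, seed = 6)
  m <- train_haetn(ds, cfg, val_fraction = 0)
  hm <- suppressWarnings(gradcam_map(m, ds$x[[6]], target_class = 2))
  expect_equal(dim(hm), c(12, 12, 3))
  expect_true(all(hm >= 0 & hm <= 1))
  expect_error(gradcam_map(m, ds$x[[6]], target_class = 5), "out of range")
  # a constant head makes every logit gradient vanish: the all-zero map is
  # returned as zeros with a warning
  mz <- m
  mz$params$out$W[] <- 0
  mz$params$out$b[] <- 0
  expect_warning(hz <- gradcam_map(mz, ds$x[[6]], target_class = 2),
                 "zero saliency")
  expect_true(all(hz == 0))
  dir <- withr::local_tempdir()
  f <- gradcam_overlay(ds$x[[6]][, , 2], hm[, , 2],
                       file.path(dir, "heat.png"))
  expect_true(file.exists(f))
})

test_that("feature-sequence mode trains on tabular rows", {
  tbl <- make_feature_dataset(n_per_class = 10, n_informative = 2,
                              n_noise = 2, effect_size = 4, seed = 9)
  X <- ft_values(tbl)
  xs <- lapply(seq_len(nrow(X)), function(i) matrix(X[i, ], nrow = 1))
  cfg <- haetn_config(conv_filters = 4, lstm_hidden = 4, attn_heads = 2,
                      ffn_hidden = 8, dense_units = 4, epochs = 10,
                      batch_size = 5, input_mode = "feature_sequence",
                      seed = 9)
  m <- train_haetn(list(x = xs, y = ft_labels(tbl)), cfg, val_fraction = 0)
  expect_gte(max(m$history$accuracy), 0.9)
  pr <- predict_haetn(m, xs)
  expect_equal(rowSums(pr), rep(1, 20), tolerance = 1e-6)
})
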