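# The network layers run on the package's reverse-mode autodiff tape; these
# tests pin the engine against central finite differences so every layer's
# backward pass is verified independently of the training loop.

num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

grad_of <- function(build, x) {
  fasftle:::ad_begin()
  leaf <- fasftle:::ad_leaf(x)
  loss <- build(leaf)
  fasftle:::ad_backward(loss)
  g <- leaf$grad
  fasftle:::ad_end()
  g
}

val_of <- function(build, x) {
  fasftle:::ad_begin()
  v <- fasftle:::ad_val(build(fasftle:::ad_leaf(x)))
  fasftle:::ad_end()
  v
}

test_that("matrix, softmax and normalisation ops backpropagate exactly", {
  set.seed(51)
  ad <- asNamespace("fasftle")
  W <- matrix(rnorm(12), 4, 3)
  M1 <- matrix(rnorm(8), 2, 4)
  M2 <- matrix(rnorm(8), 2, 4)
  builds <- list(
    matmul = function(x) ad$ad_sum(ad$ad_tanh(ad$ad_matmul(x,
      ad$ad_leaf(W)))),
    softmax = function(x) ad$ad_sum(ad$ad_mul(ad$ad_softmax_rows(x),
      ad$ad_leaf(M1))),
    layernorm = function(x) ad$ad_sum(ad$ad_mul(
      ad$ad_layernorm_rows(x, ad$ad_leaf(rep(1.2, 4)),
                           ad$ad_leaf(rep(0.1, 4))),
      ad$ad_leaf(M2))),
    sigmoid_mix = function(x) ad$ad_sum(ad$ad_mul(ad$ad_sigmoid(x),
      ad$ad_relu(x)))
  )
  for (nm in names(builds)) {
    x <- matrix(rnorm(8), 2, 4)
    ana <- grad_of(builds[[nm]], x)
    num <- num_grad(function(z) val_of(builds[[nm]], z), x)
    expect_equal(ana, num, tolerance = 1e-6, label = nm)
  }
})

test_that("convolution and pooling ops backpropagate exactly", {
  set.seed(52)
  ad <- asNamespace("fasftle")
  dw <- array(rnorm(9 * 2), c(3, 3, 2))
  pw <- matrix(rnorm(2 * 3), 2, 3)
  pb <- rnorm(3)
  wsp <- array(rnorm(9 * 2), c(3, 3, 2))
  CW <- matrix(rnorm(2), 1, 2)
  SP <- matrix(rnorm(16), 4, 4)
  builds <- list(
    depthwise = function(x) ad$ad_sum(ad$ad_conv_dw(x, ad$ad_leaf(dw))),
    pointwise = function(x) ad$ad_sum(ad$ad_conv_pw(x, ad$ad_leaf(pw),
      ad$ad_leaf(pb))),
    flatconv = function(x) ad$ad_sum(ad$ad_conv_flat(x, ad$ad_leaf(wsp),
      ad$ad_leaf(0.2))),
    maxpool = function(x) ad$ad_sum(ad$ad_maxpool(x, 2)),
    pools = function(x) ad$ad_sum(ad$ad_concat_cols(list(ad$ad_gap(x),
      ad$ad_gmp(x)))),
    chan = function(x) ad$ad_sum(ad$ad_mul_spatial(
      ad$ad_mul_channel(x, ad$ad_leaf(CW)), ad$ad_leaf(SP)))
  )
  for (nm in names(builds)) {
    x <- array(rnorm(32), c(4, 4, 2))
    ana <- grad_of(builds[[nm]], x)
    num <- num_grad(function(z) val_of(builds[[nm]], z), x)
    expect_equal(ana, num, tolerance = 1e-6, label = nm)
  }
})

test_that("full model gradients match finite differences per block", {
  set.seed(53)
  ad <- asNamespace("fasftle")
  cfg <- haetn_config(conv_filters = 4, lstm_hidden = 4, attn_heads = 2,
                      ffn_hidden = 6, dense_units = 5,
                      transformer_dropout = 0, dense_dropout = 0, seed = 53)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  set.seed(53)
  params <- ad$haetn_init_params(cfg, c(8, 8, 3))
  run <- function(params) {
    ad$ad_begin()
    P <- ad$wrap_leaves(params)
    loss <- ad$ad_cross_entropy(
      ad$haetn_forward_nodes(P, cfg, x)$logits, 2L)
    ad$ad_backward(loss)
    out <- list(loss = ad$ad_val(loss), grads = ad$collect_grads(P))
    ad$ad_end()
    out
  }
  base <- run(params)
  getp <- function(pp, path) { for (k in path) pp <- pp[[k]]; pp }
  setp <- function(pp, path, val) {
    if (length(path) == 1) { pp[[path]] <- val; return(pp) }
    pp[[path[1]]] <- setp(pp[[path[1]]], path[-1], val)
    pp
  }
  blocks <- c("conv.dw", "cbam.W1", "cbam.w_sp", "lstm.fwd.Wx",
              "lstm.bwd.Wh", "attn.Wa", "transformer.mha.Wq",
              "transformer.W1", "transformer.ln_g", "emb_ln.g",
              "dense.W", "out.b")
  eps <- 1e-6
  for (b in blocks) {
    path <- strsplit(b, ".", fixed = TRUE)[[1]]
    v0 <- getp(params, path)
    idx <- length(v0)  # last entry of each block
    va <- v0; va[idx] <- va[idx] + eps
    vb <- v0; vb[idx] <- vb[idx] - eps
    num <- (run(setp(params, path, va))$loss -
              run(setp(params, path, vb))$loss) / (2 * eps)
    ana <- getp(base$grads, path)[idx]
    expect_equal(ana, num, tolerance = 1e-5, label = b)
  }
})
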