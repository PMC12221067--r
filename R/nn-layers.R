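# Building blocks of the attention network. The nn_* internals operate on
# autodiff nodes and parameter lists of leaves; the exported functions wrap
# them for plain numeric inputs so each block can be used and tested on its
# own.

wrap_leaves <- function(x) {
  if (is.list(x)) lapply(x, wrap_leaves) else ad_leaf(x)
}

glorot <- function(nin, nout) {
  matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

# ---- separable convolution ----------------------------------------------

nn_sepconv <- function(x, P) {
  ad_conv_pw(ad_conv_dw(x, P$dw), P$pw, P$pw_b)
}

#' Depthwise separable convolution
#'
#' A per-channel spatial convolution (each input channel filtered by its own
#' k x k kernel, same padding) followed by a 1 x 1 pointwise convolution
#' mixing channels. Parameter count is K*k^2 + K*L, against K*L*k^2 for a
#' full convolution.
#'
#' @param x H x W x K numeric array (a matrix is treated as H x W x 1).
#' @param depth_kernel k x k x K array of per-channel kernels (k odd).
#' @param point_weights K x L matrix of channel-mixing weights.
#' @param point_bias length-L bias (default zeros).
#' @return H x W x L array.
#' @export
depthwise_separable_conv <- function(x, depth_kernel, point_weights,
                                     point_bias = NULL) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  if (is.matrix(depth_kernel)) {
    depth_kernel <- array(depth_kernel, c(dim(depth_kernel), 1))
  }
  point_weights <- as.matrix(point_weights)
  if (dim(depth_kernel)[3] != dim(x)[3] ||
      nrow(point_weights) != dim(x)[3]) {
    stop("depthwise_separable_conv: channel mismatch")
  }
  if (is.null(point_bias)) point_bias <- numeric(ncol(point_weights))
  P <- list(dw = ad_leaf(depth_kernel), pw = ad_leaf(point_weights),
            pw_b = ad_leaf(point_bias))
  ad_val(nn_sepconv(ad_leaf(x), P))
}

# ---- CBAM ----------------------------------------------------------------

cbam_init <- function(C, reduction = 2, kernel = 3, seed = 1) {
  set.seed(seed)
  Cr <- max(1L, C %/% reduction)
  list(W1 = glorot(C, Cr), b1 = numeric(Cr),
       W2 = glorot(Cr, C), b2 = numeric(C),
       w_sp = array(stats::runif(kernel * kernel * 2, -1, 1) *
                      sqrt(6 / (kernel * kernel * 2 + 1)),
                    c(kernel, kernel, 2)),
       b_sp = 0)
}

nn_cbam <- function(x, P) {
  mlp <- function(v) {
    ad_addvec(ad_matmul(ad_relu(ad_addvec(ad_matmul(v, P$W1), P$b1)), P$W2),
              P$b2)
  }
  Mc <- ad_sigmoid(ad_add(mlp(ad_gap(x)), mlp(ad_gmp(x))))
  x1 <- ad_mul_channel(x, Mc)
  stacked <- ad_stack_maps(list(ad_chanmean(x1), ad_chanmax(x1)))
  Ms <- ad_sigmoid(ad_conv_flat(stacked, P$w_sp, P$b_sp))
  list(out = ad_mul_spatial(x1, Ms), Mc = Mc, Ms = Ms)
}

#' Convolutional block attention (CBAM)
#'
#' Channel attention first: sigmoid of a shared two-layer MLP applied to the
#' global average- and max-pooled channel descriptors, multiplied into each
#' channel. Then spatial attention: sigmoid of a small convolution over the
#' channel-wise average and max maps of the refined tensor, multiplied into
#' each position. All attention values lie in (0, 1), so the output is an
#' elementwise attenuation of the input.
#'
#' @param x H x W x C numeric array.
#' @param weights optional parameter list (as produced internally); when
#'   `NULL`, seeded random weights are created.
#' @param reduction channel reduction ratio of the MLP bottleneck.
#' @param kernel spatial attention kernel size (odd).
#' @param seed seed for the default weights.
#' @return List with `output` (H x W x C), `Mc` (1 x C channel attention)
#'   and `Ms` (H x W spatial attention).
#' @export
cbam <- function(x, weights = NULL, reduction = 2, kernel = 3, seed = 1) {
  stopifnot(length(dim(x)) == 3)
  C <- dim(x)[3]
  if (is.null(weights)) weights <- cbam_init(C, reduction, kernel, seed)
  P <- lapply(weights, ad_leaf)
  res <- nn_cbam(ad_leaf(x), P)
  list(output = ad_val(res$out), Mc = ad_val(res$Mc), Ms = ad_val(res$Ms))
}

# ---- BiLSTM with temporal attention -------------------------------------

lstm_init <- function(input_dim, hidden) {
  # gate order i, f, g, o; forget-gate bias starts at 1
  b <- numeric(4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1
  list(Wx = glorot(input_dim, 4 * hidden),
       Wh = glorot(hidden, 4 * hidden),
       b = b)
}

nn_lstm_dir <- function(E, P, hidden, reverse = FALSE) {
  Tn <- nrow(ad_val(E))
  steps <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  h <- ad_leaf(matrix(0, 1, hidden))
  cc <- ad_leaf(matrix(0, 1, hidden))
  out <- vector("list", Tn)
  for (t in steps) {
    xt <- ad_row(E, t)
    z <- ad_addvec(ad_add(ad_matmul(xt, P$Wx), ad_matmul(h, P$Wh)), P$b)
    i <- ad_sigmoid(ad_cols(z, 1:hidden))
    f <- ad_sigmoid(ad_cols(z, (hidden + 1):(2 * hidden)))
    g <- ad_tanh(ad_cols(z, (2 * hidden + 1):(3 * hidden)))
    o <- ad_sigmoid(ad_cols(z, (3 * hidden + 1):(4 * hidden)))
    cc <- ad_add(ad_mul(f, cc), ad_mul(i, g))
    h <- ad_mul(o, ad_tanh(cc))
    out[[t]] <- h
  }
  out
}

nn_bilstm <- function(E, P, hidden) {
  fwd <- nn_lstm_dir(E, P$fwd, hidden, reverse = FALSE)
  bwd <- nn_lstm_dir(E, P$bwd, hidden, reverse = TRUE)
  rows <- lapply(seq_along(fwd), function(t) {
    ad_concat_cols(list(fwd[[t]], bwd[[t]]))
  })
  ad_rbind(rows)
}

attn_init <- function(d, attn_dim) {
  list(Wa = glorot(d, attn_dim), ba = numeric(attn_dim),
       u = glorot(attn_dim, 1))
}

nn_attention_pool <- function(H, P) {
  S <- ad_tanh(ad_addvec(ad_matmul(H, P$Wa), P$ba))
  scores <- ad_matmul(S, P$u)                       # T x 1
  alpha <- ad_softmax_rows(ad_transpose(scores))    # 1 x T
  list(v = ad_matmul(alpha, H), alpha = alpha)
}

#' Bidirectional LSTM with temporal attention pooling
#'
#' Runs a forward and a backward LSTM over the T x d input sequence,
#' concatenates the two hidden states per time step, scores each step with
#' a learned tanh projection reduced to a scalar, softmax-normalises the
#' scores into attention weights (they sum to 1), and returns the
#' attention-weighted context vector.
#'
#' @param seq T x d numeric matrix (T >= 1).
#' @param hidden LSTM hidden width per direction.
#' @param weights optional parameter list; seeded random weights otherwise.
#' @param seed seed for the default weights.
#' @return List with `context` (1 x 2*hidden), `weights` (length-T
#'   attention), and `states` (T x 2*hidden hidden-state sequence).
#' @export
bilstm_attention <- function(seq, hidden = 8, weights = NULL, seed = 1) {
  seq <- as.matrix(seq)
  if (nrow(seq) < 1) stop("bilstm_attention: empty sequence")
  if (is.null(weights)) {
    set.seed(seed)
    weights <- list(fwd = lstm_init(ncol(seq), hidden),
                    bwd = lstm_init(ncol(seq), hidden),
                    attn = attn_init(2 * hidden, hidden))
  }
  P <- wrap_leaves(weights)
  H <- nn_bilstm(ad_leaf(seq), P, hidden)
  pool <- nn_attention_pool(H, P$attn)
  list(context = ad_val(pool$v), weights = as.numeric(ad_val(pool$alpha)),
       states = ad_val(H))
}

# ---- transformer pieces --------------------------------------------------

#' Sinusoidal positional encoding
#'
#' `PE[t, 2i+1] = sin(t / 10000^(2i/d))`, `PE[t, 2i+2] = cos(...)` for
#' 0-based positions t; all entries in \[-1, 1\]. Added to embeddings so the
#' otherwise order-free attention sees token positions.
#'
#' @param T_len sequence length.
#' @param d_model embedding width (must be even).
#' @return T_len x d_model matrix.
#' @export
positional_encoding <- function(T_len, d_model) {
  if (d_model %% 2 != 0) {
    stop("positional_encoding: d_model must be even, got ", d_model)
  }
  pos <- 0:(T_len - 1)
  i <- 0:(d_model / 2 - 1)
  angle <- outer(pos, 1 / 10000^(2 * i / d_model))
  pe <- matrix(0, T_len, d_model)
  pe[, seq(1, d_model, by = 2)] <- sin(angle)
  pe[, seq(2, d_model, by = 2)] <- cos(angle)
  pe
}

mha_init <- function(d_model) {
  list(Wq = glorot(d_model, d_model), bq = numeric(d_model),
       Wk = glorot(d_model, d_model), bk = numeric(d_model),
       Wv = glorot(d_model, d_model), bv = numeric(d_model),
       Wo = glorot(d_model, d_model), bo = numeric(d_model))
}

nn_mha <- function(Q, K, V, P, heads, return_attention = FALSE) {
  d_model <- ncol(ad_val(Q))
  if (d_model %% heads != 0) {
    stop("multi_head_attention: width ", d_model,
         " not divisible by heads ", heads)
  }
  dk <- d_model %/% heads
  Qp <- ad_addvec(ad_matmul(Q, P$Wq), P$bq)
  Kp <- ad_addvec(ad_matmul(K, P$Wk), P$bk)
  Vp <- ad_addvec(ad_matmul(V, P$Wv), P$bv)
  outs <- vector("list", heads)
  attn <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    Qh <- ad_cols(Qp, idx); Kh <- ad_cols(Kp, idx); Vh <- ad_cols(Vp, idx)
    A <- ad_softmax_rows(ad_smul(ad_matmul(Qh, ad_transpose(Kh)),
                                 1 / sqrt(dk)))
    attn[[h]] <- A
    outs[[h]] <- ad_matmul(A, Vh)
  }
  out <- ad_addvec(ad_matmul(ad_concat_cols(outs), P$Wo), P$bo)
  if (return_attention) list(out = out, attention = attn) else out
}

#' Multi-head scaled dot-product attention
#'
#' Splits the model width across `heads`, computes per-head softmax
#' attention (each query row's weights sum to 1), concatenates the heads
#' and projects with an output matrix. With `weights = NULL` all
#' projections are the identity so the raw attention behaviour is exposed.
#'
#' @param Q,K,V T x d_model numeric matrices.
#' @param heads number of heads; must divide d_model.
#' @param weights optional projection parameter list; identity projections
#'   otherwise.
#' @return List with `output` (T x d_model) and `attention` (list of
#'   per-head T x T matrices).
#' @export
multi_head_attention <- function(Q, K, V, heads = 1, weights = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  d_model <- ncol(Q)
  if (is.null(weights)) {
    I <- diag(d_model)
    weights <- list(Wq = I, bq = numeric(d_model), Wk = I,
                    bk = numeric(d_model), Wv = I, bv = numeric(d_model),
                    Wo = I, bo = numeric(d_model))
  }
  P <- lapply(weights, ad_leaf)
  res <- nn_mha(ad_leaf(Q), ad_leaf(K), ad_leaf(V), P, heads,
                return_attention = TRUE)
  list(output = ad_val(res$out),
       attention = lapply(res$attention, ad_val))
}

transformer_init <- function(d_model, ffn_hidden, two_residual = FALSE) {
  p <- list(mha = mha_init(d_model),
            W1 = glorot(d_model, ffn_hidden), b1 = numeric(ffn_hidden),
            W2 = glorot(ffn_hidden, d_model), b2 = numeric(d_model),
            ln_g = rep(1, d_model), ln_b = numeric(d_model))
  if (two_residual) {
    p$ln1_g <- rep(1, d_model)
    p$ln1_b <- numeric(d_model)
  }
  p
}

nn_transformer_block <- function(X, P, heads, dropout = 0, training = FALSE,
                                 two_residual = FALSE) {
  ffn <- function(z) {
    ad_addvec(ad_matmul(
      ad_dropout(ad_relu(ad_addvec(ad_matmul(z, P$W1), P$b1)),
                 dropout, training),
      P$W2), P$b2)
  }
  A <- ad_dropout(nn_mha(X, X, X, P$mha, heads), dropout, training)
  if (two_residual) {
    Y <- ad_layernorm_rows(ad_add(X, A), P$ln1_g, P$ln1_b)
    ad_layernorm_rows(ad_add(Y, ffn(Y)), P$ln_g, P$ln_b)
  } else {
    # single-residual form: O = LayerNorm(X + FFN(Attention(X)))
    ad_layernorm_rows(ad_add(X, ffn(A)), P$ln_g, P$ln_b)
  }
}

#' Transformer encoder block
#'
#' Multi-head self-attention followed by a position-wise feed-forward
#' network, residual connection and layer normalisation, in the
#' single-residual form `O = LayerNorm(X + FFN(Attention(X)))` by default
#' (the conventional two-residual block is available via `two_residual`).
#' Output shape equals input shape.
#'
#' @param x T x d_model numeric matrix.
#' @param heads attention heads (must divide d_model).
#' @param ffn_hidden feed-forward hidden width.
#' @param weights optional parameter list; seeded random weights otherwise.
#' @param dropout dropout rate (applied only when `training = TRUE`).
#' @param training logical.
#' @param two_residual use the conventional two-residual layout.
#' @param seed seed for the default weights.
#' @return T x d_model matrix.
#' @export
transformer_block <- function(x, heads = 1, ffn_hidden = 16, weights = NULL,
                              dropout = 0, training = FALSE,
                              two_residual = FALSE, seed = 1) {
  x <- as.matrix(x)
  if (is.null(weights)) {
    set.seed(seed)
    weights <- transformer_init(ncol(x), ffn_hidden, two_residual)
  }
  P <- wrap_leaves(weights)
  ad_val(nn_transformer_block(ad_leaf(x), P, heads, dropout, training,
                              two_residual))
}
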