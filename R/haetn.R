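#' Hybrid attention-enhanced transformer network (HAETN)
#'
#' The classifier chains: a depthwise-separable convolution encoder with
#' ReLU, max pooling and CBAM applied to every slice; global average
#' pooling into a per-slice embedding; sinusoidal positional encodings; a
#' bidirectional LSTM over the slice sequence; temporal attention pooling
#' into a context vector; a transformer encoder block; an optional
#' concatenation of handcrafted (selected) features; and a dense + softmax
#' head. Training is plain SGD with momentum on the cross-entropy, run on
#' the package's reverse-mode autodiff engine, fully seeded and
#' single-threaded so repeated runs are bit-identical.
#'
#' @name haetn
NULL

#' Validate and complete a HAETN configuration
#'
#' Defaults follow the published configuration (64 conv filters, kernel 3,
#' pool 2, 128 LSTM hidden units, 8 heads, 2048 feed-forward units, dropout
#' 0.1/0.5, dense 64, 2 classes, batch 32, momentum 0.9); tests and desk
#' runs pass reduced widths, which the width-scaling contract guarantees
#' remain valid (heads must divide the model width 2*lstm_hidden, the
#' embedding width must be even, dropout in \[0,1)).
#'
#' @param ... overrides of the `haetn` block of [pipeline_config()].
#' @return A validated list of class `haetn_config`.
#' @export
haetn_config <- function(...) {
  cfg <- utils::modifyList(pipeline_config()$haetn, list(...))
  if (cfg$n_classes < 2) stop("haetn_config: n_classes must be >= 2")
  if ((2 * cfg$lstm_hidden) %% cfg$attn_heads != 0) {
    stop("haetn_config: attn_heads (", cfg$attn_heads,
         ") must divide the model width ", 2 * cfg$lstm_hidden)
  }
  if (cfg$conv_filters %% 2 != 0) {
    stop("haetn_config: conv_filters must be even (positional encoding)")
  }
  if (cfg$transformer_dropout < 0 || cfg$transformer_dropout >= 1 ||
      cfg$dense_dropout < 0 || cfg$dense_dropout >= 1) {
    stop("haetn_config: dropout rates must be in [0, 1)")
  }
  class(cfg) <- c("haetn_config", "list")
  cfg
}

haetn_init_params <- function(cfg, input_shape) {
  F <- cfg$conv_filters
  h <- cfg$lstm_hidden
  dm <- 2 * h
  k <- cfg$conv_kernel
  p <- list()
  if (cfg$input_mode == "slice_sequence") {
    p$conv <- list(
      dw = array(stats::runif(k * k, -1, 1) * sqrt(6 / (k * k + 1)),
                 c(k, k, 1)),
      pw = glorot(1, F),
      pw_b = numeric(F))
    p$cbam <- cbam_init(F, reduction = 2, kernel = 3,
                        seed = sample.int(1e6, 1))
    emb <- 2 * F   # per-slice embedding = [global average; global max] pools
  } else {
    emb <- F
    p$embed <- list(W = glorot(input_shape[2], emb), b = numeric(emb))
  }
  # embedding layer norm keeps the encoder output on the same scale as the
  # unit-amplitude positional encoding, without which the position signal
  # swamps the content signal at desk-scale widths
  p$emb_ln <- list(g = rep(1, emb), b = numeric(emb))
  p$lstm <- list(fwd = lstm_init(emb, h), bwd = lstm_init(emb, h))
  p$attn <- attn_init(dm, h)
  p$transformer <- transformer_init(dm, cfg$ffn_hidden, cfg$two_residual)
  n_hand <- if (isTRUE(cfg$fuse_handcrafted)) cfg$n_handcrafted else 0L
  p$dense <- list(W = glorot(dm + n_hand, cfg$dense_units),
                  b = numeric(cfg$dense_units))
  p$out <- list(W = glorot(cfg$dense_units, cfg$n_classes),
                b = numeric(cfg$n_classes))
  p
}

# forward pass on autodiff nodes; P is a wrapped parameter tree
haetn_forward_nodes <- function(P, cfg, x, training = FALSE, hand = NULL) {
  acts <- NULL
  if (cfg$input_mode == "slice_sequence") {
    d <- dim(x)
    if (length(d) == 2) { x <- array(x, c(d, 1)); d <- dim(x) }
    Tn <- d[3]
    emb <- vector("list", Tn)
    acts <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      xt <- ad_leaf(array(x[, , t], c(d[1], d[2], 1)))
      z <- ad_relu(nn_sepconv(xt, P$conv))
      z <- ad_maxpool(z, cfg$pool)
      cb <- nn_cbam(z, P$cbam)
      acts[[t]] <- cb$out
      # average pooling summarises diffuse content, max pooling preserves
      # localised bright features (lesions) at full contrast
      emb[[t]] <- ad_concat_cols(list(ad_gap(cb$out), ad_gmp(cb$out)))
    }
    E <- ad_rbind(emb)
    Tlen <- Tn
  } else {
    X <- ad_leaf(as.matrix(x))
    E <- ad_addvec(ad_matmul(X, P$embed$W), P$embed$b)
    Tlen <- nrow(as.matrix(x))
  }
  E <- ad_layernorm_rows(E, P$emb_ln$g, P$emb_ln$b)
  E <- ad_add(E, ad_leaf(positional_encoding(Tlen, ncol(ad_val(E)))))
  H <- nn_bilstm(E, P$lstm, cfg$lstm_hidden)
  pool <- nn_attention_pool(H, P$attn)
  O <- nn_transformer_block(pool$v, P$transformer, cfg$attn_heads,
                            cfg$transformer_dropout, training,
                            cfg$two_residual)
  if (isTRUE(cfg$fuse_handcrafted)) {
    if (is.null(hand)) stop("haetn: fuse_handcrafted is on but no ",
                            "handcrafted features supplied")
    O <- ad_concat_cols(list(O, ad_leaf(matrix(hand, 1))))
  }
  D <- ad_dropout(ad_relu(ad_addvec(ad_matmul(O, P$dense$W), P$dense$b)),
                  cfg$dense_dropout, training)
  logits <- ad_addvec(ad_matmul(D, P$out$W), P$out$b)
  list(logits = logits, acts = acts, alpha = pool$alpha)
}

#' Forward pass: class probabilities for one input
#'
#' @param model a `haetn_model` from [train_haetn()] (or [haetn_new()]).
#' @param input an H x W x T slice sequence (slice_sequence mode) or a
#'   T x d feature-sequence matrix.
#' @param handcrafted optional numeric vector of handcrafted features
#'   (required iff the config fuses them).
#' @return Numeric vector of class probabilities (sums to 1).
#' @export
haetn_forward <- function(model, input, handcrafted = NULL) {
  check_input_shape(model, input)
  P <- wrap_leaves(model$params)
  res <- haetn_forward_nodes(P, model$config, input, training = FALSE,
                             hand = handcrafted)
  softmax_vec(as.numeric(ad_val(res$logits)))
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

check_input_shape <- function(model, input) {
  cfg <- model$config
  if (cfg$input_mode == "slice_sequence") {
    d <- dim(input)
    if (is.null(d) || length(d) < 2) {
      stop("haetn: slice_sequence input must be an H x W x T array")
    }
    if (!is.null(model$input_shape) &&
        !all(d[1:2] == model$input_shape[1:2])) {
      stop("haetn: input slice size ", paste(d[1:2], collapse = "x"),
           " does not match the trained shape ",
           paste(model$input_shape[1:2], collapse = "x"))
    }
  } else {
    if (!is.matrix(input)) stop("haetn: feature_sequence input must be a ",
                                "T x d matrix")
    if (!is.null(model$input_shape) && ncol(input) != model$input_shape[2]) {
      stop("haetn: input feature width ", ncol(input),
           " does not match the trained width ", model$input_shape[2])
    }
  }
  invisible(TRUE)
}

#' Create an untrained HAETN model
#'
#' @param config a [haetn_config()].
#' @param input_shape `c(H, W, T)` for slice sequences or `c(T, d)` for
#'   feature sequences.
#' @param seed RNG seed for parameter initialisation.
#' @return A `haetn_model` with randomly initialised parameters.
#' @export
haetn_new <- function(config, input_shape, seed = 1L) {
  set.seed(seed)
  params <- haetn_init_params(config, input_shape)
  structure(list(config = config, params = params,
                 input_shape = input_shape, history = NULL),
            class = "haetn_model")
}

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- paste0(prefix, nm)
    if (is.list(p[[nm]])) out <- c(out, flatten_params(p[[nm]],
                                                       paste0(key, ".")))
    else out[[key]] <- p[[nm]]
  }
  out
}

collect_grads <- function(P) {
  if (is.environment(P)) {
    g <- P$grad
    if (is.null(g)) g <- ad_val(P) * 0
    return(g)
  }
  lapply(P, collect_grads)
}

apply_sgd <- function(params, grads, vel, lr, mom) {
  if (!is.list(params)) {
    v <- mom * vel - lr * grads
    return(list(p = params + v, v = v))
  }
  out_p <- params; out_v <- vel
  for (nm in names(params)) {
    r <- apply_sgd(params[[nm]], grads[[nm]], vel[[nm]], lr, mom)
    out_p[[nm]] <- r$p
    out_v[[nm]] <- r$v
  }
  list(p = out_p, v = out_v)
}

rescale_params <- function(p, s) {
  if (!is.list(p)) return(p * s)
  lapply(p, rescale_params, s = s)
}

zero_like <- function(p) {
  if (!is.list(p)) return(p * 0)
  lapply(p, zero_like)
}

eval_set <- function(params, cfg, xs, ys, hands = NULL) {
  n <- length(xs)
  loss <- 0; correct <- 0
  P <- wrap_leaves(params)
  for (i in seq_len(n)) {
    res <- haetn_forward_nodes(P, cfg, xs[[i]], training = FALSE,
                               hand = if (!is.null(hands)) hands[i, ])
    pr <- softmax_vec(as.numeric(ad_val(res$logits)))
    loss <- loss - log(max(pr[ys[i] + 1], 1e-12))
    correct <- correct + (which.max(pr) == ys[i] + 1)
  }
  c(loss = loss / n, accuracy = correct / n)
}

#' Train a HAETN model
#'
#' Minimises cross-entropy with SGD + momentum (momentum may be a per-epoch
#' schedule vector), recording train and validation loss/accuracy each
#' epoch. All randomness (initialisation, shuffling, dropout, the
#' validation split) flows from the config seed, so identical seeds give
#' bit-identical final weights.
#'
#' @param dataset list with `x` (list of inputs, one per sample), `y`
#'   (0/1 integer labels), optionally `handcrafted` (n x m matrix).
#' @param config a [haetn_config()].
#' @param val_fraction fraction held out (stratified) for validation; 0
#'   disables validation.
#' @return A `haetn_model` with `history` (tibble: epoch, loss, accuracy,
#'   val_loss, val_accuracy).
#' @export
train_haetn <- function(dataset, config = haetn_config(),
                        val_fraction = 0.2) {
  xs <- dataset$x
  y <- as.integer(dataset$y)
  if (length(unique(y)) < 2) stop("train_haetn: need at least 2 classes")
  hands <- dataset$handcrafted
  if (isTRUE(config$fuse_handcrafted)) {
    if (is.null(hands)) stop("train_haetn: fuse_handcrafted requires ",
                             "dataset$handcrafted")
    config$n_handcrafted <- ncol(hands)
  }
  seed <- if (is.null(config$seed)) 1L else config$seed
  set.seed(seed)
  input_shape <- if (config$input_mode == "slice_sequence") {
    dim(xs[[1]])
  } else c(nrow(xs[[1]]), ncol(xs[[1]]))
  params <- haetn_init_params(config, input_shape)
  vel <- zero_like(params)
  n <- length(xs)
  # stratified validation split
  val_idx <- integer(0)
  if (val_fraction > 0) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      take <- max(1L, round(length(idx) * val_fraction))
      val_idx <- c(val_idx, sample(idx, take))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  mom_sched <- rep_len(config$momentum, config$epochs)
  hist <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    order_idx <- tr_idx[sample.int(length(tr_idx))]
    batches <- split(order_idx,
                     ceiling(seq_along(order_idx) / config$batch_size))
    for (b in batches) {
      ad_begin()
      P <- wrap_leaves(params)
      logit_rows <- vector("list", length(b))
      for (j in seq_along(b)) {
        i <- b[j]
        res <- haetn_forward_nodes(P, config, xs[[i]], training = TRUE,
                                   hand = if (!is.null(hands)) hands[i, ])
        logit_rows[[j]] <- res$logits
      }
      loss <- ad_cross_entropy(ad_rbind(logit_rows), y[b] + 1L)
      ad_backward(loss)
      grads <- collect_grads(P)
      ad_end()
      if (!is.null(config$clip_norm) && config$clip_norm > 0) {
        gn <- sqrt(sum(vapply(flatten_params(grads),
                              function(g) sum(g^2), numeric(1))))
        if (gn > config$clip_norm) {
          grads <- rescale_params(grads, config$clip_norm / gn)
        }
      }
      upd <- apply_sgd(params, grads, vel, config$learning_rate,
                       mom_sched[ep])
      params <- upd$p
      vel <- upd$v
    }
    tr <- eval_set(params, config, xs[tr_idx], y[tr_idx],
                   if (!is.null(hands)) hands[tr_idx, , drop = FALSE])
    if (length(val_idx)) {
      va <- eval_set(params, config, xs[val_idx], y[val_idx],
                     if (!is.null(hands)) hands[val_idx, , drop = FALSE])
    } else va <- c(loss = NA_real_, accuracy = NA_real_)
    hist[[ep]] <- tibble::tibble(
      epoch = ep, loss = tr[["loss"]], accuracy = tr[["accuracy"]],
      val_loss = va[["loss"]], val_accuracy = va[["accuracy"]])
  }
  structure(list(config = config, params = params,
                 input_shape = input_shape,
                 history = dplyr::bind_rows(hist),
                 val_idx = val_idx),
            class = "haetn_model")
}

#' @export
print.haetn_model <- function(x, ...) {
  cat("<haetn_model> mode =", x$config$input_mode,
      "| conv filters =", x$config$conv_filters,
      "| lstm hidden =", x$config$lstm_hidden, "\n")
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat("  trained ", last$epoch, " epoch(s); train acc ",
        signif(last$accuracy, 4), "\n", sep = "")
  }
  invisible(x)
}

#' Predict class probabilities for a list of inputs
#'
#' @param model a trained `haetn_model`.
#' @param xs list of inputs (see [haetn_forward()]).
#' @param handcrafted optional n x m matrix.
#' @return n x n_classes probability matrix.
#' @export
predict_haetn <- function(model, xs, handcrafted = NULL) {
  t(vapply(seq_along(xs), function(i) {
    haetn_forward(model, xs[[i]],
                  if (!is.null(handcrafted)) handcrafted[i, ])
  }, numeric(model$config$n_classes)))
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint (config + parameters + history); loading restores
#' bit-identical outputs.
#'
#' @param model a `haetn_model`.
#' @param path checkpoint path.
#' @return `load_haetn()` returns the restored `haetn_model`.
#' @export
save_haetn <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_haetn
#' @export
load_haetn <- function(path) {
  structure(readRDS(path), class = "haetn_model")
}

#' Grad-CAM saliency maps
#'
#' Gradient-weighted class activation mapping on the last convolutional
#' block (the CBAM output). Per slice, the gradient of the target-class
#' logit with respect to the activations is combined with the activations
#' element-wise before rectification (the high-resolution CAM variant):
#' `relu(sum_c dY/dA_c * A_c)`. Because the encoder pools with a global
#' max alongside the average, class evidence is often carried by a few
#' spatial positions; element-wise weighting preserves them where the
#' classical spatially-averaged channel weights would cancel. The map is
#' normalised to \[0, 1\] per slice and upsampled (nearest neighbour) to
#' the input slice size. A map that is all zero before normalisation is
#' returned as zeros with a warning.
#'
#' @param model a trained slice-sequence `haetn_model`.
#' @param input H x W x T slice sequence.
#' @param target_class class index (1-based) whose logit is explained.
#' @param handcrafted optional handcrafted feature vector.
#' @return H x W x T array of heatmaps in \[0, 1\].
#' @export
gradcam_map <- function(model, input, target_class = 2,
                        handcrafted = NULL) {
  cfg <- model$config
  if (cfg$input_mode != "slice_sequence") {
    stop("gradcam_map: needs a slice_sequence model (a convolutional block)")
  }
  if (target_class < 1 || target_class > cfg$n_classes) {
    stop("gradcam_map: target_class out of range 1..", cfg$n_classes)
  }
  d <- dim(input)
  ad_begin()
  on.exit(ad_end())
  P <- wrap_leaves(model$params)
  res <- haetn_forward_nodes(P, cfg, input, training = FALSE,
                             hand = handcrafted)
  score <- ad_cols(res$logits, target_class)
  ad_backward(ad_sum(score))
  out <- array(0, d)
  warned <- FALSE
  for (t in seq_len(d[3])) {
    act <- ad_val(res$acts[[t]])
    grad <- res$acts[[t]]$grad
    if (is.null(grad)) grad <- act * 0
    cam <- pmax(apply(grad * act, c(1, 2), sum), 0)
    mx <- max(cam)
    if (mx == 0) {
      if (!warned) {
        warning("gradcam_map: zero saliency on at least one slice")
        warned <- TRUE
      }
    } else {
      cam <- cam / mx
    }
    out[, , t] <- upsample_nn(cam, c(d[1], d[2]))
  }
  out
}

upsample_nn <- function(m, target) {
  ri <- pmin(nrow(m), pmax(1L, ceiling(seq_len(target[1]) * nrow(m) /
                                         target[1])))
  ci <- pmin(ncol(m), pmax(1L, ceiling(seq_len(target[2]) * ncol(m) /
                                         target[2])))
  m[ri, ci, drop = FALSE]
}

#' Write a Grad-CAM overlay PNG
#'
#' Renders a grayscale slice with the heatmap alpha-blended in red.
#'
#' @param slice H x W numeric matrix (any range; rescaled for display).
#' @param heat H x W heatmap in \[0, 1\].
#' @param path output PNG path.
#' @param alpha blend weight of the heatmap.
#' @return Invisibly, `path`.
#' @export
gradcam_overlay <- function(slice, heat, path, alpha = 0.5) {
  rng <- range(slice)
  base <- if (diff(rng) > 0) (slice - rng[1]) / diff(rng) else slice * 0
  rgb <- array(0, c(dim(slice), 3))
  rgb[, , 1] <- pmin(1, base * (1 - alpha) + heat * alpha)
  rgb[, , 2] <- base * (1 - alpha)
  rgb[, , 3] <- base * (1 - alpha)
  png::writePNG(rgb, path)
  invisible(path)
}
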