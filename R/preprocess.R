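#' Skull stripping
#'
#' Separates brain tissue from the dark background and the bright skull
#' shell. Foreground is found by intensity thresholding (Otsu by default, or
#' a fixed quantile), then morphological closing with a ball of radius
#' `morph_radius`, hole filling, and retention of the largest face-connected
#' component (the brain; the thin skull shell loses on volume). If the image
#' has no dark background at all (every voxel positive) the whole grid is
#' treated as brain and returned unchanged.
#'
#' @param vol a [volume_image()] with finite intensities.
#' @param threshold_method `"otsu"` or `"quantile"`.
#' @param threshold_quantile quantile used when `threshold_method =
#'   "quantile"`.
#' @param morph_radius closing radius in voxels.
#' @return A list with `vol` (out-of-mask voxels zeroed) and `mask` (a
#'   `brain_mask`: logical array plus voxel count).
#' @export
skull_strip <- function(vol, threshold_method = "otsu",
                        threshold_quantile = 0.5, morph_radius = 2) {
  x <- vol$data
  if (!all(is.finite(x))) stop("skull_strip: intensities must be finite")
  if (all(x == 0)) stop("skull_strip: no foreground (all-zero volume)")
  if (all(x > 0)) {
    mask <- array(TRUE, dim(x))
  } else {
    thr <- switch(threshold_method,
      # lower threshold of a three-class Otsu: the background/tissue split,
      # robust to several tissue modes above it
      otsu = otsu_threshold2(as.vector(x))[1],
      quantile = stats::quantile(as.vector(x), threshold_quantile,
                                 names = FALSE),
      stop("skull_strip: unknown threshold_method '", threshold_method, "'")
    )
    fg <- x > thr
    if (!any(fg)) stop("skull_strip: no foreground above threshold")
    # opening (erode, take the brain, dilate back) removes impulse speckles
    # and the thin bridges they form across the brain/skull gap; taking the
    # largest component while eroded keeps the skull shell out, which
    # closing-first would otherwise merge with the brain
    er <- binary_erode(fg, 1)
    if (any(er)) fg <- binary_dilate(largest_component(er), 1) & fg
    else fg <- largest_component(fg)
    if (morph_radius > 0) fg <- binary_close(fg, morph_radius)
    mask <- fill_holes(fg)
  }
  out <- x
  out[!mask] <- 0
  stripped <- vol
  stripped$data <- out
  stripped <- record_step(stripped, "skull_strip")
  structure_mask <- structure(
    list(mask = mask, voxel_count = sum(mask)), class = "brain_mask")
  list(vol = stripped, mask = structure_mask)
}

#' Bias field correction
#'
#' Removes smooth multiplicative intensity inhomogeneity under the
#' two-component model I = B * C (bias times true tissue image). Working in
#' the log domain on the positive-intensity mask, the estimator alternates
#' two steps: (1) explain the current corrected log-image by a small set of
#' tissue class levels (quantile-initialised k-means on intensities), and
#' (2) absorb the smooth part of the unexplained residual into the log-bias
#' estimate via masked Gaussian smoothing at `smoothing_sigma_mm`. The
#' energy is the sum of squared residuals after the class-level explanation;
#' an update is accepted only if it lowers the energy, so the recorded trace
#' is non-increasing by construction. The log-bias is gauge-fixed to mean
#' zero over the mask, and the corrected volume is I / B.
#'
#' A bias-free piecewise-constant image is a fixed point: the class levels
#' explain it exactly, the residual is zero, and B stays at 1.
#'
#' @param vol a [volume_image()] with non-negative intensities.
#' @param smoothing_sigma_mm Gaussian smoothing scale of the bias estimate,
#'   in mm.
#' @param max_iter maximum number of estimate/absorb iterations.
#' @param tol stop when the relative energy decrease falls below this.
#' @param n_classes number of internal tissue levels used to explain the
#'   corrected image.
#' @return A list with `vol` (corrected) and `bias` (a `bias_model`: the
#'   multiplicative field, iterations run, and the energy trace).
#' @export
bias_field_correct <- function(vol, smoothing_sigma_mm = 8, max_iter = 30,
                               tol = 1e-4, n_classes = 3) {
  x <- vol$data
  if (any(x < 0)) {
    stop("bias_field_correct: negative intensities; normalize to a ",
         "non-negative range first")
  }
  mask <- x > 0
  if (!any(mask)) stop("bias_field_correct: mask of positive voxels is empty")
  sigma_vox <- smoothing_sigma_mm / vol$spacing
  L <- array(0, dim(x))
  L[mask] <- log(x[mask])
  b <- array(0, dim(x))
  m_num <- array(0, dim(x)); m_num[mask] <- 1
  energy <- numeric(0)
  prev_e <- Inf
  iters <- 0L
  for (k in seq_len(max_iter)) {
    u <- L - b
    centres <- class_levels(u[mask], n_classes)
    t_hat <- centres[max.col(-outer(u[mask], centres,
                                    function(a, b) (a - b)^2))]
    r <- array(0, dim(x))
    r[mask] <- u[mask] - t_hat
    e <- sum(r[mask]^2)
    if (e >= prev_e) break
    energy <- c(energy, e)
    iters <- k
    if (is.finite(prev_e) && (prev_e - e) / max(prev_e, .Machine$double.eps) <
        tol) { prev_e <- e; break }
    prev_e <- e
    num <- gauss_blur(r, sigma_vox)
    den <- gauss_blur(m_num, sigma_vox)
    s <- array(0, dim(x))
    s[mask] <- num[mask] / pmax(den[mask], 1e-12)
    b <- b + s
  }
  b <- b - mean(b[mask])
  B <- array(1, dim(x))
  B[mask] <- exp(b[mask])
  corrected <- vol
  corrected$data <- x / B
  corrected <- record_step(corrected, "bias_field_correct")
  bias <- structure(
    list(field = B, iterations_run = iters, energy_trace = energy),
    class = "bias_model")
  list(vol = corrected, bias = bias)
}

# Deterministic quantile-initialised k-means class levels (Lloyd updates).
class_levels <- function(v, k) {
  k <- min(k, length(unique(v)))
  centres <- stats::quantile(v, (seq_len(k) - 0.5) / k, names = FALSE)
  if (k == 1) return(mean(v))
  for (i in 1:20) {
    assign <- max.col(-outer(v, centres, function(a, b) (a - b)^2))
    new <- vapply(seq_len(k), function(j) {
      if (any(assign == j)) mean(v[assign == j]) else centres[j]
    }, numeric(1))
    if (max(abs(new - centres)) < 1e-10) break
    centres <- new
  }
  sort(centres)
}

#' Min-max intensity normalisation
#'
#' Rescales intensities to `(x - min) / (max - min)`, so the output range is
#' exactly \[0, 1\]. A constant image maps to all zeros with a warning.
#' Idempotent for non-degenerate input.
#'
#' @param vol a [volume_image()] with finite intensities.
#' @return The normalised [volume_image()].
#' @export
min_max_normalize <- function(vol) {
  x <- vol$data
  if (!all(is.finite(x))) stop("min_max_normalize: intensities must be finite")
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    warning("min_max_normalize: constant image; returning all zeros")
    vol$data <- array(0, dim(x))
  } else {
    vol$data <- (x - lo) / (hi - lo)
  }
  record_step(vol, "min_max_normalize")
}

#' Median filtering
#'
#' Replaces each voxel by the median of its window (odd edge length per
#' axis); borders are handled by symmetric reflect padding. Output values
#' are always a subset of input values (order-statistic property), so edges
#' are preserved while salt-and-pepper impulses are removed.
#'
#' @param vol a [volume_image()].
#' @param window odd window edge length, scalar or one per axis.
#' @return The filtered [volume_image()].
#' @export
median_filter <- function(vol, window = 3) {
  d <- dim(vol$data)
  nd <- length(d)
  window <- rep_len(as.integer(window), nd)
  if (any(window < 1) || any(window %% 2 == 0)) {
    stop("median_filter: window must be odd and >= 1 per axis")
  }
  half <- window %/% 2
  padded <- pad_replicate_reflect(vol$data, half)
  offs <- as.matrix(do.call(expand.grid, lapply(half, function(h) -h:h)))
  n <- prod(d)
  k <- nrow(offs)
  stack <- matrix(0, nrow = n, ncol = k)
  for (i in seq_len(k)) {
    idx <- lapply(seq_len(nd), function(ax) half[ax] + offs[i, ax] +
                    seq_len(d[ax]))
    sub <- if (nd == 2) padded[idx[[1]], idx[[2]]]
           else padded[idx[[1]], idx[[2]], idx[[3]]]
    stack[, i] <- as.vector(sub)
  }
  # vectorised row-sort: order by (row, value), reshape, take middle column
  o <- order(row(stack), stack)
  sorted <- matrix(stack[o], nrow = n, byrow = TRUE)
  med <- sorted[, (k + 1) %/% 2]
  vol$data <- array(med, d)
  record_step(vol, paste0("median_filter(", paste(window, collapse = "x"),
                          ")"))
}

# Symmetric reflect padding (edge value included in the reflection).
pad_replicate_reflect <- function(a, pad) {
  d <- dim(a)
  nd <- length(d)
  idx <- lapply(seq_len(nd), function(ax) {
    i <- seq_len(d[ax] + 2 * pad[ax]) - pad[ax]
    i <- ifelse(i < 1, 1 - i, i)
    i <- ifelse(i > d[ax], 2 * d[ax] + 1 - i, i)
    pmin(pmax(i, 1L), d[ax])
  })
  if (nd == 2) a[idx[[1]], idx[[2]]] else a[idx[[1]], idx[[2]], idx[[3]]]
}

#' Full preprocessing pipeline
#'
#' Applies, in order: skull stripping, bias field correction, min-max
#' normalisation, median filtering. Each step can be disabled through the
#' `preprocess` block of the [pipeline_config()]; step parameters are
#' recorded in the output's provenance metadata. With every step disabled
#' the input is returned unchanged.
#'
#' @param vol a [volume_image()].
#' @param config a [pipeline_config()] (its `preprocess` block is used).
#' @return A list with `vol` (the preprocessed volume) and `intermediates`
#'   (named list of per-step outputs: `mask`, `bias`).
#' @export
preprocess_pipeline <- function(vol, config = pipeline_config()) {
  p <- config$preprocess
  out <- vol
  inter <- list()
  if (isTRUE(p$skull_strip)) {
    ss <- skull_strip(out, threshold_method = p$threshold_method,
                      threshold_quantile = p$threshold_quantile,
                      morph_radius = p$morph_radius)
    out <- ss$vol
    inter$mask <- ss$mask
  }
  if (isTRUE(p$bias_correct)) {
    bc <- bias_field_correct(out, smoothing_sigma_mm = p$smoothing_sigma_mm,
                             max_iter = p$bias_max_iter, tol = p$bias_tol)
    out <- bc$vol
    inter$bias <- bc$bias
  }
  if (isTRUE(p$normalize)) out <- min_max_normalize(out)
  if (isTRUE(p$median_filter)) out <- median_filter(out, p$median_window)
  out$meta$preprocess_params <- p
  list(vol = out, intermediates = inter)
}
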