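#' Synthetic phantom brain volume with ground truth
#'
#' Generates the study conditions for every image stage: an ellipsoidal
#' brain of three nested tissue classes (ordered intensities, e.g.
#' CSF/GM/WM), surrounded by a dark gap and a thin bright skull shell;
#' multiplied by a smooth positive multiplicative bias field; corrupted by
#' impulse (salt-and-pepper) and Gaussian noise. Every ground truth is
#' returned, so each pipeline stage can be scored without external data.
#' Fully deterministic given the seed.
#'
#' Default class means 0.25/0.50/0.75 with sd 0.03 keep the classes
#' separated by at least twice the largest sd (the separable preset);
#' intensities live in \[0, 1\] before corruption so that min-max
#' normalisation is exercised nontrivially by the bias and noise.
#'
#' @param shape integer vector of grid dimensions (default 64 x 64 x 32).
#' @param tissue_means,tissue_sds per-class intensity means (ascending) and
#'   standard deviations.
#' @param shell_intensity skull shell brightness.
#' @param gap_frac,shell_frac dark gap and shell thickness as fractions of
#'   the ellipsoid radius.
#' @param bias_amplitude max magnitude of the log-bias field (0 = no bias).
#' @param bias_smoothness_vox Gaussian scale (voxels) of the bias field.
#' @param impulse_fraction fraction of voxels hit by salt/pepper (in
#'   \[0, 0.2\]).
#' @param gaussian_sd additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return List: `vol` ([volume_image()]), `truth` ([label_volume()] of
#'   tissue classes, 0 outside brain), `bias_field` (array), `brain_mask`
#'   (logical array), `spec` (the arguments).
#' @export
make_phantom <- function(shape = c(64, 64, 32),
                         tissue_means = c(0.25, 0.5, 0.75),
                         tissue_sds = c(0.03, 0.03, 0.03),
                         shell_intensity = 0.9,
                         gap_frac = 0.12, shell_frac = 0.08,
                         bias_amplitude = 0, bias_smoothness_vox = 12,
                         impulse_fraction = 0, gaussian_sd = 0,
                         seed = 1L) {
  if (length(shape) != 3 || any(shape < 8)) {
    stop("make_phantom: shape must be 3 axes of at least 8 voxels")
  }
  if (is.unsorted(tissue_means)) stop("make_phantom: means must ascend")
  if (impulse_fraction < 0 || impulse_fraction > 0.2) {
    stop("make_phantom: impulse_fraction must be in [0, 0.2]")
  }
  set.seed(seed)
  r <- ellipsoid_radius(shape)
  brain <- r <= 1
  labels <- array(0L, shape)
  labels[r <= 1] <- 1L            # outer shell of brain: darkest class
  labels[r <= 0.8] <- 2L
  labels[r <= 0.55] <- 3L
  shell <- r > 1 + gap_frac & r <= 1 + gap_frac + shell_frac
  x <- array(0, shape)
  for (k in 1:3) {
    idx <- labels == k
    x[idx] <- tissue_means[k] + stats::rnorm(sum(idx), 0, tissue_sds[k])
  }
  x[shell] <- shell_intensity
  bias <- array(1, shape)
  if (bias_amplitude > 0) {
    g <- gauss_blur(array(stats::rnorm(prod(shape)), shape),
                    bias_smoothness_vox)
    g <- g - mean(g[brain])
    g <- g * (bias_amplitude / max(abs(g[brain])))
    bias <- exp(g)
  }
  x <- x * bias
  if (gaussian_sd > 0) {
    x <- x + stats::rnorm(prod(shape), 0, gaussian_sd)
  }
  if (impulse_fraction > 0) {
    n_imp <- round(impulse_fraction * prod(shape))
    pos <- sample.int(prod(shape), n_imp)
    x[pos] <- ifelse(stats::runif(n_imp) < 0.5, 0, max(x))
  }
  x <- pmax(x, 0)
  legend <- stats::setNames(c("csf_like", "gm_like", "wm_like"), 1:3)
  list(
    vol = volume_image(x, meta = list(source = "synthetic phantom")),
    truth = label_volume(labels, legend = legend),
    bias_field = bias,
    brain_mask = brain,
    spec = list(shape = shape, tissue_means = tissue_means,
                tissue_sds = tissue_sds, shell_intensity = shell_intensity,
                bias_amplitude = bias_amplitude,
                impulse_fraction = impulse_fraction,
                gaussian_sd = gaussian_sd, seed = seed)
  )
}

# normalised ellipsoid radius field: 1 on the brain boundary
ellipsoid_radius <- function(shape) {
  ctr <- (shape + 1) / 2
  semi <- shape * 0.36
  g <- voxel_grid(shape) + 1
  r <- sqrt(((g[, 1] - ctr[1]) / semi[1])^2 +
            ((g[, 2] - ctr[2]) / semi[2])^2 +
            ((g[, 3] - ctr[3]) / semi[3])^2)
  array(r, shape)
}

#' Toy region atlas
#'
#' Partitions the phantom brain ellipsoid into `n_regions` contiguous slabs
#' of roughly equal volume (quantile cuts along the first axis). The first
#' slab is flagged as the temporal-lobe-like region of interest. Identity
#' affine by default.
#'
#' @param shape grid dimensions (matching the subject phantom).
#' @param n_regions number of regions (>= 2).
#' @param seed unused placeholder for generator symmetry (the slab
#'   partition is deterministic); kept so all generators share a signature.
#' @return An [atlas_ref()].
#' @export
make_toy_atlas <- function(shape = c(64, 64, 32), n_regions = 4, seed = 1L) {
  if (n_regions < 2) stop("make_toy_atlas: n_regions must be >= 2")
  r <- ellipsoid_radius(shape)
  brain <- r <= 1
  if (n_regions > sum(brain)) {
    stop("make_toy_atlas: more regions than brain voxels")
  }
  xcoord <- array(rep(seq_len(shape[1]), times = prod(shape[2:3])), shape)
  xs <- xcoord[brain]
  cuts <- stats::quantile(xs, probs = seq(0, 1, length.out = n_regions + 1),
                          names = FALSE)
  cuts[1] <- -Inf; cuts[n_regions + 1] <- Inf
  lab <- array(0L, shape)
  lab[brain] <- as.integer(cut(xs, cuts, labels = FALSE,
                               include.lowest = TRUE))
  legend <- stats::setNames(
    c("temporal_lobe_like", paste0("region_", seq_len(n_regions - 1) + 1)),
    seq_len(n_regions))
  atlas_ref(label_volume(lab, legend = legend), affine_h = diag(4),
            legend = legend)
}

#' Labelled two-class feature dataset with a known informative subset
#'
#' Informative features follow class-conditional normals whose means differ
#' by `effect_size` standard deviations (optionally equicorrelated within
#' the informative block); noise features are standard normal independent
#' of class. Columns are shuffled with a recorded permutation, so the true
#' informative set is known to the caller.
#'
#' @param n_per_class samples per class.
#' @param n_informative,n_noise feature counts.
#' @param effect_size standardised mean difference between classes.
#' @param rho correlation between informative features.
#' @param seed RNG seed.
#' @return A labelled [feature_table()] with attributes
#'   `informative_idx` (column positions of the informative features among
#'   the feature columns, after shuffling) and `permutation`.
#' @export
make_feature_dataset <- function(n_per_class = 50, n_informative = 2,
                                 n_noise = 8, effect_size = 2, rho = 0,
                                 seed = 1L) {
  stopifnot(n_per_class >= 1, n_informative >= 1, n_noise >= 0,
            effect_size >= 0)
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c(0L, 1L), each = n_per_class)
  Zi <- matrix(stats::rnorm(n * n_informative), n, n_informative)
  if (rho != 0 && n_informative > 1) {
    S <- matrix(rho, n_informative, n_informative)
    diag(S) <- 1
    Zi <- Zi %*% chol(S)
  }
  Zi <- Zi + outer(y, rep(effect_size, n_informative))
  Zn <- matrix(stats::rnorm(n * n_noise), n, n_noise)
  X <- cbind(Zi, Zn)
  d <- ncol(X)
  perm <- sample.int(d)
  X <- X[, perm, drop = FALSE]
  nm <- character(d)
  nm[match(seq_len(n_informative), perm)] <-
    paste0("inf", seq_len(n_informative))
  nm[match(n_informative + seq_len(n_noise), perm)] <-
    paste0("noise", seq_len(n_noise))
  tbl <- feature_table(X, feature_names = nm, labels = y)
  attr(tbl, "informative_idx") <- match(seq_len(n_informative), perm)
  attr(tbl, "permutation") <- perm
  tbl
}

#' Tiny labelled slice-sequence dataset with a planted blob
#'
#' Class-1 sequences carry a bright disk in a fixed quadrant of the middle
#' slices; class-0 sequences lack it. A dim ellipse mimics the brain
#' outline on every slice, and Gaussian noise is added everywhere. This is
#' the desk-scale training data for the classifier and the localisation
#' target for Grad-CAM.
#'
#' @param n_per_class sequences per class (>= 4).
#' @param shape `c(H, W, T)` of each sequence (default 16 x 16 x 4).
#' @param blob_contrast added intensity of the blob (0 makes the classes
#'   statistically indistinguishable).
#' @param blob_quadrant which quadrant holds the blob (1 = top-left rows x
#'   cols block, in matrix orientation).
#' @param noise_sd Gaussian noise sd.
#' @param seed RNG seed.
#' @return List: `x` (list of H x W x T arrays), `y` (0/1), `blob_mask`
#'   (H x W logical), `blob_slices` (indices of slices carrying the blob),
#'   `quadrant`.
#' @export
make_slice_dataset <- function(n_per_class = 20, shape = c(16, 16, 4),
                               blob_contrast = 0.6, blob_quadrant = 1,
                               noise_sd = 0.05, seed = 1L) {
  if (n_per_class < 4) stop("make_slice_dataset: n_per_class must be >= 4")
  set.seed(seed)
  H <- shape[1]; W <- shape[2]; Tn <- shape[3]
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  ij <- expand.grid(i = seq_len(H), j = seq_len(W))
  ellipse <- matrix(((ij$i - ctr[1]) / (0.45 * H))^2 +
                    ((ij$j - ctr[2]) / (0.45 * W))^2 <= 1, H, W)
  qc <- switch(blob_quadrant,
               `1` = c(0.25, 0.25), `2` = c(0.25, 0.75),
               `3` = c(0.75, 0.25), `4` = c(0.75, 0.75))
  bc <- c(qc[1] * H, qc[2] * W)
  rad <- max(2, round(min(H, W) / 6))
  blob <- matrix((ij$i - bc[1])^2 + (ij$j - bc[2])^2 <= rad^2, H, W)
  blob_slices <- seq.int(max(1L, floor(Tn / 2)), min(Tn, floor(Tn / 2) + 1L))
  base_slice <- matrix(0.2 * ellipse, H, W)
  xs <- vector("list", 2 * n_per_class)
  y <- rep(c(0L, 1L), each = n_per_class)
  for (s in seq_along(y)) {
    vol <- array(stats::rnorm(H * W * Tn, 0, noise_sd), c(H, W, Tn))
    for (t in seq_len(Tn)) {
      vol[, , t] <- vol[, , t] + base_slice
      if (y[s] == 1 && t %in% blob_slices) {
        vol[, , t] <- vol[, , t] + blob_contrast * blob
      }
    }
    xs[[s]] <- vol
  }
  list(x = xs, y = y, blob_mask = blob, blob_slices = blob_slices,
       quadrant = blob_quadrant)
}
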