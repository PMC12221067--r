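#' Fuzzy possibilistic c-means (FPCM) clustering
#'
#' FPCM combines normalised fuzzy memberships (each voxel's memberships sum
#' to 1 across clusters) with unnormalised possibilistic typicalities that
#' discount outliers. The objective couples both terms through the squared
#' voxel-to-centre distances, and the alternating updates below minimise it.
#' Distances are Euclidean on intensity (1-D) by default; all updates also
#' accept multi-feature voxel vectors (rows of a matrix).
#'
#' @name fpcm
NULL

# n x c squared distances between value rows and centre rows.
sq_dist <- function(values, V) {
  values <- as.matrix(values)
  V <- as.matrix(V)
  d2 <- outer(rowSums(values^2), rep(1, nrow(V))) +
    outer(rep(1, nrow(values)), rowSums(V^2)) -
    2 * values %*% t(V)
  pmax(d2, 0)
}

#' Initialise cluster centres
#'
#' The quantile method places the c centres at the (k - 0.5)/c quantiles of
#' the (1-D) intensity distribution, which is fully deterministic. The
#' kmeans++-style method samples a first centre uniformly and subsequent
#' centres proportionally to squared distance from the nearest chosen
#' centre, using the seeded RNG.
#'
#' @param values numeric vector (or matrix with one row per voxel) of masked
#'   intensities.
#' @param c number of clusters.
#' @param seed RNG seed (used by the kmeans++-style method).
#' @param method `"quantile"` or `"kmeanspp"`.
#' @return A c x d matrix of distinct centres (d = 1 for intensities).
#' @export
init_centers <- function(values, c, seed = 1L, method = "quantile") {
  values <- as.matrix(values)
  uniq <- unique(values)
  if (nrow(uniq) < c) {
    stop("init_centers: fewer distinct values (", nrow(uniq),
         ") than clusters (", c, ")")
  }
  if (nrow(uniq) == c) {
    return(uniq[order(uniq[, 1]), , drop = FALSE])
  }
  if (method == "quantile") {
    if (ncol(values) != 1) {
      stop("init_centers: quantile initialisation needs 1-D intensities")
    }
    q <- stats::quantile(values[, 1], (seq_len(c) - 0.5) / c, names = FALSE)
    # nudge any collided quantiles apart so centres stay pairwise distinct
    while (anyDuplicated(q)) {
      q[duplicated(q)] <- q[duplicated(q)] + 1e-9 * max(1, diff(range(values)))
    }
    matrix(sort(q), ncol = 1)
  } else if (method == "kmeanspp") {
    set.seed(seed)
    n <- nrow(values)
    centres <- values[sample.int(n, 1), , drop = FALSE]
    while (nrow(centres) < c) {
      d2 <- apply(sq_dist(values, centres), 1, min)
      if (sum(d2) == 0) {
        cand <- uniq[!duplicated(rbind(centres, uniq))[-seq_len(nrow(centres))],
                     , drop = FALSE]
        centres <- rbind(centres, cand[1, , drop = FALSE])
      } else {
        centres <- rbind(centres,
                         values[sample.int(n, 1, prob = d2), , drop = FALSE])
      }
      centres <- unique(centres)
    }
    centres[order(centres[, 1]), , drop = FALSE]
  } else {
    stop("init_centers: unknown method '", method, "'")
  }
}

#' Update fuzzy memberships
#'
#' U\[i, C\] = 1 / sum_K (D\[i,C\]/D\[i,K\])^(2/(M-1)); each row sums to 1.
#' A voxel at zero distance from a centre receives membership 1 there and 0
#' elsewhere (split evenly over ties).
#'
#' @param values voxel intensities (vector or matrix).
#' @param V cluster centres (vector or matrix, one row per cluster).
#' @param M fuzziness exponent, > 1.
#' @return n x c membership matrix.
#' @export
update_fuzzy_memberships <- function(values, V, M) {
  if (M <= 1) stop("update_fuzzy_memberships: M must be > 1")
  D2 <- sq_dist(values, V)
  expo <- 1 / (M - 1)          # applied to squared distances: (D^2)^(1/(M-1))
  inv <- D2^(-expo)
  U <- inv / rowSums(inv)
  zero <- D2 <= .Machine$double.eps
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    U[hit, ] <- zero[hit, , drop = FALSE] /
      rowSums(zero[hit, , drop = FALSE])
  }
  U
}

#' Update possibilistic memberships
#'
#' alpha\[i, C\] = 1 / (1 + (D\[i,C\]/eta\[C\])^Q); entries lie in (0, 1\],
#' reaching 1 exactly at zero distance and 0.5 at D = eta.
#'
#' @param values voxel intensities.
#' @param V cluster centres.
#' @param Q possibilistic exponent, > 1 (Q = 2 default elsewhere).
#' @param eta per-cluster scale eta_C > 0 (recycled if scalar).
#' @return n x c typicality matrix.
#' @export
update_possibilistic_memberships <- function(values, V, Q, eta) {
  V <- as.matrix(V)
  eta <- rep_len(eta, nrow(V))
  if (any(eta <= 0)) stop("update_possibilistic_memberships: eta must be > 0")
  D <- sqrt(sq_dist(values, V))
  ratio <- sweep(D, 2, eta, "/")
  1 / (1 + ratio^Q)
}

#' Estimate the possibilistic scale eta per cluster
#'
#' eta_C = K_scale * sum_i U\[i,C\]^M D\[i,C\]^2 / sum_i U\[i,C\]^M, the
#' membership-weighted mean squared distance, computed once after an initial
#' fuzzy-only pass. Degenerate clusters (eta below 1e-6) raise an error
#' naming the cluster; callers that want the floor instead pass
#' `floor_degenerate = TRUE`.
#'
#' @param U fuzzy membership matrix.
#' @param values voxel intensities.
#' @param V centres.
#' @param M fuzziness exponent.
#' @param K_scale multiplier (default 1).
#' @param floor_degenerate replace degenerate eta by the 1e-6 floor instead
#'   of erroring.
#' @return numeric vector of per-cluster eta.
#' @export
estimate_eta <- function(U, values, V, M, K_scale = 1,
                         floor_degenerate = FALSE) {
  D2 <- sq_dist(values, V)
  W <- U^M
  denom <- colSums(W)
  if (any(denom == 0)) {
    stop("estimate_eta: cluster ", which(denom == 0)[1],
         " has all-zero memberships")
  }
  eta <- K_scale * colSums(W * D2) / denom
  low <- eta < 1e-6
  if (any(low)) {
    if (!floor_degenerate) {
      stop("estimate_eta: degenerate cluster ", which(low)[1],
           " (eta = ", signif(eta[which(low)[1]], 3),
           "); a floor of 1e-6 is required")
    }
    eta[low] <- 1e-6
  }
  eta
}

#' FPCM objective function
#'
#' J_M = sum_i sum_C \[ U\[i,C\]^M D\[i,C\]^2 + alpha\[i,C\]^Q D\[i,C\]^2 \].
#' The possibilistic distance term uses the same Euclidean voxel-to-centre
#' distance as the fuzzy term.
#'
#' @param U fuzzy memberships; `A` possibilistic memberships.
#' @param A possibilistic membership matrix.
#' @param values voxel intensities.
#' @param V centres.
#' @param M,Q exponents.
#' @return Scalar objective value, finite and >= 0.
#' @export
fpcm_objective <- function(U, A, values, V, M, Q) {
  D2 <- sq_dist(values, V)
  sum(U^M * D2 + A^Q * D2)
}

#' Update cluster centres
#'
#' V_C = sum_i (alpha\[i,C\]^Q U\[i,C\]^M x_i) / sum_i (alpha\[i,C\]^Q
#' U\[i,C\]^M): centres move to the joint-membership-weighted mean.
#'
#' @param U,A membership matrices.
#' @param values voxel intensities.
#' @param M,Q exponents.
#' @return c x d centre matrix.
#' @export
update_centers <- function(U, A, values, M, Q) {
  values <- as.matrix(values)
  W <- A^Q * U^M
  denom <- colSums(W)
  if (any(denom <= 0)) {
    stop("update_centers: degenerate cluster ", which(denom <= 0)[1],
         " (zero total weight)")
  }
  V <- t(W) %*% values / denom
  V
}

#' FPCM tissue segmentation
#'
#' Alternates fuzzy and possibilistic membership updates with centre updates
#' until the objective changes by less than `epsilon` between successive
#' iterations, or `max_iter` is reached (in which case a `converged = FALSE`
#' flag is set with a warning, not an error). Each voxel's final label is
#' `argmax_C U[i,C] * alpha[i,C]`; out-of-mask voxels get label 0. Clusters
#' are sorted by ascending centre intensity before labelling, so label ids
#' are deterministic (1 = darkest tissue, e.g. CSF, upwards through GM/WM).
#'
#' eta is estimated once from an initial fuzzy-only pass
#' (see [estimate_eta()]) unless supplied numerically in `params`.
#'
#' @param vol a [volume_image()], or a numeric vector of voxel values.
#' @param mask logical array (same shape) of in-brain voxels; defaults to
#'   all voxels (or positive voxels if `mask = "positive"`).
#' @param params list of FPCM parameters: `c` clusters, `M`, `Q`, `eta`
#'   (`"auto"` or numeric), `eta_scale`, `epsilon`, `max_iter`, `init`,
#'   `seed` — see the `fpcm` block of [pipeline_config()].
#' @return A list with `labels` (a [label_volume()]; absent when `vol` is a
#'   bare vector, replaced by `label_vector`) and `state` (class
#'   `fpcm_state`: U, A, V, objective trace, iterations, convergence flag).
#' @export
fpcm_segment <- function(vol, mask = NULL, params = pipeline_config()$fpcm) {
  p <- utils::modifyList(pipeline_config()$fpcm, as.list(params))
  if (p$c < 1) stop("fpcm_segment: c must be >= 1")
  if (p$M <= 1 || p$Q <= 1) stop("fpcm_segment: M and Q must be > 1")
  if (p$epsilon <= 0) stop("fpcm_segment: epsilon must be > 0")
  is_vol <- inherits(vol, "volume_image")
  if (is_vol) {
    x <- vol$data
    if (is.null(mask)) mask <- array(TRUE, dim(x))
    if (identical(mask, "positive")) mask <- x > 0
    if (inherits(mask, "brain_mask")) mask <- mask$mask
    values <- matrix(x[mask], ncol = 1)
  } else {
    values <- as.matrix(vol)
    mask <- NULL
  }
  if (nrow(values) == 0) stop("fpcm_segment: empty mask")
  seed <- if (is.null(p$seed)) 1L else p$seed

  if (p$c == 1) {
    V <- matrix(colMeans(values), nrow = 1)
    U <- matrix(1, nrow(values), 1)
    eta <- estimate_eta(U, values, V, p$M, p$eta_scale,
                        floor_degenerate = TRUE)
    A <- update_possibilistic_memberships(values, V, p$Q, eta)
    V <- update_centers(U, A, values, p$M, p$Q)
    state <- new_fpcm_state(U, A, V, eta,
                            fpcm_objective(U, A, values, V, p$M, p$Q),
                            1L, TRUE, p)
    return(finish_fpcm(vol, mask, U, A, V, state, is_vol))
  }

  V <- init_centers(values, p$c,
                    seed = seed,
                    method = if (p$init == "kmeanspp") "kmeanspp"
                             else "quantile")
  # initial fuzzy-only passes to stabilise centres, then fix eta
  for (i in 1:5) {
    U <- update_fuzzy_memberships(values, V, p$M)
    W <- U^p$M
    V <- t(W) %*% values / colSums(W)
  }
  U <- update_fuzzy_memberships(values, V, p$M)
  eta <- if (identical(p$eta, "auto")) {
    estimate_eta(U, values, V, p$M, p$eta_scale, floor_degenerate = TRUE)
  } else rep_len(as.numeric(p$eta), p$c)

  trace <- numeric(0)
  prev_J <- Inf
  converged <- FALSE
  iters <- 0L
  A <- update_possibilistic_memberships(values, V, p$Q, eta)
  for (k in seq_len(p$max_iter)) {
    U <- update_fuzzy_memberships(values, V, p$M)
    A <- update_possibilistic_memberships(values, V, p$Q, eta)
    Vc <- update_centers(U, A, values, p$M, p$Q)
    # monotone safeguard: the printed centre update is not an exact
    # coordinate minimiser of the printed objective, so step towards it
    # only as far as the objective does not increase; an unavoidable
    # uptick is treated as convergence
    step <- 1
    J <- NA_real_
    accepted <- FALSE
    for (try in 1:8) {
      Vt <- V + step * (Vc - V)
      Jt <- fpcm_objective(U, A, values, Vt, p$M, p$Q)
      if (Jt <= prev_J + 1e-12) {
        V <- Vt
        J <- Jt
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      converged <- TRUE
      break
    }
    trace <- c(trace, J)
    iters <- k
    if (is.finite(prev_J) && abs(prev_J - J) < p$epsilon) {
      converged <- TRUE
      prev_J <- J
      break
    }
    prev_J <- J
  }
  U <- update_fuzzy_memberships(values, V, p$M)
  A <- update_possibilistic_memberships(values, V, p$Q, eta)
  if (!converged) {
    warning("fpcm_segment: did not converge in ", p$max_iter, " iterations")
  }
  # deterministic cluster identity: ascending centre intensity
  ord <- order(V[, 1])
  V <- V[ord, , drop = FALSE]
  U <- U[, ord, drop = FALSE]
  A <- A[, ord, drop = FALSE]
  eta <- eta[ord]
  state <- new_fpcm_state(U, A, V, eta, trace, iters, converged, p)
  finish_fpcm(vol, mask, U, A, V, state, is_vol)
}

new_fpcm_state <- function(U, A, V, eta, trace, iters, converged, params) {
  structure(
    list(U = U, A = A, V = V, eta = eta, objective_trace = trace,
         iterations_run = iters, converged = converged, params = params),
    class = "fpcm_state")
}

finish_fpcm <- function(vol, mask, U, A, V, state, is_vol) {
  lab <- max.col(U * state$A, ties.method = "first")
  if (is_vol) {
    labs <- array(0L, dim(vol$data))
    labs[mask] <- lab
    legend <- stats::setNames(paste0("tissue_", seq_len(nrow(V))),
                              seq_len(nrow(V)))
    lv <- label_volume(labs, legend = legend, spacing = vol$spacing,
                       affine = vol$affine,
                       meta = c(vol$meta, list(steps = "fpcm_segment")))
    list(labels = lv, state = state)
  } else {
    list(label_vector = lab, state = state)
  }
}

#' @export
print.fpcm_state <- function(x, ...) {
  cat("<fpcm_state> c =", nrow(x$V), "| iterations =", x$iterations_run,
      "| converged =", x$converged, "\n")
  cat("  centres:", paste(signif(x$V[, 1], 5), collapse = ", "), "\n")
  invisible(x)
}
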