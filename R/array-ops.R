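# Vectorised array utilities shared by the preprocessing and feature stages.
# Everything here works on plain 2-D or 3-D arrays; masks are logical arrays.

# Shift an array by integer offsets (one per axis), filling vacated cells.
shift_array <- function(a, offset, fill = 0) {
  d <- dim(a)
  nd <- length(d)
  offset <- rep_len(as.integer(offset), nd)
  idx <- vector("list", nd)
  src <- vector("list", nd)
  for (ax in seq_len(nd)) {
    o <- offset[ax]
    n <- d[ax]
    if (abs(o) >= n) return(array(fill, d))
    # destination i receives source i - o
    src[[ax]] <- seq_len(n) - o
  }
  out <- array(fill, d)
  dst <- lapply(seq_len(nd), function(ax) {
    which(src[[ax]] >= 1 & src[[ax]] <= d[ax])
  })
  srcv <- lapply(seq_len(nd), function(ax) src[[ax]][dst[[ax]]])
  if (nd == 2) {
    out[dst[[1]], dst[[2]]] <- a[srcv[[1]], srcv[[2]]]
  } else {
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[srcv[[1]], srcv[[2]], srcv[[3]]]
  }
  out
}

# Offsets inside a Euclidean ball of the given radius (in voxels).
ball_offsets <- function(radius, nd) {
  r <- max(0L, as.integer(floor(radius)))
  rng <- -r:r
  grid <- if (nd == 2) expand.grid(rng, rng) else expand.grid(rng, rng, rng)
  keep <- rowSums(grid^2) <= radius^2 + 1e-9
  as.matrix(grid[keep, , drop = FALSE])
}

binary_dilate <- function(mask, radius = 1) {
  offs <- ball_offsets(radius, length(dim(mask)))
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offs))) {
    out <- out | shift_array(mask, offs[i, ], fill = FALSE)
  }
  out
}

binary_erode <- function(mask, radius = 1) {
  offs <- ball_offsets(radius, length(dim(mask)))
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(offs))) {
    out <- out & shift_array(mask, offs[i, ], fill = FALSE)
  }
  out
}

binary_close <- function(mask, radius = 1) {
  binary_erode(binary_dilate(mask, radius), radius)
}

# Face-connected (4/6-neighbour) unit shifts.
face_offsets <- function(nd) {
  offs <- matrix(0L, nrow = 2 * nd, ncol = nd)
  for (ax in seq_len(nd)) {
    offs[2 * ax - 1, ax] <- 1L
    offs[2 * ax, ax] <- -1L
  }
  offs
}

# Grow a seed region inside `mask` to its full connected component(s),
# face connectivity; vectorised frontier expansion.
flood_grow <- function(seed, mask) {
  offs <- face_offsets(length(dim(mask)))
  cur <- seed & mask
  repeat {
    nxt <- cur
    for (i in seq_len(nrow(offs))) {
      nxt <- nxt | shift_array(cur, offs[i, ], fill = FALSE)
    }
    nxt <- nxt & mask
    if (!any(nxt & !cur)) break
    cur <- nxt
  }
  cur
}

# Label face-connected components; returns an integer array (0 background).
label_components <- function(mask) {
  out <- array(0L, dim(mask))
  remaining <- mask
  lab <- 0L
  while (any(remaining)) {
    lab <- lab + 1L
    seedpos <- which(remaining)[1]
    seed <- array(FALSE, dim(mask))
    seed[seedpos] <- TRUE
    comp <- flood_grow(seed, remaining)
    out[comp] <- lab
    remaining <- remaining & !comp
  }
  out
}

largest_component <- function(mask) {
  labs <- label_components(mask)
  if (max(labs) == 0L) return(mask & FALSE)
  counts <- tabulate(labs[labs > 0L])
  labs == which.max(counts)
}

# Fill interior holes: background connected to the array border stays
# background; enclosed background becomes foreground.
fill_holes <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  border <- array(FALSE, d)
  if (nd == 2) {
    border[c(1, d[1]), ] <- TRUE
    border[, c(1, d[2])] <- TRUE
  } else {
    border[c(1, d[1]), , ] <- TRUE
    border[, c(1, d[2]), ] <- TRUE
    border[, , c(1, d[3])] <- TRUE
  }
  bg <- !mask
  outside <- flood_grow(border & bg, bg)
  mask | (bg & !outside)
}

# Otsu's threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(x, nbins = 256) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = nbins + 1),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Two-threshold (three-class) Otsu; returns the pair of thresholds that
# maximises between-class variance. For skull stripping the lower threshold
# is the background/tissue split even when several tissue modes are present.
otsu_threshold2 <- function(x, nbins = 128) {
  rng <- range(x)
  if (diff(rng) == 0) return(c(rng[1], rng[1]))
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = nbins + 1),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  cw <- c(0, cumsum(p))
  cm <- c(0, cumsum(p * mids))
  best <- -Inf; bt <- c(mids[1], mids[2])
  for (i in 1:(nbins - 2)) {
    for (j in (i + 1):(nbins - 1)) {
      w1 <- cw[i + 1]; w2 <- cw[j + 1] - cw[i + 1]; w3 <- 1 - cw[j + 1]
      if (w1 == 0 || w2 == 0 || w3 == 0) next
      m1 <- cm[i + 1] / w1
      m2 <- (cm[j + 1] - cm[i + 1]) / w2
      m3 <- (cm[nbins + 1] - cm[j + 1]) / w3
      v <- w1 * m1^2 + w2 * m2^2 + w3 * m3^2
      if (v > best) { best <- v; bt <- c(mids[i], mids[j]) }
    }
  }
  bt
}

# FFT Gaussian blur with replicate edge padding; sigma in voxels per axis.
gauss_blur <- function(a, sigma) {
  d <- dim(a)
  nd <- length(d)
  sigma <- rep_len(sigma, nd)
  pad <- pmin(d - 1L, pmax(1L, ceiling(3 * sigma)))
  ap <- pad_replicate(a, pad)
  dp <- dim(ap)
  # separable Gaussian kernel, wrapped so its centre sits at index 1
  kern1 <- lapply(seq_len(nd), function(ax) {
    n <- dp[ax]
    pos <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-pos^2 / (2 * sigma[ax]^2))
    k / sum(k)
  })
  kern <- kern1[[1]]
  if (nd >= 2) kern <- outer(kern, kern1[[2]])
  if (nd == 3) kern <- outer(kern, kern1[[3]])
  kern <- array(kern, dp)
  sm <- Re(stats::fft(stats::fft(ap) * stats::fft(kern), inverse = TRUE)) /
    prod(dp)
  unpad(sm, pad, d)
}

pad_replicate <- function(a, pad) {
  d <- dim(a)
  nd <- length(d)
  idx <- lapply(seq_len(nd), function(ax) {
    pmin(pmax(seq_len(d[ax] + 2 * pad[ax]) - pad[ax], 1L), d[ax])
  })
  if (nd == 2) a[idx[[1]], idx[[2]]] else a[idx[[1]], idx[[2]], idx[[3]]]
}

unpad <- function(a, pad, d) {
  nd <- length(d)
  idx <- lapply(seq_len(nd), function(ax) pad[ax] + seq_len(d[ax]))
  if (nd == 2) a[idx[[1]], idx[[2]]] else a[idx[[1]], idx[[2]], idx[[3]]]
}

# Voxel coordinate grids (0-based), one matrix column per axis.
voxel_grid <- function(d) {
  nd <- length(d)
  if (nd == 2) {
    cbind(
      X = rep(seq_len(d[1]) - 1L, times = d[2]),
      Y = rep(seq_len(d[2]) - 1L, each = d[1])
    )
  } else {
    cbind(
      X = rep(seq_len(d[1]) - 1L, times = d[2] * d[3]),
      Y = rep(rep(seq_len(d[2]) - 1L, each = d[1]), times = d[3]),
      Z = rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
    )
  }
}
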