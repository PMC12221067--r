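#' Local binary pattern histogram
#'
#' For every interior masked pixel (its full 8-neighbourhood inside the
#' image), the LBP code compares each of the 8 neighbours with the centre:
#' bit N is 1 iff neighbour_N >= centre, neighbours ordered clockwise
#' starting at the top-left, weighted 2^N (N = 0..7). The 256-bin histogram
#' of codes is normalised to sum 1. The code depends only on intensity
#' *orderings*, so the histogram is invariant under adding a constant or any
#' monotone increasing intensity map.
#'
#' @param image 2-D numeric matrix (rows = x, columns = y; "top-left" is
#'   the (-1, -1) neighbour).
#' @param mask logical matrix of pixels to encode; defaults to the whole
#'   image.
#' @return Numeric vector of length 256 (bins for codes 0..255). If the
#'   masked interior is empty, an all-zero histogram with a warning.
#' @export
lbp_histogram <- function(image, mask = NULL) {
  stopifnot(is.matrix(image))
  if (is.null(mask)) mask <- array(TRUE, dim(image))
  d <- dim(image)
  interior <- mask
  interior[c(1, d[1]), ] <- FALSE
  interior[, c(1, d[2])] <- FALSE
  hist <- numeric(256)
  if (!any(interior)) {
    warning("lbp_histogram: empty masked interior; all-zero histogram")
    return(hist)
  }
  # clockwise from top-left: TL, T, TR, R, BR, B, BL, L
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- array(0, d)
  for (n in seq_len(8)) {
    nb <- shift_array(image, -offs[n, ], fill = 0)  # value at pixel+off
    code <- code + (nb >= image) * 2^(n - 1)
  }
  tab <- tabulate(code[interior] + 1, nbins = 256)
  tab / sum(tab)
}

#' Colour (intensity) moments
#'
#' First three moments of the region's intensity distribution with
#' population (1/n) normalisation: the mean m1, the population variance m2,
#' and the raw third central moment m3 (not standardised skewness). MRI is
#' single-channel, so "colour" operates on grayscale intensity.
#'
#' @param values numeric vector of region intensities (nonempty).
#' @return Named numeric vector `c(m1, m2, m3)`.
#' @export
color_moments <- function(values) {
  if (!length(values)) stop("color_moments: empty region")
  n <- length(values)
  m1 <- mean(values)
  d <- values - m1
  c(m1 = m1, m2 = sum(d^2) / n, m3 = sum(d^3) / n)
}

#' Shape descriptors of a 2-D binary region
#'
#' Computed on the largest 4-connected component of the mask:
#' * `area` — foreground pixel count;
#' * `perimeter` — count of foreground pixels with at least one background
#'   4-neighbour (the image border counts as background);
#' * `eccentricity` — C/A with A >= B the semi-axes of the ellipse with the
#'   same second central moments as the pixel coordinates (A = 2*sqrt(l1)),
#'   C = sqrt(A^2 - B^2). Each pixel contributes its unit-square extent
#'   (+1/12 per coordinate variance), which keeps eccentricity strictly
#'   below 1 even for one-pixel-wide lines and makes a single pixel
#'   perfectly round (eccentricity 0);
#' * `compactness` — perimeter^2 / area (boundary-pixel-count convention,
#'   not an arc-length estimate).
#'
#' @param mask logical or 0/1 matrix with at least one foreground pixel.
#' @return Named numeric vector `c(area, perimeter, eccentricity,
#'   compactness)`.
#' @export
shape_features <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask)) stop("shape_features: empty mask")
  comp <- largest_component(mask)
  area <- sum(comp)
  bg_nbr <- array(FALSE, dim(comp))
  for (off in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    bg_nbr <- bg_nbr | !shift_array(comp, -off, fill = FALSE)
  }
  perimeter <- sum(comp & bg_nbr)
  coords <- which(comp, arr.ind = TRUE) - 1
  n <- nrow(coords)
  mu <- colMeans(coords)
  cc <- sweep(coords, 2, mu)
  cov <- crossprod(cc) / n + diag(1 / 12, 2)  # unit-square pixel extent
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))
  c(area = area, perimeter = perimeter, eccentricity = ecc,
    compactness = perimeter^2 / area)
}

#' Extract the full per-region feature set from a volume
#'
#' For each region mask, features are computed on the region's mid slice
#' along `slice_axis` (the median of the slice indices where the region is
#' present): the 256-bin LBP histogram, the three intensity moments, and
#' the four shape descriptors, flattened with deterministic names
#' `r<id>_lbp<k>`, `r<id>_m1..m3`, `r<id>_area/perimeter/eccentricity/
#' compactness`. A region absent on every slice contributes `NA` sentinels
#' (logged as a warning).
#'
#' @param vol a [volume_image()].
#' @param region_masks named list of logical arrays (as from
#'   [region_masks()]); names are region ids.
#' @param slice_axis axis treated as the slice direction (default 3).
#' @param sample_id row id for the resulting one-row table.
#' @return A one-row [feature_table()] (no label column).
#' @export
extract_features <- function(vol, region_masks, slice_axis = 3,
                             sample_id = "s1") {
  stopifnot(inherits(vol, "volume_image"))
  vals <- list()
  for (rid in names(region_masks)) {
    m <- region_masks[[rid]]
    fnames <- feature_names_for(rid)
    if (!any(m)) {
      warning("extract_features: region ", rid, " empty; NA sentinels")
      vals[[rid]] <- stats::setNames(rep(NA_real_, length(fnames)), fnames)
      next
    }
    if (length(dim(m)) == 3) {
      present <- which(apply(m, slice_axis, any))
      z <- present[ceiling(length(present) / 2)]
      sl_img <- slice_along(vol$data, slice_axis, z)
      sl_msk <- slice_along(m, slice_axis, z)
    } else {
      sl_img <- vol$data
      sl_msk <- m
    }
    lbp <- suppressWarnings(lbp_histogram(sl_img, sl_msk))
    mom <- color_moments(sl_img[sl_msk])
    shp <- shape_features(sl_msk)
    vals[[rid]] <- stats::setNames(c(lbp, mom, shp), fnames)
  }
  v <- unlist(vals, use.names = FALSE)
  nm <- unlist(lapply(names(region_masks), feature_names_for))
  feature_table(matrix(v, nrow = 1, dimnames = list(NULL, nm)),
                sample_ids = sample_id, allow_missing = TRUE)
}

feature_names_for <- function(rid) {
  c(paste0("r", rid, "_lbp", 0:255),
    paste0("r", rid, "_", c("m1", "m2", "m3")),
    paste0("r", rid, "_", c("area", "perimeter", "eccentricity",
                            "compactness")))
}

slice_along <- function(a, axis, z) {
  switch(axis,
         `1` = a[z, , ],
         `2` = a[, z, ],
         `3` = a[, , z])
}
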