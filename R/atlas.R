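#' Atlas reference
#'
#' Bundles an atlas label volume with the 4x4 affine `affine_h` mapping
#' subject voxel coordinates (0-based) to atlas voxel coordinates, plus the
#' region legend. Any label volume can stand in for the anatomical template;
#' the toy atlas from [make_toy_atlas()] flags one block as the
#' temporal-lobe-like region of interest.
#'
#' @param labels a [label_volume()] in atlas space.
#' @param affine_h invertible 4x4 subject-voxel-to-atlas-voxel transform
#'   (identity by default).
#' @param legend label id -> region name mapping; defaults to the label
#'   volume's legend.
#' @return An object of class `atlas_ref`.
#' @export
atlas_ref <- function(labels, affine_h = diag(4), legend = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  affine_h <- as.matrix(affine_h)
  if (!all(dim(affine_h) == c(4, 4)) ||
      abs(det(affine_h)) < .Machine$double.eps) {
    stop("atlas_ref: affine_h must be an invertible 4x4 matrix")
  }
  if (is.null(legend)) legend <- labels$legend
  present <- setdiff(unique(as.integer(labels$labels)), 0L)
  if (length(setdiff(present, as.integer(names(legend))))) {
    stop("atlas_ref: legend must cover all nonzero atlas labels")
  }
  structure(list(labels = labels, affine_h = affine_h, legend = legend),
            class = "atlas_ref")
}

#' Anatomical labelling by atlas transfer
#'
#' For every in-brain voxel (X, Y, Z) of the segmentation, applies the
#' affine `h` to obtain atlas coordinates, samples the atlas label by
#' nearest neighbour (labels are categorical), and assigns that region id.
#' Coordinates falling outside the atlas grid map to 0. Also returns a
#' per-(region x tissue class) voxel count table.
#'
#' @param seg a [label_volume()] tissue segmentation (0 = out of brain).
#' @param atlas an [atlas_ref()].
#' @return A list with `regions` (a [label_volume()] of region ids) and
#'   `stats` (tibble: region_id, region, tissue, voxels).
#' @export
aal_label <- function(seg, atlas) {
  stopifnot(inherits(seg, "label_volume"), inherits(atlas, "atlas_ref"))
  d <- dim(seg$labels)
  if (length(d) != 3) stop("aal_label: expected a 3-D segmentation")
  ad <- dim(atlas$labels$labels)
  coords <- voxel_grid(d)                       # 0-based subject voxels
  hom <- cbind(coords, 1) %*% t(atlas$affine_h) # rows: (X', Y', Z', 1)
  ai <- round(hom[, 1:3])                       # nearest-neighbour sample
  inside <- ai[, 1] >= 0 & ai[, 1] < ad[1] &
            ai[, 2] >= 0 & ai[, 2] < ad[2] &
            ai[, 3] >= 0 & ai[, 3] < ad[3]
  inbrain <- as.vector(seg$labels) > 0L
  if (any(inbrain) && !any(inside & inbrain)) {
    stop("aal_label: every in-brain voxel maps outside the atlas; ",
         "check the affine/shape")
  }
  region <- integer(prod(d))
  sel <- inside & inbrain
  lin <- 1L + ai[sel, 1] + ad[1] * (ai[sel, 2] + ad[2] * ai[sel, 3])
  region[sel] <- as.vector(atlas$labels$labels)[lin]
  regions <- label_volume(array(region, d), legend = atlas$legend,
                          spacing = seg$spacing, affine = seg$affine)
  ids <- sort(as.integer(names(atlas$legend)))
  tissues <- sort(setdiff(unique(as.integer(seg$labels)), 0L))
  stats <- tidyr::expand_grid(region_id = ids, tissue = tissues)
  stats$region <- unname(atlas$legend[as.character(stats$region_id)])
  stats$voxels <- purrr::map2_int(stats$region_id, stats$tissue,
    function(r, t) sum(region == r & as.vector(seg$labels) == t))
  list(regions = regions,
       stats = stats[, c("region_id", "region", "tissue", "voxels")])
}

#' Binary masks for requested regions
#'
#' @param labeled a [label_volume()] of region ids.
#' @param roi_ids integer ids to extract; must all appear in the legend.
#' @return Named list of logical arrays, one per requested id; masks are
#'   pairwise disjoint and their union covers exactly the voxels carrying
#'   those ids.
#' @export
region_masks <- function(labeled, roi_ids) {
  stopifnot(inherits(labeled, "label_volume"))
  known <- as.integer(names(labeled$legend))
  bad <- setdiff(as.integer(roi_ids), known)
  if (length(bad)) {
    stop("region_masks: unknown region id(s) ", paste(bad, collapse = ", "),
         "; known ids: ", paste(known, collapse = ", "))
  }
  out <- lapply(as.integer(roi_ids), function(id) labeled$labels == id)
  names(out) <- as.character(roi_ids)
  out
}
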