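#' Volume image container
#'
#' A `volume_image` is a light S3 wrapper around a 2-D or 3-D numeric array
#' of voxel intensities, together with the per-axis voxel spacing in mm, a
#' 4x4 voxel-to-world affine (NIfTI convention, 0-based voxel indices) and a
#' free-form provenance record listing the processing steps applied so far.
#'
#' @param data numeric array with 2 or 3 axes.
#' @param spacing numeric vector of per-axis voxel sizes in mm (strictly
#'   positive); recycled to the number of axes if length 1.
#' @param affine 4x4 voxel-to-world matrix; must be invertible. Defaults to
#'   a diagonal affine built from `spacing`.
#' @param meta named list of provenance entries (source path, steps).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing = 1, affine = NULL, meta = list()) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L)) {
    stop("volume_image data must have 2 or 3 axes, got ", nd)
  }
  if (!is.numeric(data)) stop("volume_image data must be numeric")
  data <- array(as.double(data), dim(data))  # drop any foreign attributes
  spacing <- rep_len(as.numeric(spacing), nd)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be strictly positive and finite")
  }
  if (is.null(affine)) {
    affine <- diag(c(spacing, rep(1, 4 - nd)))
    affine[4, 4] <- 1
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
  structure(
    list(data = data, spacing = spacing, affine = affine, meta = meta),
    class = "volume_image"
  )
}

#' Label volume container
#'
#' Integer-labelled grid with the same geometry conventions as
#' [volume_image()]. Label 0 is background by definition; every nonzero
#' label must appear in the legend.
#'
#' @param labels integer array (2 or 3 axes) of non-negative region labels.
#' @param legend named character vector or list mapping label id (as the
#'   name) to region name.
#' @param spacing,affine,meta as in [volume_image()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, legend = NULL, spacing = 1, affine = NULL,
                         meta = list()) {
  labels <- as.array(labels)
  if (any(!is.finite(labels)) || any(labels < 0) ||
      any(labels != round(labels))) {
    stop("labels must be non-negative integers")
  }
  labels <- array(as.integer(labels), dim(labels))
  present <- sort(unique(as.integer(labels)))
  present <- present[present != 0L]
  if (is.null(legend)) {
    legend <- stats::setNames(paste0("region_", present), present)
  }
  legend <- unlist(legend)
  missing_ids <- setdiff(present, as.integer(names(legend)))
  if (length(missing_ids)) {
    stop("labels present but absent from legend: ",
         paste(missing_ids, collapse = ", "))
  }
  vol <- volume_image(array(0, dim(labels)), spacing = spacing,
                      affine = affine, meta = meta)
  structure(
    list(labels = labels, legend = legend, spacing = vol$spacing,
         affine = vol$affine, meta = meta),
    class = "label_volume"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$data), collapse = " x "),
      " | spacing ", paste(signif(x$spacing, 4), collapse = " x "), " mm\n",
      sep = "")
  cat("  intensity range [", signif(min(x$data), 5), ", ",
      signif(max(x$data), 5), "]\n", sep = "")
  if (length(x$meta$steps)) {
    cat("  steps:", paste(x$meta$steps, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "),
      " | ", length(x$legend), " region(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$data)

#' @export
dim.label_volume <- function(x) dim(x$labels)

record_step <- function(vol, step) {
  vol$meta$steps <- c(vol$meta$steps, step)
  vol
}

#' Read a volume from disk
#'
#' Reads NIfTI-1 files (`.nii`, `.nii.gz`) via RNifti, or a stack of
#' single-channel 2-D slices (PNG or TIFF). A slice stack is given either as
#' a directory or as a character vector of file paths; files are ordered
#' lexicographically by filename and stacked along the third axis, with unit
#' spacing and identity affine. Multi-channel (colour) slices are rejected.
#'
#' @param path path to a NIfTI file, a directory of PNG/TIFF slices, or a
#'   character vector of slice paths.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  if (length(path) == 1L && !file.exists(path)) {
    stop("read_volume: path does not exist: ", path)
  }
  if (length(path) == 1L && dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (!length(files)) stop("read_volume: no PNG/TIFF slices in ", path)
    return(read_slice_stack(sort(files)))
  }
  if (length(path) > 1L) {
    missing <- path[!file.exists(path)]
    if (length(missing)) stop("read_volume: path does not exist: ", missing[1])
    return(read_slice_stack(sort(path)))
  }
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    dat <- as.array(img)
    nd <- length(dim(dat))
    if (nd > 3L) stop("read_volume: expected a 2-D/3-D volume, got ", nd,
                      " axes in ", path)
    pix <- RNifti::pixdim(img)
    affine <- tryCatch(unclass(RNifti::xform(img)),
                       error = function(e) NULL)
    volume_image(dat, spacing = pix[seq_len(nd)], affine = affine,
                 meta = list(source = path))
  } else if (grepl("\\.(png|tif|tiff)$", lower)) {
    read_slice_stack(path)
  } else {
    stop("read_volume: unsupported format for ", path,
         " (expected .nii, .nii.gz, .png, .tif)")
  }
}

read_one_slice <- function(p) {
  lower <- tolower(p)
  img <- if (grepl("\\.png$", lower)) {
    png::readPNG(p)
  } else {
    tiff::readTIFF(p)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) {
      img <- img[, , 1]
    } else {
      stop("read_volume: expected grayscale slice, got ", dim(img)[3],
           " channels in ", p)
    }
  }
  img
}

read_slice_stack <- function(files) {
  slices <- lapply(files, read_one_slice)
  d <- dim(slices[[1]])
  ok <- vapply(slices, function(s) all(dim(s) == d), logical(1))
  if (!all(ok)) stop("read_volume: slice shapes differ across the stack")
  dat <- array(unlist(slices), dim = c(d, length(slices)))
  if (length(files) == 1L) dat <- array(dat, dim = d)
  volume_image(dat, spacing = 1, meta = list(source = files))
}

#' Write a volume or label volume to disk
#'
#' Writes NIfTI-1. Label volumes are written with an integer datatype, and
#' their legend is written to a JSON sidecar `<path>.labels.json`.
#'
#' @param vol a [volume_image()] or [label_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path))) {
    stop("write_volume: parent directory does not exist: ", dirname(path))
  }
  as_img <- function(data, datatype, spacing, affine) {
    nd <- length(dim(data))
    ref <- list(pixdim = c(-1, spacing, rep(1, 7 - nd)))
    img <- RNifti::asNifti(data, reference = ref, datatype = datatype)
    RNifti::`sform<-`(img, structure(affine, code = 2L))
  }
  if (inherits(vol, "label_volume")) {
    img <- as_img(vol$labels, "int32", vol$spacing, vol$affine)
    RNifti::writeNifti(img, path)
    sidecar <- paste0(path, ".labels.json")
    jsonlite::write_json(as.list(vol$legend), sidecar, auto_unbox = TRUE,
                         pretty = TRUE)
  } else if (inherits(vol, "volume_image")) {
    img <- as_img(vol$data, "double", vol$spacing, vol$affine)
    RNifti::writeNifti(img, path)
  } else {
    stop("write_volume: expected volume_image or label_volume")
  }
  invisible(path)
}

#' Read a label volume and its legend sidecar
#'
#' @param path path to a NIfTI label file written by [write_volume()].
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  vol <- read_volume(path)
  sidecar <- paste0(path, ".labels.json")
  legend <- NULL
  if (file.exists(sidecar)) {
    legend <- unlist(jsonlite::read_json(sidecar))
  }
  label_volume(round(vol$data), legend = legend, spacing = vol$spacing,
               affine = vol$affine, meta = vol$meta)
}
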