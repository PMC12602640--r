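#' Construct a 3D scalar volume
#'
#' A `replica_volume` is the unit of comparison in the framework: a 3D voxel
#' grid of finite scalar intensities on a physical grid. Volumes entering a
#' comparison must share shape and spacing; the package never resamples.
#'
#' @param data Numeric 3D array of voxel intensities; all values finite.
#' @param spacing Numeric length-3 vector, millimetres per voxel along each
#'   axis; strictly positive and finite.
#' @param id Stable string identifier for the volume.
#' @param affine Optional 4x4 grid-to-world matrix. Carried through on
#'   read/write but never used in metric computation; all distances are
#'   computed in voxel-grid space scaled by `spacing`.
#' @return An object of class `replica_volume`.
#' @examples
#' v <- volume(array(stats::runif(8 * 8 * 4), c(8, 8, 4)), id = "demo")
#' dim(v$data)
#' @export
volume <- function(data, spacing = c(1, 1, 1), id = "volume", affine = NULL) {
  data <- validate_grid(data, what = "volume", id = id)
  if (!is.numeric(data) || !all(is.finite(data))) {
    abort(sprintf("volume '%s': all voxel values must be finite numbers", id),
          class = "replicheck_nonfinite")
  }
  spacing <- validate_spacing(spacing, id)
  structure(
    list(data = data, spacing = spacing, id = as.character(id),
         affine = affine),
    class = "replica_volume"
  )
}

#' Construct a segmentation mask
#'
#' A `replica_segmask` holds integer labels on the same grid contract as
#' [volume()]: label 0 is background, positive labels are structures of
#' interest (e.g. a haemorrhage lesion, artery segments).
#'
#' @param labels 3D array of non-negative integers.
#' @param spacing,id As in [volume()].
#' @param label_names Optional named character vector mapping label value to
#'   an anatomical/pathological name, e.g. `c("1" = "ICH")`.
#' @return An object of class `replica_segmask`.
#' @export
seg_mask <- function(labels, spacing = c(1, 1, 1), id = "mask",
                     label_names = NULL) {
  labels <- validate_grid(labels, what = "mask", id = id)
  if (!all(is.finite(labels)) || any(labels < 0) ||
      any(labels != round(labels))) {
    abort(sprintf("mask '%s': labels must be finite non-negative integers", id),
          class = "replicheck_bad_labels")
  }
  spacing <- validate_spacing(spacing, id)
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, spacing = spacing, id = as.character(id),
         label_names = label_names),
    class = "replica_segmask"
  )
}

validate_grid <- function(x, what, id) {
  if (!is.array(x)) abort(sprintf("%s '%s': expected an array", what, id))
  d <- dim(x)
  # squeeze a singleton trailing 4th axis (common NIfTI dialect)
  if (length(d) == 4L && d[4] == 1L) {
    x <- array(x, d[1:3])
    d <- dim(x)
  }
  if (length(d) != 3L || any(d < 1L)) {
    abort(sprintf("%s '%s': data must have exactly 3 axes (got %s)",
                  what, id, paste(d, collapse = "x")),
          class = "replicheck_not_3d")
  }
  x
}

validate_spacing <- function(spacing, id) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    abort(sprintf("'%s': spacing must be 3 strictly positive finite values", id),
          class = "replicheck_bad_spacing")
  }
  spacing
}

#' @export
print.replica_volume <- function(x, ...) {
  cat(sprintf("<replica_volume '%s'> %s voxels @ %s mm\n", x$id,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
print.replica_segmask <- function(x, ...) {
  labs <- sort(unique(as.vector(x$labels)))
  cat(sprintf("<replica_segmask '%s'> %s voxels, labels: %s\n", x$id,
              paste(dim(x$labels), collapse = "x"),
              paste(labs, collapse = ", ")))
  invisible(x)
}

#' Read a volume or segmentation mask from a NIfTI-1 file
#'
#' Reads a 3D scalar NIfTI image (a singleton 4th axis is squeezed). Voxel
#' spacing comes from the header; the affine is preserved but not
#' interpreted. The id defaults to the file stem (`sub-01.nii.gz` ->
#' `sub-01`).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param id Identifier; default file stem.
#' @return [read_volume()] a `replica_volume`; [read_seg_mask()] a
#'   `replica_segmask`.
#' @export
read_volume <- function(path, id = NULL) {
  payload <- read_nifti_payload(path)
  id <- id %||% nifti_stem(path)
  if (!all(is.finite(payload$data))) {
    abort(sprintf("non-finite voxel values in '%s'", path),
          class = "replicheck_nonfinite")
  }
  volume(payload$data, spacing = payload$spacing, id = id,
         affine = payload$affine)
}

#' @rdname read_volume
#' @export
read_seg_mask <- function(path, id = NULL) {
  payload <- read_nifti_payload(path)
  id <- id %||% nifti_stem(path)
  seg_mask(round(payload$data), spacing = payload$spacing, id = id)
}

read_nifti_payload <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read '%s': no such file", path),
          class = "replicheck_unreadable")
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    abort(sprintf("cannot read '%s' as NIfTI: %s", path,
                                  conditionMessage(e)),
                          class = "replicheck_unreadable")
                  })
  d <- dim(img)
  dat <- array(as.numeric(img), d)  # strip niftiImage attributes
  if (length(d) == 4L && d[4] == 1L) dat <- array(dat, d[1:3])
  if (length(dim(dat)) != 3L) {
    abort(sprintf("'%s': expected a 3D image, got %s axes after squeezing",
                  path, length(dim(dat))),
          class = "replicheck_not_3d")
  }
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  affine <- tryCatch(structure(RNifti::xform(img), class = "matrix"),
                     error = function(e) NULL)
  list(data = dat, spacing = spacing, affine = affine)
}

nifti_stem <- function(path) {
  sub("\\.nii(\\.gz)?$", "", basename(path))
}

#' Write a volume or mask to NIfTI-1
#'
#' @param x A `replica_volume` or `replica_segmask`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  dat <- if (inherits(x, "replica_segmask")) x$labels else x$data
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
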