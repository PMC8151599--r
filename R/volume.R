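#' Tissue class codes
#'
#' Integer label codes used throughout the package: 0 = background,
#' 1 = cerebrospinal fluid (CSF), 2 = gray matter (GM), 3 = white matter (WM).
#'
#' @format Named integer vector of length 4.
#' @export
CLASS_CODES <- c(background = 0L, csf = 1L, gm = 2L, wm = 3L)

#' Create an intensity volume
#'
#' A volume is a 3D array of intensities (height x width x slices) together
#' with the anatomical plane its slice axis corresponds to.  The plane is
#' recorded explicitly, never inferred from the shape.
#'
#' @param data 3D numeric array, height x width x slices.
#' @param plane One of `"axial"`, `"coronal"`, `"sagittal"`.
#' @param spacing Voxel spacing, length 3 (informational only; all geometry
#'   in this package is in voxel units).
#' @return An object of class `squseg_volume`.
#' @export
as_volume <- function(data, plane = c("axial", "coronal", "sagittal"),
                      spacing = c(1, 1, 1)) {
  plane <- match.arg(plane)
  if (length(dim(data)) != 3L) {
    stop("volume data must be a 3D array (height x width x slices)")
  }
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  structure(
    list(data = data, plane = plane, spacing = spacing,
         source_shape = dim(data)),
    class = "squseg_volume"
  )
}

#' Create a label volume
#'
#' @param labels 3D integer array with values in 0:3 (see [CLASS_CODES]).
#' @return An object of class `squseg_labels`.
#' @export
as_label_volume <- function(labels) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (!all(labels %in% 0:3)) {
    stop("labels must take values in {0,1,2,3} (background, CSF, GM, WM)")
  }
  structure(list(labels = labels, class_codes = CLASS_CODES,
                 source_shape = dim(labels)),
            class = "squseg_labels")
}

#' @export
print.squseg_volume <- function(x, ...) {
  cat(sprintf("<squseg_volume %s, %s plane, range [%.3g, %.3g]>\n",
              paste(dim(x$data), collapse = " x "), x$plane,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.squseg_labels <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:3,
                      labels = names(CLASS_CODES)))
  cat(sprintf("<squseg_labels %s>\n", paste(dim(x$labels), collapse = " x ")))
  print(tab)
  invisible(x)
}

#' Read a volume or label map from NIfTI
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param labels If `TRUE`, return a label volume (values checked against the
#'   four tissue codes).
#' @param plane Anatomical plane of the stored slice axis.
#' @return A [as_volume()] or [as_label_volume()] object.
#' @export
read_volume <- function(path, labels = FALSE, plane = "axial") {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) > 3L) arr <- arr[, , , 1L]
  d <- dim(arr)
  if (labels) as_label_volume(array(as.integer(round(arr)), d))
  else as_volume(array(as.numeric(arr), d), plane = plane)
}

#' Write a volume or label map to NIfTI
#'
#' @param x A `squseg_volume` or `squseg_labels` object, or a plain 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "squseg_volume")) x$data
         else if (inherits(x, "squseg_labels")) x$labels
         else x
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Reorient a stored volume so its third axis matches a requested plane
#'
#' Volumes are stored as height x width x slices arrays for one acquisition
#' plane.  The other two planes are obtained by a fixed axis permutation so
#' the same slice pipeline applies: relative to the stored (H, W, S) axes,
#' `"axial"` keeps (H, W, S), `"coronal"` permutes to (H, S, W) and
#' `"sagittal"` permutes to (W, S, H).
#'
#' @param x 3D array, `squseg_volume`, or `squseg_labels`.
#' @param plane Target plane.
#' @return Object of the same kind with permuted axes and updated plane.
#' @export
reorient_plane <- function(x, plane = c("axial", "coronal", "sagittal")) {
  plane <- match.arg(plane)
  perm <- switch(plane, axial = c(1, 2, 3), coronal = c(1, 3, 2),
                 sagittal = c(2, 3, 1))
  if (inherits(x, "squseg_volume")) {
    as_volume(aperm(x$data, perm), plane = plane, spacing = x$spacing[perm])
  } else if (inherits(x, "squseg_labels")) {
    as_label_volume(aperm(x$labels, perm))
  } else {
    aperm(x, perm)
  }
}
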