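#' Select informative slices on an arithmetic schedule
#'
#' Slice selection excludes the mostly-empty first and last slices of a scan
#' and thins out near-duplicate consecutive slices.  The default schedule
#' takes 48 slices starting from the 10th with a stride of 3, so a 176-slice
#' scan is covered up to slice 151.  Indices are 1-based ordinals into the
#' slice axis.
#'
#' @param volume A `squseg_volume`, `squseg_labels`, or 3D array.
#' @param start First selected slice (1-based ordinal). Default 10.
#' @param interval Stride between selected slices. Default 3.
#' @param count Number of slices to select. Default 48.
#' @return Integer vector of `count` slice indices.
#' @export
select_slices <- function(volume, start = 10L, interval = 3L, count = 48L) {
  stopifnot(start >= 1, interval >= 1, count >= 1)
  n_slices <- slice_count(volume)
  last <- start + interval * (count - 1L)
  if (last > n_slices) {
    stop(sprintf(paste0(
      "volume has %d slices but the schedule (start %d, interval %d, ",
      "count %d) needs slice %d; the volume is too shallow to preprocess"),
      n_slices, start, interval, count, last))
  }
  as.integer(seq.int(start, by = interval, length.out = count))
}

slice_count <- function(x) {
  if (inherits(x, "squseg_volume")) dim(x$data)[3]
  else if (inherits(x, "squseg_labels")) dim(x$labels)[3]
  else dim(x)[3]
}

#' Zero-pad a slice to a target shape, centred
#'
#' Pads with exact zeros so that the original content is centred; when the
#' total padding along an axis is odd, the extra row/column goes to the
#' bottom/right.  The returned `pad_spec` allows the paired label slice to be
#' padded identically and the prediction to be cropped back losslessly.
#'
#' @param slice 2D matrix.
#' @param target Target shape, `c(rows, cols)`. Default `c(256, 256)`.
#' @param value Padding value (0 for intensities; use 0 for labels too, which
#'   is the background class).
#' @return List with `slice` (target-shaped matrix) and
#'   `pad_spec = c(top, bottom, left, right)`.
#' @export
pad_slice <- function(slice, target = c(256L, 256L), value = 0) {
  d <- dim(slice)
  if (is.null(d)) stop("slice must be a 2D matrix")
  if (d[1] > target[1] || d[2] > target[2]) {
    stop(sprintf(paste0(
      "slice (%d x %d) exceeds the target (%d x %d); this pipeline only ",
      "zero-pads, it never crops or resamples"),
      d[1], d[2], target[1], target[2]))
  }
  pr <- as.integer(target[1] - d[1])
  pc <- as.integer(target[2] - d[2])
  spec <- c(top = pr %/% 2L, bottom = pr - pr %/% 2L,
            left = pc %/% 2L, right = pc - pc %/% 2L)
  out <- matrix(value, target[1], target[2])
  out[(spec[["top"]] + 1L):(spec[["top"]] + d[1]),
      (spec[["left"]] + 1L):(spec[["left"]] + d[2])] <- slice
  list(slice = out, pad_spec = spec)
}

#' Crop a padded slice back to its source shape
#'
#' Inverse of [pad_slice()].
#'
#' @param slice Padded 2D matrix.
#' @param pad_spec Padding `c(top, bottom, left, right)` as returned by
#'   [pad_slice()].
#' @return The unpadded matrix.
#' @export
unpad_slice <- function(slice, pad_spec) {
  d <- dim(slice)
  rows <- (pad_spec[[1]] + 1L):(d[1] - pad_spec[[2]])
  cols <- (pad_spec[[3]] + 1L):(d[2] - pad_spec[[4]])
  slice[rows, cols, drop = FALSE]
}

#' Split a 256 x 256 slice into four uniform 128 x 128 patches
#'
#' The four quadrants tile the slice with no overlap and no gap, in row-major
#' order: top-left, top-right, bottom-left, bottom-right (quadrants 1-4).
#' Pure sub-setting; no interpolation.
#'
#' @param slice 2D matrix, exactly 256 x 256.
#' @param slice_index Optional source slice index recorded in the origin.
#' @return A `squseg_patchset`: list with `patches` (list of 4 matrices),
#'   `layout`, and `origin`.
#' @export
split_patches <- function(slice, slice_index = NA_integer_) {
  d <- dim(slice)
  if (is.null(d) || d[1] != 256L || d[2] != 256L) {
    stop("split_patches expects exactly a 256 x 256 slice")
  }
  ranges <- list(list(1:128, 1:128),     # 1: top-left
                 list(1:128, 129:256),   # 2: top-right
                 list(129:256, 1:128),   # 3: bottom-left
                 list(129:256, 129:256)) # 4: bottom-right
  patches <- lapply(ranges, function(r) slice[r[[1]], r[[2]], drop = FALSE])
  structure(list(patches = patches,
                 layout = c("top-left", "top-right",
                            "bottom-left", "bottom-right"),
                 origin = list(slice_index = slice_index, quadrants = 1:4)),
            class = "squseg_patchset")
}

#' Map a parent-slice pixel to its quadrant and local coordinate
#'
#' @param row,col 1-based pixel coordinates in the 256 x 256 parent slice.
#' @return List with `quadrant` (1-4, row-major) and `local` (1-based
#'   coordinates within the 128 x 128 patch).
#' @export
patch_coordinate <- function(row, col) {
  stopifnot(row >= 1, row <= 256, col >= 1, col <= 256)
  qr <- as.integer(row > 128L)
  qc <- as.integer(col > 128L)
  list(quadrant = 2L * qr + qc + 1L,
       local = c(as.integer(row) - 128L * qr, as.integer(col) - 128L * qc))
}

#' Reassemble a slice from its four quadrant patches
#'
#' Exact inverse of [split_patches()]: `merge_patches(split_patches(x))` is
#' bit-identical to `x`.
#'
#' @param patch_set A `squseg_patchset`, or a list of 4 matrices in row-major
#'   quadrant order.
#' @return The 256 x 256 matrix.
#' @export
merge_patches <- function(patch_set) {
  if (inherits(patch_set, "squseg_patchset")) {
    q <- patch_set$origin$quadrants
    if (length(q) != 4L || anyDuplicated(q) || !setequal(q, 1:4)) {
      stop("patch set must contain each quadrant 1-4 exactly once")
    }
    si <- patch_set$origin$slice_index
    if (length(si) > 1L && length(unique(si[!is.na(si)])) > 1L) {
      stop("patches originate from different slices; refusing to merge")
    }
    patches <- patch_set$patches[order(q)]
  } else {
    patches <- patch_set
    if (length(patches) != 4L) stop("need exactly 4 patches")
  }
  ok <- vapply(patches, function(p) identical(dim(p), c(128L, 128L)), TRUE)
  if (!all(ok)) stop("every patch must be 128 x 128")
  out <- matrix(0, 256L, 256L)
  out[1:128, 1:128]     <- patches[[1L]]
  out[1:128, 129:256]   <- patches[[2L]]
  out[129:256, 1:128]   <- patches[[3L]]
  out[129:256, 129:256] <- patches[[4L]]
  out
}

#' Preprocess a volume into patch training samples
#'
#' Composes slice selection, centred zero padding to 256 x 256, and uniform
#' patch splitting.  With the default schedule a paper-shaped scan yields
#' 48 slices x 4 patches = 192 samples.  Labels, when given, are padded with
#' the background class using the same `pad_spec` and split with the same
#' quadrant layout, so voxel/label correspondence is preserved everywhere
#' (padded pixels are (0, background)).
#'
#' @param volume A `squseg_volume` or 3D array.
#' @param labels Optional `squseg_labels` or 3D integer array (same shape).
#' @param start,interval,count Slice schedule, see [select_slices()].
#' @param target Padded slice shape. Default `c(256, 256)`.
#' @return List with `samples` (each a list of `patch`, `label`, `slice_index`,
#'   `quadrant`), plus `slice_indices`, `pad_spec`, `source_shape` — enough
#'   metadata for bit-exact reassembly.
#' @export
preprocess_volume <- function(volume, labels = NULL, start = 10L,
                              interval = 3L, count = 48L,
                              target = c(256L, 256L)) {
  vol <- if (inherits(volume, "squseg_volume")) volume$data else volume
  lab <- if (inherits(labels, "squseg_labels")) labels$labels else labels
  if (!is.null(lab) && !identical(dim(vol), dim(lab))) {
    stop("volume and label shapes differ")
  }
  idx <- select_slices(vol, start, interval, count)
  pad_spec <- NULL
  samples <- vector("list", length(idx) * 4L)
  k <- 0L
  for (s in idx) {
    p <- pad_slice(vol[, , s], target)
    pad_spec <- p$pad_spec
    ps <- split_patches(p$slice, slice_index = s)
    lp <- NULL
    if (!is.null(lab)) {
      lps <- pad_slice(lab[, , s], target, value = 0L)
      lp <- split_patches(lps$slice, slice_index = s)
    }
    for (q in 1:4) {
      k <- k + 1L
      samples[[k]] <- list(patch = ps$patches[[q]],
                           label = if (is.null(lp)) NULL else lp$patches[[q]],
                           slice_index = s, quadrant = q)
    }
  }
  list(samples = samples, slice_indices = idx, pad_spec = pad_spec,
       source_shape = dim(vol))
}
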