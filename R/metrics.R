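#' Dice similarity coefficient between two binary masks
#'
#' `2 |X ∩ Y| / (|X| + |Y|)`.  By convention two empty masks (both raters
#' agree the class is absent) score 1; an empty mask against a non-empty one
#' scores 0.
#'
#' @param x,y Logical arrays/vectors of equal length (class masks).
#' @return Dice coefficient in \[0, 1\].
#' @export
dsc <- function(x, y) {
  x <- as.logical(x); y <- as.logical(y)
  if (length(x) != length(y)) stop("mask sizes differ")
  nx <- sum(x); ny <- sum(y)
  if (nx + ny == 0L) return(1)
  2 * sum(x & y) / (nx + ny)
}

#' Jaccard index, from the Dice identity
#'
#' Computed as `DSC / (2 - DSC)`, which equals `|X ∩ Y| / |X ∪ Y|`.
#'
#' @inheritParams dsc
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard <- function(x, y) {
  d <- dsc(x, y)
  d / (2 - d)
}

#' Hausdorff distance between two binary masks
#'
#' Symmetric bidirectional max-min Euclidean distance between the pixel (or
#' voxel) coordinate sets of the two masks, in index units (unit spacing).
#' By default the full masks are the point sets; `boundary = TRUE` first
#' reduces each mask to its boundary pixels (pixels with at least one
#' 4-neighbour outside the mask).
#'
#' @inheritParams dsc
#' @param boundary Use boundary pixels instead of full masks.
#' @return Non-negative distance; 0 iff the masks are identical.
#' @export
hausdorff <- function(x, y, boundary = FALSE) {
  x <- as.array(x); y <- as.array(y)
  if (!identical(dim(x), dim(y))) stop("mask shapes differ")
  if (boundary) {
    x <- mask_boundary(x)
    y <- mask_boundary(y)
  }
  A <- which(x != 0, arr.ind = TRUE)
  B <- which(y != 0, arr.ind = TRUE)
  if (nrow(A) == 0L || nrow(B) == 0L) {
    stop("Hausdorff distance undefined: a mask is empty ",
         "(class absent in prediction or truth)")
  }
  hausdorff_cpp(A * 1.0, B * 1.0)
}

mask_boundary <- function(m) {
  m <- m != 0
  d <- dim(m)
  if (length(d) != 2L) stop("boundary mode expects a 2D mask")
  shifted <- function(di, dj) {
    out <- matrix(FALSE, d[1], d[2])
    ri <- seq_len(d[1]) + di; cj <- seq_len(d[2]) + dj
    ok_r <- ri >= 1 & ri <= d[1]; ok_c <- cj >= 1 & cj <= d[2]
    out[ok_r, ok_c] <- m[ri[ok_r], cj[ok_c]]
    out
  }
  inner <- shifted(1, 0) & shifted(-1, 0) & shifted(0, 1) & shifted(0, -1)
  m & !inner
}

#' Mean squared error between one-hot truth and predicted probabilities
#'
#' Averages the squared difference over all pixels and all four classes.
#' Zero iff the prediction is exactly the one-hot encoding of the truth.
#'
#' @param truth Integer label map (values 0-3), any shape.
#' @param probs Probability array with one more (last) dimension of size 4,
#'   or a matrix `n x 4` matching `length(truth)`.
#' @return Non-negative scalar.
#' @export
seg_mse <- function(truth, probs) {
  n <- length(truth)
  pm <- matrix(probs, nrow = n)
  if (ncol(pm) != 4L) stop("probabilities must have 4 classes")
  onehot <- matrix(0, n, 4L)
  onehot[cbind(seq_len(n), as.integer(truth) + 1L)] <- 1
  mean((onehot - pm)^2)
}

#' Per-class evaluation of a predicted segmentation
#'
#' Computes DSC, Jaccard, and Hausdorff distance for each tissue class
#' (CSF, GM, WM; background is excluded from reporting), plus a global MSE
#' when class probabilities are supplied.
#'
#' @param predicted Integer label map (array or `squseg_labels`).
#' @param truth Integer label map of the same shape.
#' @param probs Optional probability array (last dimension 4) for the MSE.
#' @param classes Integer codes to report. Default `1:3` (CSF, GM, WM).
#' @param hd Compute the Hausdorff distance (can be slow on large masks).
#' @return A data.frame with one row per class and columns
#'   `class`, `dsc`, `jaccard`, `hausdorff`, and attribute `mse` when
#'   `probs` is given.
#' @export
evaluate_segmentation <- function(predicted, truth, probs = NULL,
                                  classes = 1:3, hd = TRUE) {
  p <- if (inherits(predicted, "squseg_labels")) predicted$labels
       else as.array(predicted)
  t <- if (inherits(truth, "squseg_labels")) truth$labels else as.array(truth)
  if (!identical(dim(p), dim(t))) stop("prediction and truth shapes differ")
  rows <- lapply(classes, function(k) {
    pm <- p == k; tm <- t == k
    h <- NA_real_
    if (hd) {
      # an absent class makes the distance undefined; report NA, keep going
      h <- tryCatch(hausdorff(pm, tm), error = function(e) {
        warning("Hausdorff undefined for class ", k, ": ",
                conditionMessage(e), call. = FALSE)
        NA_real_
      })
    }
    data.frame(class = names(CLASS_CODES)[match(k, CLASS_CODES)],
               dsc = dsc(pm, tm),
               jaccard = jaccard(pm, tm),
               hausdorff = h)
  })
  out <- do.call(rbind, rows)
  if (!is.null(probs)) attr(out, "mse") <- seg_mse(t, probs)
  out
}

#' Aggregate per-subject metric tables
#'
#' Mean and sample standard deviation per class across subjects, matching the
#' usual "mean ± sd" reporting of segmentation studies.
#'
#' @param reports List of data.frames from [evaluate_segmentation()].
#' @return data.frame with per-class mean and sd of each metric.
#' @export
aggregate_metrics <- function(reports) {
  all <- do.call(rbind, reports)
  agg <- lapply(split(all, all$class), function(d) {
    data.frame(class = d$class[1],
               dsc_mean = mean(d$dsc), dsc_sd = sd(d$dsc),
               jaccard_mean = mean(d$jaccard), jaccard_sd = sd(d$jaccard),
               hausdorff_mean = mean(d$hausdorff),
               hausdorff_sd = sd(d$hausdorff))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
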