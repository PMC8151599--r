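test_that("slice schedule enumerates the arithmetic sequence exactly", {
  vol <- array(0, c(8, 8, 176))
  idx <- select_slices(vol, start = 10, interval = 3, count = 48)
  expect_identical(idx, as.integer(seq(10, by = 3, length.out = 48)))
  expect_length(idx, 48L)
  expect_identical(max(idx), 151L)          # 10 + 3*47, fits 176 slices
  expect_true(all(diff(idx) == 3L))
  expect_identical(select_slices(vol, 10, 3, 1), 10L)
})

test_that("too-shallow volumes are rejected with a descriptive error", {
  vol <- array(0, c(4, 4, 150))
  expect_error(select_slices(vol, 10, 3, 48), "too shallow")
  # boundary: exactly deep enough passes
  vol2 <- array(0, c(4, 4, 151))
  expect_silent(select_slices(vol2, 10, 3, 48))
})

test_that("zero padding is centred, exact, and conserves content", {
  # OASIS-like in-plane shape
  sl <- matrix(runif(208 * 176), 208, 176)
  p <- pad_slice(sl)
  expect_identical(unname(p$pad_spec), c(24L, 24L, 40L, 40L))
  expect_identical(dim(p$slice), c(256L, 256L))
  expect_identical(p$slice[25:232, 41:216], sl)
  expect_equal(sum(p$slice), sum(sl))       # pad value exactly 0
  # IBSR-like in-plane shape: the short in-plane axis gets the 64-pad
  p2 <- pad_slice(matrix(1, 256, 128))
  expect_identical(unname(p2$pad_spec), c(0L, 0L, 64L, 64L))
  # no-op padding
  sl3 <- matrix(runif(256 * 256), 256, 256)
  p3 <- pad_slice(sl3)
  expect_identical(p3$slice, sl3)
  expect_identical(unname(p3$pad_spec), c(0L, 0L, 0L, 0L))
  # odd remainders go bottom/right
  p4 <- pad_slice(matrix(1, 5, 5), target = c(8, 8))
  expect_identical(unname(p4$pad_spec), c(1L, 2L, 1L, 2L))
  # non-pad multiset conserved
  expect_identical(sort(as.numeric(p$slice)[p$slice != 0]),
                   sort(as.numeric(sl)[sl != 0]))
  expect_error(pad_slice(matrix(0, 300, 10)), "exceeds")
  # inverse crop restores the source
  expect_identical(unpad_slice(p$slice, p$pad_spec), sl)
})

test_that("patch splitting gives four 128x128 quadrants in row-major order", {
  sl <- matrix(seq_len(256 * 256), 256, 256)
  ps <- split_patches(sl)
  expect_length(ps$patches, 4L)
  for (p in ps$patches) expect_identical(dim(p), c(128L, 128L))
  # constant slice gives constant patches
  psc <- split_patches(matrix(3.5, 256, 256))
  for (p in psc$patches) expect_true(all(p == 3.5))
  expect_error(split_patches(matrix(0, 128, 256)), "256 x 256")
  # quadrant arithmetic vs brute force over the four offsets
  set.seed(42)
  for (k in 1:25) {
    rc <- sample(256, 2, replace = TRUE)
    got <- patch_coordinate(rc[1], rc[2])
    expect_identical(ps$patches[[got$quadrant]][got$local[1], got$local[2]],
                     sl[rc[1], rc[2]])
  }
  # the worked case: parent pixel at row 131, col 6 (1-based) sits in the
  # bottom-left quadrant at local (3, 6)
  pc <- patch_coordinate(131, 6)
  expect_identical(pc$quadrant, 3L)
  expect_identical(pc$local, c(3L, 6L))
})

test_that("split/merge is a bit-exact bijection and checks origins", {
  set.seed(7)
  for (k in 1:50) {
    sl <- matrix(rnorm(256 * 256), 256, 256)
    expect_identical(merge_patches(split_patches(sl)), sl)
  }
  # distinct constant patches land in quadrant order
  blocks <- lapply(1:4, function(v) matrix(v, 128, 128))
  merged <- merge_patches(blocks)
  expect_equal(merged[1, 1], 1)
  expect_equal(merged[1, 256], 2)
  expect_equal(merged[256, 1], 3)
  expect_equal(merged[256, 256], 4)
  # conflicting origins refuse to merge
  a <- split_patches(matrix(0, 256, 256), slice_index = 1L)
  b <- split_patches(matrix(1, 256, 256), slice_index = 2L)
  bad <- a
  bad$origin$slice_index <- c(1L, 2L)
  expect_error(merge_patches(bad), "different slices")
  dup <- a
  dup$origin$quadrants <- c(1L, 1L, 3L, 4L)
  expect_error(merge_patches(dup), "exactly once")
})

test_that("volume preprocessing yields aligned intensity/label samples", {
  ph <- small_phantom()
  pp <- preprocess_volume(ph$volume, ph$labels,
                          start = small_schedule$start,
                          interval = small_schedule$interval,
                          count = small_schedule$count)
  expect_length(pp$samples, small_schedule$count * 4L)
  s1 <- pp$samples[[1]]
  expect_identical(dim(s1$patch), c(128L, 128L))
  expect_identical(dim(s1$label), c(128L, 128L))
  # padded region is (0, background)
  expect_true(all(s1$label %in% 0:3))
  pad_rows <- seq_len(pp$pad_spec[["top"]])
  expect_true(all(s1$patch[pad_rows, ] == 0))
  expect_true(all(s1$label[pad_rows, ] == 0))
  # voxel/label correspondence on random interior pixels
  set.seed(1)
  for (k in 1:20) {
    i <- sample(length(pp$samples), 1)
    smp <- pp$samples[[i]]
    r <- sample(128, 1); c <- sample(128, 1)
    qs <- list(c(0L, 0L), c(0L, 128L), c(128L, 0L), c(128L, 128L))
    off <- qs[[smp$quadrant]]
    pr <- r + off[1] - pp$pad_spec[["top"]]
    pc <- c + off[2] - pp$pad_spec[["left"]]
    if (pr >= 1 && pr <= dim(ph$volume$data)[1] &&
        pc >= 1 && pc <= dim(ph$volume$data)[2]) {
      expect_identical(smp$patch[r, c],
                       ph$volume$data[pr, pc, smp$slice_index])
      expect_identical(smp$label[r, c],
                       ph$labels$labels[pr, pc, smp$slice_index])
    } else {
      expect_identical(smp$patch[r, c], 0)
      expect_identical(smp$label[r, c], 0L)
    }
  }
  # inference path: no labels
  pp2 <- preprocess_volume(ph$volume, NULL, start = 4, interval = 2,
                           count = 2)
  expect_null(pp2$samples[[1]]$label)
})

test_that("plane reorientation permutes axes consistently", {
  arr <- array(seq_len(4 * 5 * 6), c(4, 5, 6))
  v <- as_volume(arr)
  cor <- reorient_plane(v, "coronal")
  expect_identical(dim(cor$data), c(4L, 6L, 5L))
  expect_identical(cor$data[2, 3, 4], arr[2, 4, 3])
  sag <- reorient_plane(v, "sagittal")
  expect_identical(dim(sag$data), c(5L, 6L, 4L))
  expect_identical(sag$data[2, 3, 4], arr[4, 2, 3])
})
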