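# Shared fixtures and brute-force oracles, all built in code.

# Tiny two-level model config: fast enough for gradient checks and forward
# contracts (inputs must be divisible by 2^(levels+1) = 8).
tiny_config <- function(variant = "full") {
  model_config(variant, filters_per_level = c(8L, 8L), fires_per_level = 2L,
               patch_size = 16L)
}

# Small phantom: 80x64 in-plane (fits the 256-pad pipeline), few slices.
small_phantom <- function(seed = 7L, noise_sd = 2, bias = 0.02) {
  generate_phantom(phantom_spec(shape = c(80L, 64L, 24L),
                                noise_sd = noise_sd, bias_amplitude = bias,
                                seed = seed))
}
small_schedule <- list(start = 4L, interval = 2L, count = 6L)

# one-hot encode an HxW label map to HxWx4
onehot4 <- function(y) {
  n <- length(y)
  oh <- matrix(0, n, 4)
  oh[cbind(seq_len(n), as.integer(y) + 1L)] <- 1
  array(oh, c(dim(y), 4L))
}

# Brute-force 2x2 max pooling with per-window argmax positions (oracle for
# the C++ implementation).  Returns the pooled plane and 1-based (i, j)
# argmax coordinates per window, first maximum in column-major scan order.
oracle_maxpool <- function(m) {
  h <- nrow(m) / 2
  w <- ncol(m) / 2
  y <- matrix(0, h, w)
  ai <- matrix(0L, h, w)
  aj <- matrix(0L, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      win <- m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
      y[i, j] <- max(win)
      k <- which.max(win)          # column-major, first max
      ai[i, j] <- 2L * i - 1L + (k - 1L) %% 2L
      aj[i, j] <- 2L * j - 1L + (k - 1L) %/% 2L
    }
  }
  list(y = y, ai = ai, aj = aj)
}

# Brute-force set metrics on coordinate sets / masks.
oracle_dsc <- function(x, y) {
  X <- which(x); Y <- which(y)
  if (length(X) + length(Y) == 0) return(1)
  2 * length(intersect(X, Y)) / (length(X) + length(Y))
}
oracle_jaccard <- function(x, y) {
  X <- which(x); Y <- which(y)
  if (length(union(X, Y)) == 0) return(1)
  length(intersect(X, Y)) / length(union(X, Y))
}
oracle_hausdorff <- function(A, B) {
  # A, B: n x 2 coordinate matrices; all-pairs max-min distance
  dmat <- outer(seq_len(nrow(A)), seq_len(nrow(B)),
                Vectorize(function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

random_mask <- function(d = c(12L, 12L), p = 0.25) {
  array(runif(prod(d)) < p, d)
}
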