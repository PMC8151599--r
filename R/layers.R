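# Layer primitives: parameter constructors plus forward/backward passes.
# Feature maps are H x W x C arrays; gradients mirror parameter shapes.
# Backward passes recompute im2col from cached inputs rather than caching
# the column matrices, trading a little CPU for a large memory saving.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

as_cube <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("expected an H x W x C feature map")
  x
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (!all(da[1:2] == db[1:2])) stop("spatial shapes differ in concat")
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

scale_channels <- function(x, g) {
  # multiply channel c of x by g[c]
  d <- dim(x)
  array(t(t(matrix(x, d[1] * d[2], d[3])) * g), d)
}

gap_channels <- function(x) {
  d <- dim(x)
  colMeans(matrix(x, d[1] * d[2], d[3]))
}

#' Create convolution parameters (He-uniform initialised)
#'
#' Weights are stored as a `(k*k*cin) x cout` matrix plus a bias vector; the
#' initial values are drawn from the current RNG state, so a fixed seed gives
#' identical parameters.  Initialisation is He-uniform
#' (`limit = sqrt(6 / fan_in)`): with ~30 stacked ReLU convolution blocks
#' and no batch normalisation, fan-average (Glorot) scaling attenuates the
#' forward signal by two orders of magnitude and training stalls at the
#' majority class, whereas He scaling preserves the activation variance.
#'
#' @param k Kernel size (1 or 3).
#' @param cin,cout Input/output channels.
#' @return A `conv_param` list with `W`, `b`, `k`, `cin`, `cout`.
#' @export
conv_param <- function(k, cin, cout) {
  lim <- sqrt(6 / (k * k * cin))
  list(W = matrix(runif(k * k * cin * cout, -lim, lim), k * k * cin, cout),
       b = numeric(cout), k = as.integer(k),
       cin = as.integer(cin), cout = as.integer(cout))
}

conv_fwd <- function(p, x) {
  conv2d_fwd(x, p$W, p$b, p$k, if (p$k == 3L) 1L else 0L)
}

conv_bwd <- function(p, x, dy) {
  b <- conv2d_bwd(x, p$W, p$k, if (p$k == 3L) 1L else 0L, dy)
  b$db <- as.numeric(b$db)
  b
}

## ---- fire module -----------------------------------------------------------

#' Create fire-module parameters
#'
#' A fire module squeezes to `F/4` channels with a 1 x 1 convolution and
#' expands through parallel 1 x 1 and 3 x 3 convolutions of `F/2` channels
#' each, concatenated, so the output width is exactly `F`.
#'
#' @param cin Input channels.
#' @param F_out Module width; must be divisible by 4.
#' @return Named list of three [conv_param()]s (`squeeze`, `expand1`,
#'   `expand3`).
#' @export
fire_params <- function(cin, F_out) {
  if (F_out %% 4L != 0L) {
    stop("fire module width must be divisible by 4 (squeeze F/4, expand F/2)")
  }
  list(squeeze = conv_param(1L, cin, F_out %/% 4L),
       expand1 = conv_param(1L, F_out %/% 4L, F_out %/% 2L),
       expand3 = conv_param(3L, F_out %/% 4L, F_out %/% 2L))
}

fire_fwd <- function(p, x, cache = FALSE) {
  res <- fire_fwd_cpp(x, p$squeeze$W, p$squeeze$b, p$expand1$W, p$expand1$b,
                      p$expand3$W, p$expand3$b, cache)
  if (cache) list(out = res$out, x = x, s = res$s) else res$out
}

fire_bwd <- function(p, cache, dout) {
  b <- fire_bwd_cpp(cache$x, cache$s, cache$out, p$squeeze$W,
                    p$expand1$W, p$expand3$W, dout)
  list(dx = b$dx,
       grads = list(squeeze = list(dW = b$dWs, db = as.numeric(b$dbs)),
                    expand1 = list(dW = b$dW1, db = as.numeric(b$db1)),
                    expand3 = list(dW = b$dW3, db = as.numeric(b$db3))))
}

#' Apply a fire module to a feature map
#'
#' @param x Feature map (H x W x C array, or matrix treated as single
#'   channel).
#' @param params Parameters from [fire_params()].
#' @return Feature map with the module width as channel count and unchanged
#'   spatial size.
#' @export
fire_module <- function(x, params) {
  fire_fwd(params, as_cube(x))
}

#' Apply a transposed fire module
#'
#' The decoder mirror of [fire_module()]: a 1 x 1 transposed convolution
#' squeeze feeding parallel 1 x 1 and 3 x 3 transposed convolutions that are
#' concatenated.  All transposed convolutions have stride 1 (spatial
#' up-scaling is done by index unpooling, not here), so each is a
#' convolution with the same parameter shapes as the encoder module and the
#' operation is parameterised identically.
#'
#' @inheritParams fire_module
#' @export
transposed_fire_module <- function(x, params) {
  fire_fwd(params, as_cube(x))
}

## ---- multi-scale input branch ----------------------------------------------

#' Create multi-scale input-fusion parameters
#'
#' @param cin Input channels of the branch source.
#' @param width Output width; each parallel branch has `width/2` channels.
#' @export
ms_params <- function(cin, width) {
  if (width %% 2L != 0L) stop("multi-scale width must be even")
  list(c1 = conv_param(1L, cin, width %/% 2L),
       c3 = conv_param(3L, cin, width %/% 2L))
}

ms_fwd <- function(p, x_prev, cache = FALSE) {
  d <- dim(x_prev)
  if (d[1] %% 2L || d[2] %% 2L) {
    stop("multi-scale input requires even spatial dimensions")
  }
  mp <- maxpool2_fwd(x_prev)
  c1 <- relu(conv_fwd(p$c1, mp$y))
  c3 <- relu(conv_fwd(p$c3, mp$y))
  out <- concat_c(c1, c3)
  if (cache) {
    list(out = out, idx = mp$idx, m = mp$y, c1 = c1, c3 = c3,
         in_dim = d)
  } else out
}

ms_bwd <- function(p, cache, dout) {
  w2 <- p$c1$cout
  dc1 <- dout[, , seq_len(w2), drop = FALSE] * (cache$c1 > 0)
  dc3 <- dout[, , w2 + seq_len(w2), drop = FALSE] * (cache$c3 > 0)
  b1 <- conv_bwd(p$c1, cache$m, dc1)
  b3 <- conv_bwd(p$c3, cache$m, dc3)
  dm <- b1$dx + b3$dx
  dx <- unpool_scatter(dm, cache$idx, cache$in_dim[1], cache$in_dim[2])
  list(dx = dx,
       grads = list(c1 = list(dW = b1$dW, db = b1$db),
                    c3 = list(dW = b3$dW, db = b3$db)))
}

#' Multi-scale input fusion
#'
#' Max-pools the previous layer's input with a 2 x 2 window (stride 2) and
#' concatenates parallel 1 x 1 and 3 x 3 convolution outputs, halving the
#' spatial size.
#'
#' @param x_prev Source feature map with even spatial dimensions.
#' @param params Parameters from [ms_params()].
#' @export
multiscale_input <- function(x_prev, params) {
  ms_fwd(params, as_cube(x_prev))
}

## ---- global attention module ------------------------------------------------

#' Create global-attention parameters
#'
#' @param c_low Channels of the modulated (low-level) feature map.
#' @param c_gate Channels of the gating (context) feature map.
#' @export
gam_params <- function(c_low, c_gate) {
  list(gate = conv_param(1L, c_gate, c_low),
       low = conv_param(1L, c_low, c_low))
}

gam_fwd <- function(p, x_low, gate, cache = FALSE) {
  gv <- gap_channels(gate)
  gvc <- array(gv, c(1L, 1L, length(gv)))
  g <- relu(conv_fwd(p$gate, gvc))[1, 1, ]
  pmap <- conv_fwd(p$low, x_low)
  alpha <- scale_channels(pmap, g)
  out <- x_low + alpha
  if (cache) {
    list(out = out, x_low = x_low, gvc = gvc, g = g, pmap = pmap,
         gate_dim = dim(gate))
  } else out
}

gam_bwd <- function(p, cache, dout) {
  # residual: d x_low gets dout directly, plus the projection path
  dpm <- scale_channels(dout, cache$g)
  d <- dim(dout)
  dg <- colSums(matrix(dout * cache$pmap, d[1] * d[2], d[3]))
  bl <- conv_bwd(p$low, cache$x_low, dpm)
  dgp <- array(dg * (cache$g > 0), c(1L, 1L, length(dg)))
  bg <- conv_bwd(p$gate, cache$gvc, dgp)
  gd <- cache$gate_dim
  dgate <- array(rep(as.numeric(bg$dx) / (gd[1] * gd[2]),
                     each = gd[1] * gd[2]), gd)
  list(dx_low = dout + bl$dx, dgate = dgate,
       grads = list(gate = list(dW = bg$dW, db = bg$db),
                    low = list(dW = bl$dW, db = bl$db)))
}

#' Global attention module
#'
#' Global average pooling reduces the gating map to a context vector, which
#' is projected by a 1 x 1 convolution with ReLU; the low-level map is
#' projected by a second 1 x 1 convolution, and the two are combined by
#' multiplicative attention to form the coefficient map `alpha`, which is
#' added element-wise back onto the low-level features.  Because the gate is
#' globally pooled, `alpha` always lives at the low-level map's resolution
#' and no interpolation is needed; a coarser gate is therefore allowed.
#' With zero projection weights the module is the identity.
#'
#' @param x_low Low-level feature map (modulated; sets the output shape).
#' @param x_gate Gating feature map (may have coarser spatial size).
#' @param params Parameters from [gam_params()].
#' @export
global_attention <- function(x_low, x_gate, params) {
  x_low <- as_cube(x_low); x_gate <- as_cube(x_gate)
  if (params$gate$cin != dim(x_gate)[3] || params$low$cin != dim(x_low)[3]) {
    stop("attention projections do not match the input channel counts")
  }
  gam_fwd(params, x_low, x_gate)
}

## ---- head and loss ----------------------------------------------------------

softmax_channels <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, d[1] * d[2], d[3])
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  array(e / rowSums(e), d)
}

#' Pixel-wise classification head
#'
#' A 1 x 1 convolution to `num_classes` logits followed by a per-pixel
#' softmax; every pixel's class probabilities sum to 1.
#'
#' @param x Feature map at full patch resolution.
#' @param params A [conv_param()] with `cout = num_classes`.
#' @return H x W x num_classes probability array.
#' @export
classification_head <- function(x, params) {
  softmax_channels(conv_fwd(params, as_cube(x)))
}

#' Cross-entropy loss
#'
#' Mean over pixels of `-sum_i y_i log(y'_i)` between one-hot truth and
#' predicted class probabilities.  Zero exactly when the prediction equals
#' the one-hot truth.
#'
#' @param y_true Integer label map (H x W, values 0-3) or one-hot
#'   H x W x C array.
#' @param y_pred H x W x C probability array (checked to be normalised).
#' @param tol Normalisation tolerance.
#' @return Non-negative scalar loss.
#' @export
cross_entropy_loss <- function(y_true, y_pred, tol = 1e-6) {
  d <- dim(y_pred)
  pm <- matrix(y_pred, d[1] * d[2], d[3])
  if (any(abs(rowSums(pm) - 1) > tol) || any(pm < -tol)) {
    stop("predicted values are not normalised class probabilities")
  }
  oh <- onehot_map(y_true, d)
  om <- matrix(oh, d[1] * d[2], d[3])
  eps <- 1e-12
  mean(-rowSums(om * log(pmax(pm, eps))))
}

onehot_map <- function(y_true, d) {
  if (length(dim(y_true)) == 3L) return(y_true)
  n <- length(y_true)
  oh <- matrix(0, n, d[3])
  oh[cbind(seq_len(n), as.integer(y_true) + 1L)] <- 1
  array(oh, d)
}
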