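test_that("fire module keeps spatial size and outputs exactly F channels", {
  set.seed(1)
  p <- fire_params(1L, 64L)
  x <- array(rnorm(128 * 128), c(128, 128, 1))
  y <- fire_module(x, p)
  expect_identical(dim(y), c(128L, 128L, 64L))
  # squeeze filter count is below the total expand filter count
  expect_lt(p$squeeze$cout, p$expand1$cout + p$expand3$cout)
  expect_identical(p$squeeze$cout, 16L)
  expect_identical(p$expand1$cout, 32L)
  # zero input with zero biases stays zero through the ReLUs
  y0 <- fire_module(array(0, c(16, 16, 1)), p)
  expect_true(all(y0 == 0))
  expect_error(fire_params(1L, 30L), "divisible by 4")
})

test_that("fire module parameter count follows k^2*Cin*Cout + Cout", {
  p <- fire_params(1L, 64L)
  n <- sum(vapply(p, function(q) length(q$W) + length(q$b), 0))
  # squeeze 1*16+16, expand1 16*32+32, expand3 9*16*32+32
  expect_identical(as.integer(n), 32L + 544L + 4640L)
  # transposed module has identical parameterisation
  pt <- fire_params(64L, 64L)
  x <- array(rnorm(16 * 16 * 64), c(16, 16, 64))
  expect_identical(dim(transposed_fire_module(x, pt)), c(16L, 16L, 64L))
  nt <- sum(vapply(pt, function(q) length(q$W) + length(q$b), 0))
  expect_identical(as.integer(nt), 64L * 16L + 16L + 544L + 4640L)
})

test_that("multi-scale fusion halves the spatial size and concatenates", {
  set.seed(2)
  p <- ms_params(1L, 64L)
  x <- array(rnorm(128 * 128), c(128, 128, 1))
  y <- multiscale_input(x, p)
  expect_identical(dim(y), c(64L, 64L, 64L))
  # constant input max-pools to the same constant
  mp <- maxpool2_fwd(array(2.5, c(8, 8, 1)))
  expect_true(all(mp$y == 2.5))
  # single 2x2 window
  one <- maxpool2_fwd(array(c(1, 3, 2, 4), c(2, 2, 1)))
  expect_equal(as.numeric(one$y), 4)
  expect_error(multiscale_input(array(0, c(7, 8, 1)), p), "even")
})

test_that("max-pool indices agree with a brute-force per-window oracle", {
  set.seed(3)
  for (k in 1:10) {
    m <- matrix(rnorm(64), 8, 8)
    got <- maxpool2_fwd(array(m, c(8, 8, 1)))
    ora <- oracle_maxpool(m)
    expect_equal(got$y[, , 1], ora$y)
    # stored linear indices point at the oracle argmax coordinates
    lin <- (ora$aj - 1L) * 8L + (ora$ai - 1L)
    expect_identical(as.integer(got$idx), as.integer(lin))
  }
  # maxima forced into window corner (0,0) offsets
  m <- matrix(-seq_len(64), 8, 8)      # strictly decreasing -> corner wins
  got <- maxpool2_fwd(array(m, c(8, 8, 1)))
  ij <- arrayInd(as.integer(got$idx) + 1L, c(8, 8))
  expect_true(all(ij[, 1] %% 2 == 1))  # odd rows/cols = window corner
  expect_true(all(ij[, 2] %% 2 == 1))
})

test_that("unpooling is adjoint to pooling: values at argmax, zeros elsewhere", {
  set.seed(4)
  for (k in 1:10) {
    x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    mp <- maxpool2_fwd(x)
    up <- unpool_scatter(mp$y, mp$idx, 8L, 8L)
    ora <- lapply(1:3, function(c) oracle_maxpool(x[, , c]))
    for (c in 1:3) {
      expected <- matrix(0, 8, 8)
      o <- ora[[c]]
      for (i in 1:4) for (j in 1:4) {
        expected[o$ai[i, j], o$aj[i, j]] <- o$y[i, j]
      }
      expect_equal(up[, , c], expected)
    }
    # gather inverts scatter on the pooled support
    expect_equal(unpool_gather(up, mp$idx, 4L, 4L), mp$y)
  }
})

test_that("global attention preserves shape and is the identity at zero", {
  set.seed(5)
  p <- gam_params(8L, 16L)
  x_low <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  gate <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  out <- global_attention(x_low, gate, p)
  expect_identical(dim(out), dim(x_low))
  expect_true(all(is.finite(out)))
  # zeroed projections: alpha = 0, exact identity
  p0 <- p
  p0$gate$W[] <- 0; p0$gate$b[] <- 0
  p0$low$W[] <- 0; p0$low$b[] <- 0
  expect_identical(global_attention(x_low, gate, p0), x_low)
  # global average pooling of a constant map is that constant per channel
  cst <- array(rep(c(1.5, -2), each = 36), c(6, 6, 2))
  expect_equal(squseg:::gap_channels(cst), c(1.5, -2))
  expect_error(global_attention(x_low, array(0, c(8, 8, 3)), p),
               "channel counts")
})

test_that("classification head and loss match their analytic values", {
  # equal logits -> uniform probabilities
  p <- conv_param(1L, 4L, 4L)
  p$W[] <- 0; p$b[] <- 0
  probs <- classification_head(array(rnorm(4 * 4 * 4), c(4, 4, 4)), p)
  expect_equal(as.numeric(probs), rep(0.25, 64), tolerance = 1e-12)
  # dominant logit saturates
  sm <- squseg:::softmax_channels(array(c(50, 0, 0, 0), c(1, 1, 4)))
  expect_gt(sm[1, 1, 1], 1 - 1e-12)
  # logits (0, log 2, 0, 0) -> (1/5, 2/5, 1/5, 1/5)
  sm2 <- squseg:::softmax_channels(array(c(0, log(2), 0, 0), c(1, 1, 4)))
  expect_equal(as.numeric(sm2), c(1, 2, 1, 1) / 5, tolerance = 1e-12)
  # loss: perfect one-hot -> 0; uniform -> log 4; single case -log 0.7
  y <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  expect_equal(cross_entropy_loss(y, onehot4(y)), 0, tolerance = 1e-9)
  unif <- array(0.25, c(2, 2, 4))
  expect_equal(cross_entropy_loss(y, unif), log(4), tolerance = 1e-12)
  one <- array(c(0.1, 0.7, 0.1, 0.1), c(1, 1, 4))
  expect_equal(cross_entropy_loss(matrix(1L, 1, 1), one), -log(0.7),
               tolerance = 1e-12)
  expect_error(cross_entropy_loss(y, unif * 2), "not normalised")
})

test_that("backpropagated gradients match finite differences", {
  set.seed(6)
  for (variant in c("squeeze_usegnet", "multiscale", "multiattention",
                    "full")) {
    m <- build_model(tiny_config(variant), seed = 5)
    x <- array(rnorm(16 * 16) * 2, c(16, 16, 1))
    y <- matrix(sample(0:3, 256, TRUE), 16, 16)
    oh <- onehot4(y)
    lossfn <- function(mm) cross_entropy_loss(y, forward_model(mm, x))
    fw <- forward_model(m, x, train = TRUE)
    bw <- squseg:::backward_model(m, fw, (fw$probs - oh) / 256)
    eps <- 1e-6
    checked <- 0L
    for (nm in names(m$params)) {
      for (sn in names(m$params[[nm]])) {
        if (!is.list(m$params[[nm]][[sn]])) next   # flat conv (head)
        W <- m$params[[nm]][[sn]]$W
        g <- bw$grads[[nm]][[sn]]$dW
        for (i in sample(length(W), min(2L, length(W)))) {
          m2 <- m
          m2$params[[nm]][[sn]]$W[i] <- W[i] + eps
          l1 <- lossfn(m2)
          m2$params[[nm]][[sn]]$W[i] <- W[i] - eps
          l0 <- lossfn(m2)
          fd <- (l1 - l0) / (2 * eps)
          if (abs(fd) > 1e-4) {   # skip entries sitting on ReLU/pool kinks
            checked <- checked + 1L
            expect_lt(abs(fd - g[i]) / (abs(fd) + abs(g[i])), 1e-4)
          }
        }
      }
    }
    expect_gt(checked, 0L)
  }
})
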