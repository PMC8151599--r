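# Model assembly for the four architecture variants, the full forward and
# backward passes, and exact parameter counting.
#
# Channel flow (filters F_l per level, L levels, nf fire modules per level):
#   encoder level l: fire chain (input -> F_l), optional multi-scale branch
#   ms_l (from the pooled trunk of the previous level), optional encoder
#   attention (gate = ms_l in the full variant, the layer input otherwise),
#   2x2 max-pool storing indices.  In the multiscale-only variant ms_l is
#   concatenated onto the pooled stream; elsewhere it is consumed by the
#   attention gate so the stream width stays F_l.
#   bottleneck: fire(-> 2*F_L) then fire(-> F_L).
#   decoder level l: index unpooling, attention-gated skip (the encoder fire
#   output gated by the coarser decoder stream), concatenation, transposed
#   fire chain ending at the next level's width.
#   head: 1x1 convolution to 4 classes + softmax.

MODEL_VARIANTS <- c("squeeze_usegnet", "multiscale", "multiattention", "full")

#' Reference learnable-parameter counts of the four published variants
#'
#' Named integer vector used by [ablation_report()] to show residuals of the
#' built models against the published counts.
#' @export
REFERENCE_COUNTS <- c(squeeze_usegnet = 768788L, multiscale = 860180L,
                      multiattention = 942164L, full = 1030420L)

#' Model configuration
#'
#' The single source of truth for the architecture: variant, depth, and
#' per-level filter widths.  Widths must be divisible by 4 so the fire-module
#' squeeze (`F/4`) and expand (`F/2`) widths are integral.  The defaults (3
#' levels of widths 96/96/192 with 3 fire modules per level and a
#' double-width bottleneck) are the assignment that comes closest to the
#' published parameter counts of all four variants simultaneously while
#' preserving their ordering; see the ablation report for the residuals.
#'
#' @param variant One of `"squeeze_usegnet"` (fire modules, plain skips),
#'   `"multiscale"` (adds the multi-scale input branch), `"multiattention"`
#'   (adds encoder+decoder attention), `"full"` (both).
#' @param filters_per_level Integer vector of per-level widths (all divisible
#'   by 4); its length sets the number of encoder/decoder levels.
#' @param fires_per_level Fire modules stacked per level (encoder and
#'   decoder).
#' @param num_classes Output classes (4: background, CSF, GM, WM).
#' @param input_channels Input channels (1 for T1-weighted intensity).
#' @param patch_size Nominal input patch size; the network itself is fully
#'   convolutional and accepts any spatial size divisible by
#'   `2^(levels + 1)`.
#' @return A `squseg_config` list.
#' @export
model_config <- function(variant = "full",
                         filters_per_level = c(96L, 96L, 192L),
                         fires_per_level = 3L,
                         num_classes = 4L,
                         input_channels = 1L,
                         patch_size = 128L) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  if (any(filters_per_level %% 4L != 0L)) {
    stop("filters_per_level must be divisible by 4")
  }
  structure(list(variant = variant,
                 levels = length(filters_per_level),
                 filters_per_level = as.integer(filters_per_level),
                 fires_per_level = as.integer(fires_per_level),
                 num_classes = as.integer(num_classes),
                 input_channels = as.integer(input_channels),
                 patch_size = as.integer(patch_size)),
            class = "squseg_config")
}

has_ms <- function(config) config$variant %in% c("multiscale", "full")
has_gam <- function(config) config$variant %in% c("multiattention", "full")

# Channel bookkeeping shared by the builder, the forward pass, and the
# summary: returns per-level input channels for the fire chain (main stream),
# the trunk channels feeding the ms branch, and the attention gate channels.
plan_channels <- function(config) {
  L <- config$levels
  F <- config$filters_per_level
  main_in <- trunk_in <- gate_in <- integer(L)
  cur_main <- cur_trunk <- config$input_channels
  for (l in seq_len(L)) {
    main_in[l] <- cur_main
    trunk_in[l] <- cur_trunk
    gate_in[l] <- if (config$variant == "full") F[l] else main_in[l]
    cur_trunk <- F[l]
    cur_main <- F[l] + if (config$variant == "multiscale") F[l] else 0L
  }
  dec_out <- c(F[1], F[seq_len(L - 1)])  # G_l: level 1 keeps F_1
  list(main_in = main_in, trunk_in = trunk_in, gate_in = gate_in,
       bott_in = cur_main, dec_out = dec_out)
}

#' Build a network variant
#'
#' Constructs and initialises all trainable parameters for the requested
#' variant.  Initialisation is Glorot-uniform from `seed`, so two builds with
#' the same seed have identical parameters (and identical forward outputs).
#'
#' @param config A [model_config()].
#' @param seed RNG seed for weight initialisation.
#' @return A `squseg_model` list with `config` and named `params`.
#' @export
build_model <- function(config = model_config(), seed = 42L) {
  stopifnot(inherits(config, "squseg_config"))
  L <- config$levels
  F <- config$filters_per_level
  nf <- config$fires_per_level
  ch <- plan_channels(config)
  params <- list()
  with_seed(seed, {
    for (l in seq_len(L)) {
      cin <- ch$main_in[l]
      for (k in seq_len(nf)) {
        params[[sprintf("enc%d.fire%d", l, k)]] <- fire_params(cin, F[l])
        cin <- F[l]
      }
      if (has_ms(config)) {
        params[[sprintf("enc%d.ms", l)]] <- ms_params(ch$trunk_in[l], F[l])
      }
      if (has_gam(config)) {
        params[[sprintf("enc%d.gam", l)]] <- gam_params(F[l], ch$gate_in[l])
      }
    }
    params[["bott.fire1"]] <- fire_params(ch$bott_in, 2L * F[L])
    params[["bott.fire2"]] <- fire_params(2L * F[L], F[L])
    for (l in rev(seq_len(L))) {
      if (has_gam(config)) {
        params[[sprintf("dec%d.gam", l)]] <- gam_params(F[l], F[l])
      }
      cin <- 2L * F[l]
      G <- ch$dec_out[l]
      if (nf == 1L) {
        params[[sprintf("dec%d.fire1", l)]] <- fire_params(cin, G)
      } else {
        params[[sprintf("dec%d.fire1", l)]] <- fire_params(cin, F[l])
        if (nf > 2L) {
          for (k in seq(2L, nf - 1L)) {
            params[[sprintf("dec%d.fire%d", l, k)]] <- fire_params(F[l], F[l])
          }
        }
        params[[sprintf("dec%d.fire%d", l, nf)]] <- fire_params(F[l], G)
      }
    }
    params[["head"]] <- conv_param(1L, ch$dec_out[1], config$num_classes)
  })
  structure(list(config = config, params = params), class = "squseg_model")
}

#' @export
print.squseg_model <- function(x, ...) {
  cat(sprintf("<squseg_model variant=%s, levels=%d, filters=[%s], %s params>\n",
              x$config$variant, x$config$levels,
              paste(x$config$filters_per_level, collapse = ", "),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# walk a (possibly nested) parameter list, applying f to every conv_param
walk_convs <- function(params, f) {
  for (name in names(params)) {
    p <- params[[name]]
    if (!is.null(p$W)) f(name, p)
    else for (sub in names(p)) f(paste(name, sub, sep = "."), p[[sub]])
  }
  invisible(NULL)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (all convolution weights and biases),
#' framework-independent and deterministic.
#'
#' @param model A `squseg_model`.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  total <- 0
  walk_convs(model$params, function(name, p) {
    total <<- total + length(p$W) + length(p$b)
  })
  as.integer(total)
}

#' Per-layer architecture summary
#'
#' The audit trail for parameter counting: one row per convolution with its
#' kernel size, channel counts, and parameter count.
#'
#' @param model A `squseg_model`.
#' @return data.frame with columns `layer`, `kernel`, `in_channels`,
#'   `out_channels`, `params`.
#' @export
model_summary <- function(model) {
  rows <- list()
  walk_convs(model$params, function(name, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = name, kernel = sprintf("%dx%d", p$k, p$k),
      in_channels = p$cin, out_channels = p$cout,
      params = as.integer(length(p$W) + length(p$b)))
  })
  do.call(rbind, rows)
}

## ---- forward ---------------------------------------------------------------

#' Run the network forward on one patch
#'
#' @param model A `squseg_model`.
#' @param x Input patch: H x W matrix or H x W x C array with spatial size
#'   divisible by `2^(levels + 1)`.
#' @param train Keep intermediate activations for a backward pass.
#' @return If `train = FALSE`, the H x W x num_classes probability array;
#'   otherwise a list with `probs` and the activation caches.
#' @export
forward_model <- function(model, x, train = FALSE) {
  config <- model$config
  P <- model$params
  L <- config$levels
  F <- config$filters_per_level
  nf <- config$fires_per_level
  x <- as_cube(x)
  if (any(dim(x)[1:2] %% 2L^(L + 1L) != 0L)) {
    stop(sprintf("input spatial size must be divisible by %d", 2L^(L + 1L)))
  }
  enc <- vector("list", L)
  cur_main <- cur_trunk <- x
  for (l in seq_len(L)) {
    fires <- vector("list", nf)
    t <- cur_main
    for (k in seq_len(nf)) {
      fires[[k]] <- fire_fwd(P[[sprintf("enc%d.fire%d", l, k)]], t,
                             cache = train)
      t <- if (train) fires[[k]]$out else fires[[k]]
    }
    oexp <- t
    msc <- NULL
    if (has_ms(config)) {
      msc <- ms_fwd(P[[sprintf("enc%d.ms", l)]], cur_trunk, cache = train)
    }
    ms_out <- if (is.null(msc)) NULL else if (train) msc$out else msc
    gamc <- NULL
    if (has_gam(config)) {
      gate <- if (config$variant == "full") ms_out else cur_main
      gamc <- gam_fwd(P[[sprintf("enc%d.gam", l)]], oexp, gate, cache = train)
      z <- if (train) gamc$out else gamc
    } else {
      z <- oexp
    }
    pool <- maxpool2_fwd(z)
    enc[[l]] <- list(fires = fires, ms = msc, gam = gamc, idx = pool$idx,
                     z_dim = dim(z), oexp = oexp)
    cur_trunk <- pool$y
    cur_main <- if (config$variant == "multiscale") concat_c(pool$y, ms_out)
                else pool$y
  }
  b1 <- fire_fwd(P[["bott.fire1"]], cur_main, cache = train)
  d <- if (train) b1$out else b1
  b2 <- fire_fwd(P[["bott.fire2"]], d, cache = train)
  d <- if (train) b2$out else b2
  dec <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gamc <- NULL
    if (has_gam(config)) {
      gamc <- gam_fwd(P[[sprintf("dec%d.gam", l)]], enc[[l]]$oexp, d,
                      cache = train)
      sk <- if (train) gamc$out else gamc
    } else {
      sk <- enc[[l]]$oexp
    }
    up <- unpool_scatter(d, enc[[l]]$idx, enc[[l]]$z_dim[1], enc[[l]]$z_dim[2])
    t <- concat_c(sk, up)
    cat_in <- t
    fires <- vector("list", nf)
    for (k in seq_len(nf)) {
      fires[[k]] <- fire_fwd(P[[sprintf("dec%d.fire%d", l, k)]], t,
                             cache = train)
      t <- if (train) fires[[k]]$out else fires[[k]]
    }
    dec[[l]] <- list(gam = gamc, fires = fires, d_dim = dim(d),
                     cat_dim = dim(cat_in))
    d <- t
  }
  logits <- conv_fwd(P[["head"]], d)
  probs <- softmax_channels(logits)
  if (!train) return(probs)
  list(probs = probs, x = x, enc = enc, bott = list(b1 = b1, b2 = b2),
       dec = dec, d_final = d)
}

## ---- backward --------------------------------------------------------------

zero_like_grads <- function(params) {
  g <- list()
  for (name in names(params)) {
    p <- params[[name]]
    if (!is.null(p$W)) {
      g[[name]] <- list(dW = 0 * p$W, db = 0 * p$b)
    } else {
      g[[name]] <- lapply(p, function(q) list(dW = 0 * q$W, db = 0 * q$b))
    }
  }
  g
}

acc_grads <- function(acc, name, grads) {
  if (!is.null(grads$dW)) {
    acc[[name]]$dW <- acc[[name]]$dW + grads$dW
    acc[[name]]$db <- acc[[name]]$db + grads$db
  } else {
    for (sub in names(grads)) {
      acc[[name]][[sub]]$dW <- acc[[name]][[sub]]$dW + grads[[sub]]$dW
      acc[[name]][[sub]]$db <- acc[[name]][[sub]]$db + grads[[sub]]$db
    }
  }
  acc
}

fire_chain_bwd <- function(P, prefix, fires, nf, dout, acc) {
  for (k in rev(seq_len(nf))) {
    nm <- sprintf("%s.fire%d", prefix, k)
    bk <- fire_bwd(P[[nm]], fires[[k]], dout)
    acc <- acc_grads(acc, nm, bk$grads)
    dout <- bk$dx
  }
  list(dx = dout, acc = acc)
}

# Backward pass from the softmax/cross-entropy gradient.  `dlogits` is
# (probs - onehot) / n_pixels for the mean-pixel CE loss.
backward_model <- function(model, fw, dlogits) {
  config <- model$config
  P <- model$params
  L <- config$levels
  F <- config$filters_per_level
  nf <- config$fires_per_level
  acc <- zero_like_grads(P)
  bh <- conv_bwd(P[["head"]], fw$d_final, dlogits)
  acc <- acc_grads(acc, "head", list(dW = bh$dW, db = bh$db))
  dstream <- bh$dx
  d_oexp <- vector("list", L)   # accumulated grads for encoder skip tensors
  # decoder levels were processed L..1; reverse order is 1..L
  for (l in seq_len(L)) {
    res <- fire_chain_bwd(P, sprintf("dec%d", l), fw$dec[[l]]$fires, nf,
                          dstream, acc)
    acc <- res$acc
    dcat <- res$dx
    dsk <- dcat[, , seq_len(F[l]), drop = FALSE]
    dup <- dcat[, , F[l] + seq_len(F[l]), drop = FALSE]
    dd <- unpool_gather(dup, fw$enc[[l]]$idx,
                        fw$dec[[l]]$d_dim[1], fw$dec[[l]]$d_dim[2])
    if (has_gam(config)) {
      nm <- sprintf("dec%d.gam", l)
      bg <- gam_bwd(P[[nm]], fw$dec[[l]]$gam, dsk)
      acc <- acc_grads(acc, nm, bg$grads)
      d_oexp[[l]] <- bg$dx_low
      dd <- dd + bg$dgate
    } else {
      d_oexp[[l]] <- dsk
    }
    dstream <- dd
  }
  b2 <- fire_bwd(P[["bott.fire2"]], fw$bott$b2, dstream)
  acc <- acc_grads(acc, "bott.fire2", b2$grads)
  b1 <- fire_bwd(P[["bott.fire1"]], fw$bott$b1, b2$dx)
  acc <- acc_grads(acc, "bott.fire1", b1$grads)
  d_main <- b1$dx                       # grad wrt encoder level-L output
  d_trunk_pending <- NULL               # grad wrt pooled trunk from ms above
  for (l in rev(seq_len(L))) {
    e <- fw$enc[[l]]
    if (config$variant == "multiscale") {
      d_pool <- d_main[, , seq_len(F[l]), drop = FALSE]
      d_ms <- d_main[, , F[l] + seq_len(F[l]), drop = FALSE]
    } else {
      d_pool <- d_main
      d_ms <- NULL
    }
    if (!is.null(d_trunk_pending)) d_pool <- d_pool + d_trunk_pending
    dz <- unpool_scatter(d_pool, e$idx, e$z_dim[1], e$z_dim[2])
    d_gate_main <- NULL
    if (has_gam(config)) {
      nm <- sprintf("enc%d.gam", l)
      bg <- gam_bwd(P[[nm]], e$gam, dz)
      acc <- acc_grads(acc, nm, bg$grads)
      doexp <- bg$dx_low
      if (config$variant == "full") {
        d_ms <- if (is.null(d_ms)) bg$dgate else d_ms + bg$dgate
      } else {
        d_gate_main <- bg$dgate
      }
    } else {
      doexp <- dz
    }
    doexp <- doexp + d_oexp[[l]]
    res <- fire_chain_bwd(P, sprintf("enc%d", l), e$fires, nf, doexp, acc)
    acc <- res$acc
    dmain_in <- res$dx
    if (!is.null(d_gate_main)) dmain_in <- dmain_in + d_gate_main
    d_trunk_pending <- NULL
    if (has_ms(config) && !is.null(d_ms)) {
      nm <- sprintf("enc%d.ms", l)
      bm <- ms_bwd(P[[nm]], e$ms, d_ms)
      acc <- acc_grads(acc, nm, bm$grads)
      d_trunk_pending <- bm$dx
    }
    d_main <- dmain_in
    if (l == 1L && !is.null(d_trunk_pending)) {
      # at the first level the trunk and the main input are both the image
      d_main <- d_main + d_trunk_pending
      d_trunk_pending <- NULL
    }
  }
  list(grads = acc, dx = d_main)
}

## ---- spec-level layer wrappers ---------------------------------------------

#' One encoder layer of a built model
#'
#' Applies the level's fire chain, the multi-scale branch and encoder
#' attention as dictated by the model's variant, and the stored-index
#' max-pooling.
#'
#' @param model A `squseg_model`.
#' @param level Encoder level (1-based).
#' @param x_in Main-stream input feature map for the level.
#' @param prev_raw Trunk input feeding the multi-scale branch (defaults to
#'   `x_in`, which is correct except in the multiscale-only variant where the
#'   trunk excludes the concatenated branch).
#' @return List with `out` (pooled stream), `indices`, and the pre-pool
#'   tensors `oexp` and `ms`.
#' @export
encoder_layer <- function(model, level, x_in, prev_raw = x_in) {
  config <- model$config
  P <- model$params
  nf <- config$fires_per_level
  t <- as_cube(x_in)
  for (k in seq_len(nf)) {
    t <- fire_fwd(P[[sprintf("enc%d.fire%d", level, k)]], t)
  }
  ms_out <- NULL
  if (has_ms(config)) {
    ms_out <- ms_fwd(P[[sprintf("enc%d.ms", level)]], as_cube(prev_raw))
  }
  z <- t
  if (has_gam(config)) {
    gate <- if (config$variant == "full") ms_out else as_cube(x_in)
    z <- gam_fwd(P[[sprintf("enc%d.gam", level)]], t, gate)
  }
  pool <- maxpool2_fwd(z)
  out <- pool$y
  if (config$variant == "multiscale") out <- concat_c(out, ms_out)
  list(out = out, indices = pool$idx, oexp = t, ms = ms_out)
}

#' One decoder layer of a built model
#'
#' Unpools the incoming stream with the stored encoder indices, gates the
#' skip tensor through the decoder attention module (when the variant has
#' one), concatenates, and applies the transposed fire chain; the spatial
#' size doubles.
#'
#' @param model A `squseg_model`.
#' @param level Decoder level (1-based, matching the encoder level whose
#'   indices are reused).
#' @param x_up Incoming (coarse) decoder stream.
#' @param skip Encoder skip tensor (the level's fire output).
#' @param indices Pooling indices stored at that encoder level.
#' @return The decoded feature map at doubled spatial size.
#' @export
decoder_layer <- function(model, level, x_up, skip, indices) {
  config <- model$config
  P <- model$params
  nf <- config$fires_per_level
  x_up <- as_cube(x_up); skip <- as_cube(skip)
  sk <- skip
  if (has_gam(config)) {
    sk <- gam_fwd(P[[sprintf("dec%d.gam", level)]], skip, x_up)
  }
  up <- unpool_scatter(x_up, indices, 2L * dim(x_up)[1], 2L * dim(x_up)[2])
  t <- concat_c(sk, up)
  for (k in seq_len(nf)) {
    t <- fire_fwd(P[[sprintf("dec%d.fire%d", level, k)]], t)
  }
  t
}
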