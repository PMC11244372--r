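# Four-stage hierarchical encoder in the SegNeXt style. Each stage holds
# depth x [attention block; feed-forward block]; the attention block's
# channel-mixing slot (the original 1x1 convolution) carries the depthwise
# 2D S4 layer followed by a pointwise mixing convolution when use_s4 = TRUE.

#' Encoder configuration
#'
#' Stage geometry and regularization settings. Defaults follow the published
#' four-stage design: channels 32/64/160/256, depths 3/3/5/2, feed-forward
#' expansion ratios 8/8/4/4, drop-path 0.01, batch-norm epsilon 1e-5 and
#' momentum 0.1.
#'
#' @param channels per-stage channel counts (length 4).
#' @param depths per-stage block counts (length 4).
#' @param expansion_ratios per-stage FFN expansion ratios (length 4).
#' @param use_s4 if `FALSE`, the attention block keeps the original 1x1
#'   convolution (ablation switch).
#' @param state_dim S4 state dimension per axis.
#' @param drop_path_rate stochastic-depth rate.
#' @param bn_epsilon,bn_momentum batch-norm settings.
#' @param dw_kernel attention depthwise kernel size.
#' @param strip_kernels strip-convolution branch lengths.
#' @return A list of class `EncoderConfig`.
#' @export
encoder_config <- function(channels = c(32L, 64L, 160L, 256L),
                           depths = c(3L, 3L, 5L, 2L),
                           expansion_ratios = c(8L, 8L, 4L, 4L),
                           use_s4 = TRUE,
                           state_dim = 16L,
                           drop_path_rate = 0.01,
                           bn_epsilon = 1e-5,
                           bn_momentum = 0.1,
                           dw_kernel = 5L,
                           strip_kernels = c(7L, 11L, 21L)) {
  if (length(channels) != 4 || length(depths) != 4 ||
      length(expansion_ratios) != 4)
    stop("encoder_config: exactly four stages are required")
  if (any(channels < 1) || any(depths < 1) || any(expansion_ratios < 1))
    stop("encoder_config: all counts must be positive")
  structure(list(channels = as.integer(channels), depths = as.integer(depths),
                 expansion_ratios = as.integer(expansion_ratios),
                 use_s4 = isTRUE(use_s4), state_dim = as.integer(state_dim),
                 drop_path_rate = drop_path_rate, bn_epsilon = bn_epsilon,
                 bn_momentum = bn_momentum, dw_kernel = as.integer(dw_kernel),
                 strip_kernels = as.integer(strip_kernels)),
            class = "EncoderConfig")
}

#' Stem: two stride-2 3x3 convolutions reaching stride 4
#'
#' @param cfg an `EncoderConfig`.
#' @return Stem module mapping 3 x H x W images to stage-1 width at H/4.
#' @export
make_stem <- function(cfg) {
  m <- new_module("stem")
  cmid <- max(cfg$channels[1] %/% 2L, 1L)
  m$children <- list(
    conv1 = layer_conv2d(3L, cmid, 3L, stride = 2L),
    bn1 = layer_bn(cmid, cfg$bn_epsilon, cfg$bn_momentum),
    act1 = layer_gelu(),
    conv2 = layer_conv2d(cmid, cfg$channels[1], 3L, stride = 2L),
    bn2 = layer_bn(cfg$channels[1], cfg$bn_epsilon, cfg$bn_momentum)
  )
  ch <- m$children
  m$forward <- function(x) {
    if (dim(x)[3] != 3) stop("stem: expected a 3-channel image")
    ch$bn2$forward(ch$conv2$forward(ch$act1$forward(ch$bn1$forward(ch$conv1$forward(x)))))
  }
  m$backward <- function(g) {
    ch$conv1$backward(ch$bn1$backward(ch$act1$backward(ch$conv2$backward(ch$bn2$backward(g)))))
  }
  m
}

#' Convolutional-attention block (MSCA with an S4-2D channel-mixing slot)
#'
#' Pre-norm, 5x5 depthwise convolution, three parallel strip-convolution
#' branches summed with the identity, then the mixing slot (S4-2D +
#' pointwise, or the original 1x1 convolution when `use_s4 = FALSE`); the
#' result gates the normalized input multiplicatively, with residual add
#' and drop-path.
#'
#' @param C channel count of the stage.
#' @param cfg an `EncoderConfig`.
#' @param tag identification string used in numerical error messages.
#' @return A module.
#' @export
msca_block <- function(C, cfg, tag = "msca") {
  m <- new_module("msca")
  ks <- cfg$strip_kernels
  kids <- list(
    bn = layer_bn(C, cfg$bn_epsilon, cfg$bn_momentum),
    dw = layer_conv2d(C, C, cfg$dw_kernel, groups = C),
    s1a = layer_conv2d(C, C, 1L, ks[1], groups = C),
    s1b = layer_conv2d(C, C, ks[1], 1L, groups = C),
    s2a = layer_conv2d(C, C, 1L, ks[2], groups = C),
    s2b = layer_conv2d(C, C, ks[2], 1L, groups = C),
    s3a = layer_conv2d(C, C, 1L, ks[3], groups = C),
    s3b = layer_conv2d(C, C, ks[3], 1L, groups = C),
    dp = layer_droppath(cfg$drop_path_rate)
  )
  if (cfg$use_s4) {
    kids$s4 <- layer_s4_2d(C, cfg$state_dim)
    kids$pw <- layer_conv2d(C, C, 1L)
  } else {
    kids$mix <- layer_conv2d(C, C, 1L)
  }
  m$children <- kids
  m$meta <- list(tag = tag, use_s4 = cfg$use_s4)
  ch <- m$children
  m$forward <- function(x) {
    h <- ch$bn$forward(x)
    a0 <- ch$dw$forward(h)
    a <- a0 + ch$s1b$forward(ch$s1a$forward(a0)) +
      ch$s2b$forward(ch$s2a$forward(a0)) +
      ch$s3b$forward(ch$s3a$forward(a0))
    att <- if (m$meta$use_s4) ch$pw$forward(ch$s4$forward(a))
           else ch$mix$forward(a)
    if (!all(is.finite(att)))
      stop(sprintf("msca_block[%s]: non-finite attention activations", m$meta$tag))
    m$cache <- list(h = h, att = att)
    x + ch$dp$forward(att * h)
  }
  m$backward <- function(g) {
    cc <- m$cache
    gout <- ch$dp$backward(g)
    gatt <- gout * cc$h
    gh_prod <- gout * cc$att
    ga <- if (m$meta$use_s4) ch$s4$backward(ch$pw$backward(gatt))
          else ch$mix$backward(gatt)
    ga0 <- ga + ch$s1a$backward(ch$s1b$backward(ga)) +
      ch$s2a$backward(ch$s2b$backward(ga)) +
      ch$s3a$backward(ch$s3b$backward(ga))
    gh <- ch$dw$backward(ga0) + gh_prod
    ch$bn$backward(gh) + g
  }
  m
}

#' Feed-forward block (inverted bottleneck)
#'
#' Pre-norm, pointwise expand by the stage ratio, depthwise 3x3, GELU,
#' pointwise project; residual with drop-path. Shape preserving.
#'
#' @param C channel count.
#' @param expansion expansion ratio.
#' @param cfg an `EncoderConfig`.
#' @return A module.
#' @export
ffn_block <- function(C, expansion, cfg) {
  m <- new_module("ffn")
  hidden <- C * expansion
  m$children <- list(
    bn = layer_bn(C, cfg$bn_epsilon, cfg$bn_momentum),
    pw1 = layer_conv2d(C, hidden, 1L),
    dw = layer_conv2d(hidden, hidden, 3L, groups = hidden),
    act = layer_gelu(),
    pw2 = layer_conv2d(hidden, C, 1L),
    dp = layer_droppath(cfg$drop_path_rate)
  )
  m$meta <- list(hidden = hidden)
  ch <- m$children
  m$forward <- function(x) {
    x + ch$dp$forward(ch$pw2$forward(ch$act$forward(ch$dw$forward(ch$pw1$forward(ch$bn$forward(x))))))
  }
  m$backward <- function(g) {
    gi <- ch$bn$backward(ch$pw1$backward(ch$dw$backward(ch$act$backward(ch$pw2$backward(ch$dp$backward(g))))))
    gi + g
  }
  m
}

#' Build the four-stage encoder
#'
#' @param cfg an `EncoderConfig`.
#' @return Encoder module; run with [encoder_forward()].
#' @export
build_encoder <- function(cfg = encoder_config()) {
  stopifnot(inherits(cfg, "EncoderConfig"))
  m <- new_module("encoder")
  kids <- list(stem = make_stem(cfg))
  for (s in 1:4) {
    if (s > 1) {
      kids[[sprintf("down%d", s)]] <- layer_conv2d(cfg$channels[s - 1],
                                                   cfg$channels[s], 3L,
                                                   stride = 2L)
      kids[[sprintf("downbn%d", s)]] <- layer_bn(cfg$channels[s],
                                                 cfg$bn_epsilon,
                                                 cfg$bn_momentum)
    }
    for (b in seq_len(cfg$depths[s])) {
      kids[[sprintf("stage%d.block%d.attn", s, b)]] <-
        msca_block(cfg$channels[s], cfg, tag = sprintf("stage%d.block%d", s, b))
      kids[[sprintf("stage%d.block%d.ffn", s, b)]] <-
        ffn_block(cfg$channels[s], cfg$expansion_ratios[s], cfg)
    }
  }
  m$children <- kids
  m$cfg <- cfg
  m
}

#' Run the encoder, returning the four-stage feature pyramid
#'
#' @param enc module from [build_encoder()].
#' @param image numeric array H x W x 3 x N (H, W divisible by 32).
#' @param training logical.
#' @return List of four arrays at strides 4, 8, 16, 32 with the configured
#'   channel counts.
#' @export
encoder_forward <- function(enc, image, training = FALSE) {
  set_training(enc, training)
  d <- dim(image)
  if (length(d) != 4) stop("encoder_forward: need an H x W x 3 x N array")
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0)
    stop("encoder_forward: H and W must be divisible by 32 (pad upstream)")
  cfg <- enc$cfg
  x <- enc$children$stem$forward(image)
  feats <- vector("list", 4)
  for (s in 1:4) {
    if (s > 1) {
      x <- enc$children[[sprintf("downbn%d", s)]]$forward(
        enc$children[[sprintf("down%d", s)]]$forward(x))
    }
    for (b in seq_len(cfg$depths[s])) {
      x <- enc$children[[sprintf("stage%d.block%d.attn", s, b)]]$forward(x)
      x <- enc$children[[sprintf("stage%d.block%d.ffn", s, b)]]$forward(x)
    }
    feats[[s]] <- x
  }
  feats
}

#' Backpropagate through the encoder
#'
#' @param enc encoder module (after a forward pass).
#' @param gfeats list of four gradients matching the pyramid shapes.
#' @return Gradient with respect to the input image.
#' @export
encoder_backward <- function(enc, gfeats) {
  cfg <- enc$cfg
  g <- NULL
  for (s in 4:1) {
    g <- if (is.null(g)) gfeats[[s]] else g + gfeats[[s]]
    for (b in rev(seq_len(cfg$depths[s]))) {
      g <- enc$children[[sprintf("stage%d.block%d.ffn", s, b)]]$backward(g)
      g <- enc$children[[sprintf("stage%d.block%d.attn", s, b)]]$backward(g)
    }
    if (s > 1) {
      g <- enc$children[[sprintf("down%d", s)]]$backward(
        enc$children[[sprintf("downbn%d", s)]]$backward(g))
    }
  }
  enc$children$stem$backward(g)
}
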