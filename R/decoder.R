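# UNETR-like decoder: progressive 2x transpose-convolution upsampling from
# the deepest encoder stage, skip fusion with each shallower stage through
# residual convolution blocks, then a full-resolution refinement path fed by
# an image-derived shallow skip, ending in a 1x1 two-class head.

#' Decoder configuration
#'
#' @param skip_channels encoder stage widths (deep to shallow order is
#'   derived internally); must match the encoder configuration.
#' @param head_channels width of the full-resolution refinement path.
#' @param num_classes number of output classes (2: tongue, background).
#' @param decoder_kind `"unetr"` (implemented) or `"ham"` (ablation stub).
#' @param bn_epsilon,bn_momentum batch-norm settings.
#' @return A list of class `DecoderConfig`.
#' @export
decoder_config <- function(skip_channels = c(32L, 64L, 160L, 256L),
                           head_channels = 16L,
                           num_classes = 2L,
                           decoder_kind = c("unetr", "ham"),
                           bn_epsilon = 1e-5, bn_momentum = 0.1) {
  decoder_kind <- match.arg(decoder_kind)
  if (num_classes < 2) stop("decoder_config: num_classes must be >= 2")
  structure(list(skip_channels = as.integer(skip_channels),
                 head_channels = as.integer(head_channels),
                 num_classes = as.integer(num_classes),
                 decoder_kind = decoder_kind,
                 bn_epsilon = bn_epsilon, bn_momentum = bn_momentum),
            class = "DecoderConfig")
}

#' Upsampling fusion block
#'
#' Doubles the deep feature map's resolution with a 2x2 transpose
#' convolution, concatenates the encoder skip, and fuses through two 3x3
#' convolutions with a projected residual path.
#'
#' @param cin_deep channels of the deeper (smaller) input.
#' @param c_skip channels of the skip input (= output channels).
#' @param bn_eps,bn_mom batch-norm settings.
#' @return A module with a two-argument `forward(deep, skip)`; its backward
#'   returns `list(gdeep, gskip)`.
#' @export
up_block <- function(cin_deep, c_skip, bn_eps = 1e-5, bn_mom = 0.1) {
  m <- new_module("up_block")
  m$children <- list(
    up = layer_convt2(cin_deep, c_skip),
    conv1 = layer_conv2d(2L * c_skip, c_skip, 3L),
    bn1 = layer_bn(c_skip, bn_eps, bn_mom),
    act1 = layer_gelu(),
    conv2 = layer_conv2d(c_skip, c_skip, 3L),
    bn2 = layer_bn(c_skip, bn_eps, bn_mom),
    proj = layer_conv2d(2L * c_skip, c_skip, 1L),
    act_out = layer_gelu()
  )
  ch <- m$children
  m$meta <- list(c_skip = c_skip)
  m$forward2 <- function(deep, skip) {
    dd <- dim(deep); ds <- dim(skip)
    u <- ch$up$forward(deep)
    if (!all(dim(u)[1:2] == ds[1:2]))
      stop(sprintf("up_block: upsampled %dx%d does not match skip %dx%d",
                   dim(u)[1], dim(u)[2], ds[1], ds[2]))
    cat2 <- array(0, dim = c(ds[1], ds[2], dim(u)[3] + ds[3], ds[4]))
    cat2[, , seq_len(dim(u)[3]), ] <- u
    cat2[, , dim(u)[3] + seq_len(ds[3]), ] <- skip
    m$cache <- list(nu = dim(u)[3], nskip = ds[3])
    h <- ch$bn2$forward(ch$conv2$forward(ch$act1$forward(ch$bn1$forward(ch$conv1$forward(cat2)))))
    ch$act_out$forward(h + ch$proj$forward(cat2))
  }
  m$backward2 <- function(g) {
    g <- ch$act_out$backward(g)
    gcat <- ch$conv1$backward(ch$bn1$backward(ch$act1$backward(ch$conv2$backward(ch$bn2$backward(g))))) +
      ch$proj$backward(g)
    nu <- m$cache$nu
    gu <- gcat[, , seq_len(nu), , drop = FALSE]
    gskip <- gcat[, , nu + seq_len(m$cache$nskip), , drop = FALSE]
    list(gdeep = ch$up$backward(gu), gskip = gskip)
  }
  m
}

res_block <- function(C, bn_eps = 1e-5, bn_mom = 0.1) {
  m <- new_module("res_block")
  m$children <- list(
    conv1 = layer_conv2d(C, C, 3L), bn1 = layer_bn(C, bn_eps, bn_mom),
    act1 = layer_gelu(),
    conv2 = layer_conv2d(C, C, 3L), bn2 = layer_bn(C, bn_eps, bn_mom),
    act_out = layer_gelu()
  )
  ch <- m$children
  m$forward <- function(x) {
    h <- ch$bn2$forward(ch$conv2$forward(ch$act1$forward(ch$bn1$forward(ch$conv1$forward(x)))))
    ch$act_out$forward(h + x)
  }
  m$backward <- function(g) {
    g <- ch$act_out$backward(g)
    ch$conv1$backward(ch$bn1$backward(ch$act1$backward(ch$conv2$backward(ch$bn2$backward(g))))) + g
  }
  m
}

#' Build the decoder
#'
#' @param cfg a `DecoderConfig`.
#' @return Decoder module; run with [decoder_forward()].
#' @export
build_decoder <- function(cfg = decoder_config()) {
  stopifnot(inherits(cfg, "DecoderConfig"))
  if (cfg$decoder_kind == "ham")
    stop("decoder_kind = \"ham\" (the original Hamburger decoder) is not implemented; ",
         "it exists only as an ablation configuration stub. Use \"unetr\".")
  sc <- cfg$skip_channels
  hc <- cfg$head_channels
  m <- new_module("decoder")
  m$children <- list(
    up3 = up_block(sc[4], sc[3], cfg$bn_epsilon, cfg$bn_momentum),
    up2 = up_block(sc[3], sc[2], cfg$bn_epsilon, cfg$bn_momentum),
    up1 = up_block(sc[2], sc[1], cfg$bn_epsilon, cfg$bn_momentum),
    up_half = layer_convt2(sc[1], hc),
    res_half = res_block(hc, cfg$bn_epsilon, cfg$bn_momentum),
    up_full = layer_convt2(hc, hc),
    img_conv = layer_conv2d(3L, hc, 3L),
    img_bn = layer_bn(hc, cfg$bn_epsilon, cfg$bn_momentum),
    img_act = layer_gelu(),
    fuse_conv = layer_conv2d(2L * hc, hc, 3L),
    fuse_bn = layer_bn(hc, cfg$bn_epsilon, cfg$bn_momentum),
    fuse_act = layer_gelu(),
    head = layer_conv2d(hc, cfg$num_classes, 1L)
  )
  m$cfg <- cfg
  m
}

#' Run the decoder over an encoder pyramid
#'
#' @param dec module from [build_decoder()].
#' @param feats list of four encoder stage outputs (strides 4, 8, 16, 32).
#' @param image the (padded) input image, H x W x 3 x N; provides the
#'   full-resolution shallow skip.
#' @param training logical.
#' @return Logits array H x W x num_classes x N.
#' @export
decoder_forward <- function(dec, feats, image, training = FALSE) {
  if (length(feats) != 4) stop("decoder_forward: need all four pyramid levels")
  set_training(dec, training)
  ch <- dec$children
  x <- ch$up3$forward2(feats[[4]], feats[[3]])
  x <- ch$up2$forward2(x, feats[[2]])
  x <- ch$up1$forward2(x, feats[[1]])
  x <- ch$res_half$forward(ch$up_half$forward(x))
  x <- ch$up_full$forward(x)
  imgf <- ch$img_act$forward(ch$img_bn$forward(ch$img_conv$forward(image)))
  d <- dim(x)
  cat2 <- array(0, dim = c(d[1], d[2], d[3] + dim(imgf)[3], d[4]))
  cat2[, , seq_len(d[3]), ] <- x
  cat2[, , d[3] + seq_len(dim(imgf)[3]), ] <- imgf
  dec$cache <- list(nup = d[3], nimg = dim(imgf)[3])
  h <- ch$fuse_act$forward(ch$fuse_bn$forward(ch$fuse_conv$forward(cat2)))
  ch$head$forward(h)
}

#' Backpropagate through the decoder
#'
#' @param dec decoder module (after a forward pass).
#' @param g gradient with respect to the logits.
#' @return `list(gfeats = list of four, gimage = array)`.
#' @export
decoder_backward <- function(dec, g) {
  ch <- dec$children
  g <- ch$fuse_conv$backward(ch$fuse_bn$backward(ch$fuse_act$backward(ch$head$backward(g))))
  nup <- dec$cache$nup
  gx <- g[, , seq_len(nup), , drop = FALSE]
  gimgf <- g[, , nup + seq_len(dec$cache$nimg), , drop = FALSE]
  gimage <- ch$img_conv$backward(ch$img_bn$backward(ch$img_act$backward(gimgf)))
  gx <- ch$up_half$backward(ch$res_half$backward(ch$up_full$backward(gx)))
  r1 <- ch$up1$backward2(gx)
  r2 <- ch$up2$backward2(r1$gdeep)
  r3 <- ch$up3$backward2(r2$gdeep)
  list(gfeats = list(r1$gskip, r2$gskip, r3$gskip, r3$gdeep),
       gimage = gimage)
}
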