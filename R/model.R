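# Whole-network assembly and inference helpers.

#' Assemble the segmentation network
#'
#' @param enc_cfg an [encoder_config()].
#' @param dec_cfg a [decoder_config()]; its skip channels are aligned to the
#'   encoder automatically.
#' @return A model module with `encoder` and `decoder` children.
#' @export
seg_model <- function(enc_cfg = encoder_config(), dec_cfg = NULL) {
  if (is.null(dec_cfg)) dec_cfg <- decoder_config(skip_channels = enc_cfg$channels)
  if (!all(dec_cfg$skip_channels == enc_cfg$channels))
    stop("seg_model: decoder skip channels must match encoder channels")
  m <- new_module("model")
  m$children <- list(encoder = build_encoder(enc_cfg),
                     decoder = build_decoder(dec_cfg))
  m$enc_cfg <- enc_cfg
  m$dec_cfg <- dec_cfg
  m
}

#' Forward pass: image batch to class logits
#'
#' @param model module from [seg_model()].
#' @param image array H x W x 3 x N with H, W divisible by 32 (use
#'   [pad_image()] otherwise).
#' @param training logical.
#' @return Logits array H x W x num_classes x N.
#' @export
model_forward <- function(model, image, training = FALSE) {
  feats <- encoder_forward(model$children$encoder, image, training)
  model$cache_feats <- feats
  decoder_forward(model$children$decoder, feats, image, training)
}

#' Backward pass from a logits gradient
#'
#' @param model module (after [model_forward()]).
#' @param glogits gradient with respect to the logits.
#' @return Gradient with respect to the input image (sum of the encoder path
#'   and the decoder's image skip).
#' @export
model_backward <- function(model, glogits) {
  r <- decoder_backward(model$children$decoder, glogits)
  gimg <- encoder_backward(model$children$encoder, r$gfeats)
  gimg + r$gimage
}

#' Reflect-pad an image batch to the next multiple of a stride
#'
#' @param image H x W x C x N array (or H x W x C).
#' @param stride divisibility target (default 32).
#' @return List with `data` (padded array) and `orig` (original H, W).
#' @export
pad_image <- function(image, stride = 32L) {
  d <- dim(image)
  nd <- length(d)
  if (nd == 3) dim(image) <- c(d, 1L)
  d <- dim(image)
  Hp <- as.integer(ceiling(d[1] / stride) * stride)
  Wp <- as.integer(ceiling(d[2] / stride) * stride)
  if (Hp == d[1] && Wp == d[2])
    return(list(data = image, orig = c(d[1], d[2])))
  if (Hp - d[1] >= d[1] || Wp - d[2] >= d[2]) {
    # image smaller than the pad amount: fall back to edge replication
    ridx <- c(seq_len(d[1]), rep(d[1], Hp - d[1]))
    cidx <- c(seq_len(d[2]), rep(d[2], Wp - d[2]))
  } else {
    ridx <- c(seq_len(d[1]), seq(d[1] - 1, by = -1, length.out = Hp - d[1]))
    cidx <- c(seq_len(d[2]), seq(d[2] - 1, by = -1, length.out = Wp - d[2]))
  }
  list(data = image[ridx, cidx, , , drop = FALSE], orig = c(d[1], d[2]))
}

#' Segment an image: binary mask at the input resolution
#'
#' Pads the image to stride-32 divisibility, runs the network in eval mode,
#' crops the logits back and takes the per-pixel argmax.
#'
#' @param model module from [seg_model()] (trained or freshly initialized).
#' @param image H x W x 3 array in \[0, 1\], or a file path readable by
#'   [read_image()].
#' @return Integer H x W matrix with values in \{0, 1\}.
#' @export
segment_image <- function(model, image) {
  if (is.character(image)) image <- read_image(image)
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("segment_image: need an H x W x 3 image")
  p <- pad_image(image)
  logits <- model_forward(model, p$data, training = FALSE)
  logits <- logits[seq_len(d[1]), seq_len(d[2]), , 1, drop = FALSE]
  fg <- logits[, , 2, 1, drop = TRUE]
  bg <- logits[, , 1, 1, drop = TRUE]
  mask <- matrix(0L, d[1], d[2])
  mask[fg > bg] <- 1L
  mask
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the full state dict together with a snapshot of both
#' configurations, so a checkpoint is self-describing.
#'
#' @param model the model module.
#' @param path destination `.rds` path.
#' @param extra optional named list stored alongside (e.g. metric log).
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  obj <- list(state = state_dict(model), enc_cfg = model$enc_cfg,
              dec_cfg = model$dec_cfg, extra = extra,
              package_version = as.character(utils::packageVersion("tongueseg")))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns the reconstructed model; the raw
#'   checkpoint list is attached as attribute `"checkpoint"`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- seg_model(obj$enc_cfg, obj$dec_cfg)
  load_state_dict(model, obj$state)
  attr(model, "checkpoint") <- obj[c("extra", "package_version")]
  model
}
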