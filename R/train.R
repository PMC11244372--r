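# Training loop (AdamW), evaluation and prediction entry points.

#' Training configuration
#'
#' Optimizer defaults follow the published hyperparameter table: AdamW with
#' base learning rate 1e-4, betas (0.9, 0.999), batch size 16, encoder
#' drop-path 0.01, batch-norm epsilon 1e-5 and momentum 0.1. Epoch count,
#' learning-rate schedule (constant) and input resolution are this
#' package's own defaults since they are not part of that table.
#'
#' @param base_lr learning rate.
#' @param betas AdamW beta pair.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param seed master seed for init, shuffling and drop-path.
#' @param alpha loss mix: `alpha * CE + (1 - alpha) * boundary`; 1 = plain
#'   cross-entropy (the shipped configuration).
#' @param weight_decay decoupled weight decay on >=2-D tensors.
#' @param image_size training resolution (must be divisible by 32); images
#'   are bilinearly resized, masks nearest-neighbor.
#' @param eval_every evaluate on the test split every this many epochs.
#' @param split_ratio train fraction of the 8:2-style split.
#' @param encoder,decoder nested [encoder_config()] / [decoder_config()].
#' @param device kept for config compatibility; only `"cpu"` is supported.
#' @return A list of class `TrainConfig`.
#' @export
train_config <- function(base_lr = 1e-4, betas = c(0.9, 0.999),
                         batch_size = 16L, epochs = 100L, seed = 0L,
                         alpha = 1, weight_decay = 0.01,
                         image_size = 256L, eval_every = 1L,
                         split_ratio = 0.8,
                         encoder = encoder_config(),
                         decoder = NULL,
                         device = "cpu") {
  if (image_size %% 32 != 0) stop("train_config: image_size must be divisible by 32")
  if (alpha < 0 || alpha > 1) stop("train_config: alpha must be in [0, 1]")
  if (batch_size < 1 || epochs < 1) stop("train_config: counts must be positive")
  if (is.null(decoder)) decoder <- decoder_config(skip_channels = encoder$channels)
  structure(list(base_lr = base_lr, betas = betas,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 alpha = alpha, weight_decay = weight_decay,
                 image_size = as.integer(image_size),
                 eval_every = as.integer(eval_every),
                 split_ratio = split_ratio,
                 encoder = encoder, decoder = decoder, device = device),
            class = "TrainConfig")
}

#' Save / load a training configuration as JSON
#' @param cfg a `TrainConfig`.
#' @param path JSON file path.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "TrainConfig"))
  jsonlite::write_json(unclass_deep(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  enc <- do.call(encoder_config, j$encoder)
  dec <- do.call(decoder_config, j$decoder)
  keep <- setdiff(names(j), c("encoder", "decoder"))
  do.call(train_config, c(j[keep], list(encoder = enc, decoder = dec)))
}

prepare_items <- function(images, masks, size) {
  n <- length(images)
  out_i <- vector("list", n)
  out_m <- vector("list", n)
  for (i in seq_len(n)) {
    img <- images[[i]]
    msk <- masks[[i]]
    if (!all(dim(img)[1:2] == c(size, size))) {
      img <- resize_bilinear(img, size, size)
      msk <- resize_mask(msk, size, size)
    }
    out_i[[i]] <- img
    out_m[[i]] <- msk
  }
  list(images = out_i, masks = out_m)
}

assemble_batch <- function(images, masks, ids) {
  H <- dim(images[[ids[1]]])[1]; W <- dim(images[[ids[1]]])[2]
  B <- length(ids)
  x <- array(0, dim = c(H, W, 3, B))
  y <- array(0L, dim = c(H, W, B))
  for (k in seq_along(ids)) {
    x[, , , k] <- images[[ids[k]]]
    y[, , k] <- masks[[ids[k]]]
  }
  list(x = x, y = y)
}

predict_masks_batched <- function(model, images, batch = 8L) {
  n <- length(images)
  preds <- vector("list", n)
  i <- 1L
  while (i <= n) {
    ids <- i:min(i + batch - 1L, n)
    H <- dim(images[[ids[1]]])[1]; W <- dim(images[[ids[1]]])[2]
    x <- array(0, dim = c(H, W, 3, length(ids)))
    for (k in seq_along(ids)) x[, , , k] <- images[[ids[k]]]
    logits <- model_forward(model, x, training = FALSE)
    for (k in seq_along(ids)) {
      fg <- logits[, , 2, k] > logits[, , 1, k]
      m <- matrix(0L, H, W)
      m[fg] <- 1L
      preds[[ids[k]]] <- m
    }
    i <- i + batch
  }
  preds
}

#' Train the segmentation network
#'
#' Runs the AdamW loop over the train split, computes Dice/mIoU/pixel
#' accuracy on the test split every `eval_every` epochs, keeps the
#' best-by-Dice checkpoint and appends a JSON-lines structured log.
#'
#' @param cfg a [train_config()].
#' @param data a `SegmentationBatch` (or list with `images`, `masks`); if
#'   `NULL`, loaded from `data_dir`'s manifest.
#' @param data_dir dataset directory written by [make_dataset()].
#' @param out_dir output directory for `checkpoint.rds`, `log.jsonl` and
#'   `config.json`; `NULL` trains in memory only.
#' @param split optional precomputed list(train, test) of item indices;
#'   defaults to a seeded [split_dataset()] split. Pass identical train and
#'   test ids for overfitting experiments.
#' @param augment optional `function(image, mask)` returning a modified
#'   `list(image, mask)`, applied to every training item each epoch. `NULL`
#'   (the default) trains on the raw data, mirroring the no-augmentation
#'   protocol of the source setting.
#' @return List with `model`, `log` (data frame), `best` (best test-metric
#'   list) and `split`.
#' @export
ts_train <- function(cfg, data = NULL, data_dir = NULL, out_dir = NULL,
                     split = NULL, augment = NULL) {
  stopifnot(inherits(cfg, "TrainConfig"))
  if (is.null(data)) {
    if (is.null(data_dir)) stop("ts_train: provide data or data_dir")
    data <- load_dataset_dir(data_dir)
  }
  n <- length(data$images)
  if (n < 1) stop("ts_train: empty dataset")
  if (length(data$masks) != n) stop("ts_train: images/masks count mismatch")
  if (!is.null(out_dir) && !dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE))
    stop("ts_train: cannot create ", out_dir)

  set.seed(cfg$seed)
  model <- seg_model(cfg$encoder, cfg$decoder)
  opt <- adamw_new(model, lr = cfg$base_lr, betas = cfg$betas,
                   weight_decay = cfg$weight_decay)
  prep <- prepare_items(data$images, data$masks, cfg$image_size)
  if (is.null(split)) split <- split_dataset(n, cfg$split_ratio, cfg$seed)
  train_ids <- split$train
  test_ids <- split$test

  logfile <- if (!is.null(out_dir)) file.path(out_dir, "log.jsonl") else NULL
  if (!is.null(out_dir)) save_config(cfg, file.path(out_dir, "config.json"))
  log_rows <- list()
  emit <- function(rec) {
    log_rows[[length(log_rows) + 1L]] <<- rec
    if (!is.null(logfile))
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          file = logfile, append = TRUE, sep = "")
  }

  best <- list(dice = -Inf)
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(train_ids)
    i <- 1L
    epoch_loss <- 0; nb <- 0L
    while (i <= length(ord)) {
      ids <- ord[i:min(i + cfg$batch_size - 1L, length(ord))]
      b <- assemble_batch(prep$images, prep$masks, ids)
      if (!is.null(augment)) {
        for (k in seq_along(ids)) {
          a <- augment(b$x[, , , k], b$y[, , k])
          b$x[, , , k] <- a[[1]]
          b$y[, , k] <- a[[2]]
        }
      }
      logits <- model_forward(model, b$x, training = TRUE)
      ls <- combined_loss(logits, b$y, alpha = cfg$alpha)
      zero_grads(model)
      model_backward(model, ls$grad)
      adamw_step(opt)
      step <- step + 1L
      epoch_loss <- epoch_loss + ls$loss; nb <- nb + 1L
      emit(list(type = "train", epoch = epoch, step = step, loss = ls$loss))
      i <- i + cfg$batch_size
    }
    if (epoch %% cfg$eval_every == 0 || epoch == cfg$epochs) {
      preds <- predict_masks_batched(model, prep$images[test_ids],
                                     batch = cfg$batch_size)
      ev <- evaluate_masks(preds, prep$masks[test_ids])
      emit(list(type = "eval", epoch = epoch, dice = ev$dice, miou = ev$miou,
                pixel_accuracy = ev$pixel_accuracy,
                mean_train_loss = epoch_loss / max(nb, 1L)))
      if (ev$dice > best$dice) {
        best <- list(dice = ev$dice, miou = ev$miou,
                     pixel_accuracy = ev$pixel_accuracy, epoch = epoch)
        if (!is.null(out_dir))
          save_checkpoint(model, file.path(out_dir, "checkpoint.rds"),
                          extra = list(best = best, config = unclass_deep(cfg)))
      }
    }
  }
  log_df <- do.call(rbind, lapply(log_rows, function(r)
    as.data.frame(r[c("type", "epoch")], stringsAsFactors = FALSE)))
  list(model = model, log = log_rows, log_summary = log_df, best = best,
       split = split)
}

#' Load a dataset directory written by [make_dataset()]
#' @param dir directory containing `manifest.csv`.
#' @return List with `images`, `masks`, `manifest`.
#' @export
load_dataset_dir <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("load_dataset_dir: no manifest.csv in ", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  images <- lapply(file.path(dir, manifest$image_path), read_image)
  masks <- lapply(file.path(dir, manifest$mask_path), read_mask)
  list(images = images, masks = masks, manifest = manifest)
}

#' Evaluate a model (or checkpoint) on a dataset
#'
#' @param model a model module or path to a checkpoint `.rds`.
#' @param data a `SegmentationBatch`/list with `images` and `masks`, or
#'   `NULL` to load `data_dir`.
#' @param data_dir dataset directory.
#' @param image_size evaluation resolution (divisible by 32).
#' @param out optional path prefix; writes `<out>.csv` (per image) and
#'   `<out>.json` (aggregates).
#' @param average `"micro"` (default) or `"macro"`.
#' @return The [evaluate_masks()] result.
#' @export
ts_evaluate <- function(model, data = NULL, data_dir = NULL, image_size = 64L,
                        out = NULL, average = "micro") {
  if (is.character(model)) model <- load_checkpoint(model)
  if (is.null(data)) {
    if (is.null(data_dir)) stop("ts_evaluate: provide data or data_dir")
    data <- load_dataset_dir(data_dir)
  }
  if (length(data$images) == 0) stop("ts_evaluate: empty dataset")
  prep <- prepare_items(data$images, data$masks, image_size)
  preds <- predict_masks_batched(model, prep$images)
  ev <- evaluate_masks(preds, prep$masks, average = average)
  if (!is.null(out)) {
    utils::write.csv(ev$per_image, paste0(out, ".csv"), row.names = FALSE)
    jsonlite::write_json(list(dice = ev$dice, miou = ev$miou,
                              pixel_accuracy = ev$pixel_accuracy,
                              n = length(preds), average = average),
                         paste0(out, ".json"), auto_unbox = TRUE, digits = NA)
  }
  ev
}

#' Segment images from disk and write masks + red overlays
#'
#' @param model a model module or checkpoint path.
#' @param image_paths character vector of image files.
#' @param out_dir output directory; writes `<name>_mask.png` and
#'   `<name>_overlay.png` per input.
#' @return Invisibly, the data frame of output paths.
#' @export
ts_predict <- function(model, image_paths, out_dir) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("ts_predict: cannot create ", out_dir)
  res <- data.frame(input = image_paths, mask = NA_character_,
                    overlay = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(image_paths)) {
    img <- read_image(image_paths[i])
    mask <- segment_image(model, img)
    base <- tools::file_path_sans_ext(basename(image_paths[i]))
    mp <- file.path(out_dir, paste0(base, "_mask.png"))
    op <- file.path(out_dir, paste0(base, "_overlay.png"))
    write_mask(mp, mask)
    write_image(op, overlay_mask(img, mask))
    res$mask[i] <- mp
    res$overlay[i] <- op
  }
  invisible(res)
}
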