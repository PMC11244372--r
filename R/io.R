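# Image and mask I/O plus simple resampling helpers. Images live in memory
# as H x W x 3 arrays in [0, 1]; masks as integer H x W matrices in {0, 1}.
# On disk masks are single-channel PNG with values {0, 255}.

#' Read an RGB image (PNG or JPEG)
#'
#' Grayscale images are replicated to three channels, alpha is dropped.
#'
#' @param path file path.
#' @return H x W x 3 array in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    if (ext %in% c("jpg", "jpeg")) jpeg::readJPEG(path) else png::readPNG(path)
  }, error = function(e) stop("read_image: cannot decode ", path, ": ",
                              conditionMessage(e)))
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1) img <- array(rep(img, 3), dim = c(dim(img)[1:2], 3))
  img
}

#' Write an RGB image as PNG
#' @param path destination path.
#' @param img H x W x 3 array in \[0, 1\].
#' @export
write_image <- function(path, img) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read a binary mask (any nonzero pixel becomes foreground)
#' @param path single-channel PNG path.
#' @return Integer H x W matrix in \{0, 1\}.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("read_mask: no such file: ", path)
  m <- tryCatch(png::readPNG(path),
                error = function(e) stop("read_mask: cannot decode ", path,
                                         ": ", conditionMessage(e)))
  if (!is.matrix(m)) m <- m[, , 1, drop = TRUE]
  out <- matrix(0L, nrow(m), ncol(m))
  out[m > 0] <- 1L
  out
}

#' Write a binary mask as single-channel PNG ({0, 255} on disk)
#' @param path destination path.
#' @param mask H x W matrix; any nonzero value is foreground.
#' @export
write_mask <- function(path, mask) {
  m <- matrix(0, nrow(mask), ncol(mask))
  m[mask != 0] <- 1
  png::writePNG(m, path)
  invisible(path)
}

#' Bilinear resize of an image array
#' @param img H x W x C array (or matrix).
#' @param H,W target size.
#' @return Resized array.
#' @export
resize_bilinear <- function(img, H, W) {
  was_mat <- is.matrix(img)
  if (was_mat) img <- array(img, dim = c(dim(img), 1L))
  d <- dim(img)
  # map target pixel centers into source coordinates
  ys <- (seq_len(H) - 0.5) * d[1] / H + 0.5 - 1e-9
  xs <- (seq_len(W) - 0.5) * d[2] / W + 0.5 - 1e-9
  y0 <- pmin(pmax(floor(ys), 1), d[1]); y1 <- pmin(y0 + 1, d[1])
  x0 <- pmin(pmax(floor(xs), 1), d[2]); x1 <- pmin(x0 + 1, d[2])
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, dim = c(H, W, d[3]))
  for (ch in seq_len(d[3])) {
    s <- img[, , ch, drop = TRUE]
    a <- s[y0, x0, drop = FALSE] * outer(1 - wy, 1 - wx) +
      s[y1, x0, drop = FALSE] * outer(wy, 1 - wx) +
      s[y0, x1, drop = FALSE] * outer(1 - wy, wx) +
      s[y1, x1, drop = FALSE] * outer(wy, wx)
    out[, , ch] <- a
  }
  if (was_mat) out[, , 1, drop = TRUE] else out
}

#' Nearest-neighbor resize of a mask
#' @param mask H x W matrix.
#' @param H,W target size.
#' @return Resized integer matrix.
#' @export
resize_mask <- function(mask, H, W) {
  d <- dim(mask)
  yi <- pmin(pmax(ceiling((seq_len(H) - 0.5) * d[1] / H), 1), d[1])
  xi <- pmin(pmax(ceiling((seq_len(W) - 0.5) * d[2] / W), 1), d[2])
  out <- mask[yi, xi, drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Red-overlay visualization of a mask on an image
#' @param img H x W x 3 array.
#' @param mask H x W binary matrix.
#' @param alpha overlay opacity.
#' @return H x W x 3 array.
#' @export
overlay_mask <- function(img, mask, alpha = 0.45) {
  out <- img
  sel <- mask != 0
  out[, , 1][sel] <- (1 - alpha) * out[, , 1][sel] + alpha * 1
  out[, , 2][sel] <- (1 - alpha) * out[, , 2][sel]
  out[, , 3][sel] <- (1 - alpha) * out[, , 3][sel]
  out
}
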