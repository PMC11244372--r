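# Pixel-confusion bookkeeping, the Dice / mIoU / pixel-accuracy metrics, and
# the training losses (cross-entropy; optional boundary loss driven by a
# signed distance map of the ground truth).

#' Pixel confusion counts
#'
#' Exact integer tallies of true/false positives/negatives between two
#' binary masks (foreground = 1).
#'
#' @param pred,truth binary matrices (or arrays) of identical shape.
#' @return List of class `ConfusionCounts` with fields `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("confusion: shape mismatch")
  p <- as.integer(pred)
  t <- as.integer(truth)
  if (!all(p %in% c(0L, 1L)) || !all(t %in% c(0L, 1L)))
    stop("confusion: masks must be binary (0/1)")
  structure(list(TP = sum(p == 1L & t == 1L), TN = sum(p == 0L & t == 0L),
                 FP = sum(p == 1L & t == 0L), FN = sum(p == 0L & t == 1L)),
            class = "ConfusionCounts")
}

# IoU-style ratio with the empty-region convention: 1 if the class is
# absent from both masks, 0 if absent from exactly one.
safe_ratio <- function(num, den) {
  if (den == 0) return(1)
  num / den
}

#' Dice similarity coefficient
#'
#' `2 TP / (FP + 2 TP + FN)`; returns 1 when both regions are empty.
#' @param c a `ConfusionCounts`.
#' @return Score in \[0, 1\].
#' @export
dice <- function(c) {
  stopifnot(inherits(c, "ConfusionCounts"))
  safe_ratio(2 * c$TP, c$FP + 2 * c$TP + c$FN)
}

#' Mean intersection over union
#'
#' Mean of the foreground IoU `TP/(TP+FP+FN)` and background IoU
#' `TN/(TN+FN+FP)`, with the empty-class convention of [dice()].
#' @param c a `ConfusionCounts`.
#' @return Score in \[0, 1\].
#' @export
miou <- function(c) {
  stopifnot(inherits(c, "ConfusionCounts"))
  (safe_ratio(c$TP, c$TP + c$FP + c$FN) +
     safe_ratio(c$TN, c$TN + c$FN + c$FP)) / 2
}

#' Pixel accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#' @param c a `ConfusionCounts`.
#' @return Score in \[0, 1\].
#' @export
pixel_accuracy <- function(c) {
  stopifnot(inherits(c, "ConfusionCounts"))
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) return(1)
  (c$TP + c$TN) / total
}

#' Signed Euclidean distance to the mask boundary
#'
#' The boundary is the set of foreground pixels with a 4-neighbor in the
#' background. `phi` is 0 on the boundary, `-d` inside the region and `+d`
#' outside, where `d` is the exact Euclidean distance (in pixels) to the
#' nearest boundary pixel. Degenerate masks (no boundary: all foreground or
#' all background) yield an all-zero map with a warning.
#'
#' @param truth binary matrix.
#' @return Numeric matrix `phi` of the same shape.
#' @export
signed_distance <- function(truth) {
  if (!is.matrix(truth)) stop("signed_distance: need a matrix mask")
  if (!all(truth %in% c(0, 1))) stop("signed_distance: mask must be binary (0/1)")
  t <- truth
  storage.mode(t) <- "integer"
  if (all(t == 1L) || all(t == 0L)) {
    warning("signed_distance: degenerate mask (no boundary); returning zeros")
    return(matrix(0, nrow(t), ncol(t)))
  }
  cpp_signed_distance(t)
}

#' Boundary loss
#'
#' Discretized `integral of phi_G(q) * s_theta(q)`: the mean over pixels of
#' the signed distance map times the predicted foreground probability. The
#' mean (not the sum) keeps the scale resolution-independent.
#'
#' @param probs foreground probabilities in \[0, 1\], same shape as `phi`.
#' @param phi signed distance map from [signed_distance()].
#' @return Scalar loss (negative when probability mass sits inside the
#'   ground-truth region).
#' @export
boundary_loss <- function(probs, phi) {
  if (!identical(dim(probs), dim(phi)))
    stop("boundary_loss: shape mismatch")
  if (any(probs < -1e-9) || any(probs > 1 + 1e-9))
    stop("boundary_loss: probs must lie in [0, 1]")
  mean(phi * probs)
}

softmax2 <- function(logits) {
  # logits: H x W x 2 x N -> foreground probability H x W x N (and bg)
  l0 <- logits[, , 1, , drop = FALSE]
  l1 <- logits[, , 2, , drop = FALSE]
  mx <- pmax(l0, l1)
  e0 <- exp(l0 - mx)
  e1 <- exp(l1 - mx)
  p1 <- e1 / (e0 + e1)
  d <- dim(logits)
  array(p1, dim = c(d[1], d[2], d[4]))
}

#' Cross-entropy loss for two-class logits
#'
#' @param logits array H x W x 2 x N.
#' @param truth binary array H x W x N (or H x W matrix for N = 1).
#' @return List with `loss` (mean negative log-likelihood per pixel) and
#'   `grad` (same shape as `logits`).
#' @export
ce_loss <- function(logits, truth) {
  d <- dim(logits)
  if (length(d) != 4 || d[3] != 2) stop("ce_loss: logits must be H x W x 2 x N")
  if (is.matrix(truth)) truth <- array(truth, dim = c(dim(truth), 1L))
  if (!all(dim(truth) == d[c(1, 2, 4)])) stop("ce_loss: truth shape mismatch")
  l0 <- logits[, , 1, , drop = TRUE]
  l1 <- logits[, , 2, , drop = TRUE]
  dim(l0) <- d[c(1, 2, 4)]; dim(l1) <- d[c(1, 2, 4)]
  mx <- pmax(l0, l1)
  lse <- mx + log(exp(l0 - mx) + exp(l1 - mx))
  lt <- ifelse(truth > 0, l1, l0)
  npix <- prod(d[c(1, 2, 4)])
  loss <- sum(lse - lt) / npix
  p1 <- exp(l1 - lse)
  g1 <- (p1 - (truth > 0)) / npix
  grad <- array(0, dim = d)
  grad[, , 1, ] <- -g1
  grad[, , 2, ] <- g1
  list(loss = loss, grad = grad)
}

#' Combined cross-entropy + boundary loss
#'
#' `alpha * CE + (1 - alpha) * L_B`; `alpha = 1` is exactly plain
#' cross-entropy (the shipped configuration), `alpha = 0` the pure boundary
#' loss of the softmaxed logits.
#'
#' @param logits array H x W x 2 x N.
#' @param truth binary array H x W x N.
#' @param alpha mixing weight in \[0, 1\].
#' @param phi optional precomputed list/array of signed distance maps (one
#'   H x W matrix per sample); computed from `truth` when omitted.
#' @return List with `loss` and `grad` (with respect to the logits).
#' @export
combined_loss <- function(logits, truth, alpha = 1, phi = NULL) {
  if (alpha < 0 || alpha > 1) stop("combined_loss: alpha must be in [0, 1]")
  ce <- ce_loss(logits, truth)
  if (alpha == 1) return(ce)
  d <- dim(logits)
  if (is.matrix(truth)) truth <- array(truth, dim = c(dim(truth), 1L))
  if (is.null(phi)) {
    phi <- array(0, dim = dim(truth))
    for (n in seq_len(d[4]))
      phi[, , n] <- suppressWarnings(signed_distance(truth[, , n, drop = TRUE]))
  } else if (is.list(phi)) {
    phi <- array(unlist(phi), dim = dim(truth))
  }
  l0 <- logits[, , 1, , drop = TRUE]
  l1 <- logits[, , 2, , drop = TRUE]
  dim(l0) <- d[c(1, 2, 4)]; dim(l1) <- d[c(1, 2, 4)]
  mx <- pmax(l0, l1)
  lse <- mx + log(exp(l0 - mx) + exp(l1 - mx))
  p1 <- exp(l1 - lse)
  npix <- prod(d[c(1, 2, 4)])
  bl <- sum(phi * p1) / npix
  gb1 <- phi * p1 * (1 - p1) / npix
  gb <- array(0, dim = d)
  gb[, , 1, ] <- -gb1
  gb[, , 2, ] <- gb1
  list(loss = alpha * ce$loss + (1 - alpha) * bl,
       grad = alpha * ce$grad + (1 - alpha) * gb)
}

#' Aggregate segmentation metrics over a set of mask pairs
#'
#' @param preds,truths lists of binary matrices.
#' @param average `"micro"` accumulates confusion counts globally before
#'   computing the metrics (default); `"macro"` averages per-image scores.
#' @return List with `dice`, `miou`, `pixel_accuracy` and the per-image
#'   data frame `per_image`.
#' @export
evaluate_masks <- function(preds, truths, average = c("micro", "macro")) {
  average <- match.arg(average)
  stopifnot(length(preds) == length(truths), length(preds) >= 1)
  per <- data.frame(id = seq_along(preds), dice = NA_real_, miou = NA_real_,
                    pixel_accuracy = NA_real_)
  tot <- list(TP = 0, TN = 0, FP = 0, FN = 0)
  for (i in seq_along(preds)) {
    cc <- confusion(preds[[i]], truths[[i]])
    per$dice[i] <- dice(cc)
    per$miou[i] <- miou(cc)
    per$pixel_accuracy[i] <- pixel_accuracy(cc)
    for (f in names(tot)) tot[[f]] <- tot[[f]] + cc[[f]]
  }
  if (average == "micro") {
    cc <- structure(tot, class = "ConfusionCounts")
    list(dice = dice(cc), miou = miou(cc), pixel_accuracy = pixel_accuracy(cc),
         per_image = per)
  } else {
    list(dice = mean(per$dice), miou = mean(per$miou),
         pixel_accuracy = mean(per$pixel_accuracy), per_image = per)
  }
}
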