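test_that("confusion counts match hand fixtures and reject bad input", {
  ones <- matrix(1L, 4, 4)
  cc <- confusion(ones, ones)
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 16L, TN = 0L, FP = 0L, FN = 0L))
  cc2 <- confusion(1L - ones, ones)
  expect_equal(cc2$TP + cc2$TN, 0L)
  # 6 agreeing foreground, 2 false positives, 2 false negatives on 16 px
  truth <- matrix(0L, 4, 4); truth[1:2, 1:4] <- 1L          # 8 fg
  pred <- truth
  pred[2, 3:4] <- 0L                                        # 2 FN
  pred[4, 1:2] <- 1L                                        # 2 FP
  cc3 <- confusion(pred, truth)
  expect_equal(unclass(cc3)[c("TP", "TN", "FP", "FN")],
               list(TP = 6L, TN = 6L, FP = 2L, FN = 2L))
  expect_error(confusion(matrix(0L, 3, 3), ones), "shape")
  expect_error(confusion(matrix(2L, 4, 4), ones), "binary")
})

test_that("Dice, mIoU and PA match the printed formulas on the fixture", {
  fx <- structure(list(TP = 6, TN = 6, FP = 2, FN = 2),
                  class = "ConfusionCounts")
  expect_equal(dice(fx), 0.75)
  expect_equal(miou(fx), 0.6)
  expect_equal(pixel_accuracy(fx), 0.75)
  perfect <- structure(list(TP = 10, TN = 6, FP = 0, FN = 0),
                       class = "ConfusionCounts")
  expect_equal(dice(perfect), 1)
  expect_equal(miou(perfect), 1)
  expect_equal(pixel_accuracy(perfect), 1)
  # all-foreground prediction on half-foreground truth
  half <- structure(list(TP = 8, TN = 0, FP = 8, FN = 0),
                    class = "ConfusionCounts")
  expect_equal(miou(half), 0.25)
  # zero-numerator and empty-region conventions
  expect_equal(dice(structure(list(TP = 0, TN = 12, FP = 2, FN = 2),
                              class = "ConfusionCounts")), 0)
  expect_equal(dice(structure(list(TP = 0, TN = 16, FP = 0, FN = 0),
                              class = "ConfusionCounts")), 1)
  allwrong <- structure(list(TP = 0, TN = 0, FP = 8, FN = 8),
                        class = "ConfusionCounts")
  expect_equal(pixel_accuracy(allwrong), 0)
})

test_that("metrics agree exactly with the double-loop oracle on random masks", {
  set.seed(31)
  for (i in 1:100) {
    pred <- matrix(rbinom(256, 1, runif(1, 0.2, 0.8)), 16, 16)
    truth <- matrix(rbinom(256, 1, runif(1, 0.2, 0.8)), 16, 16)
    co <- confusion_oracle(pred, truth)
    cc <- confusion(pred, truth)
    expect_identical(unclass(cc)[c("TP", "TN", "FP", "FN")], co)
  }
})

test_that("all three metrics equal 1 iff the masks are identical", {
  set.seed(32)
  for (i in 1:20) {
    truth <- matrix(rbinom(64, 1, 0.5), 8, 8)
    if (all(truth == 0) || all(truth == 1)) next
    cc <- confusion(truth, truth)
    expect_equal(c(dice(cc), miou(cc), pixel_accuracy(cc)), c(1, 1, 1))
    flip <- truth
    idx <- sample(64, 1)
    flip[idx] <- 1L - flip[idx]
    cf <- confusion(flip, truth)
    expect_true(dice(cf) < 1 && miou(cf) < 1 && pixel_accuracy(cf) < 1)
  }
})

test_that("Dice and mIoU are monotone in TP at fixed totals", {
  # move one pixel from FN to TP (overlap grows, totals fixed)
  base <- structure(list(TP = 5, TN = 6, FP = 2, FN = 3),
                    class = "ConfusionCounts")
  more <- structure(list(TP = 6, TN = 6, FP = 2, FN = 2),
                    class = "ConfusionCounts")
  expect_gt(dice(more), dice(base))
  expect_gt(miou(more), miou(base))
})

test_that("signed distance matches the brute-force oracle exactly", {
  m <- matrix(0L, 8, 8); m[3:6, 3:6] <- 1L
  expect_equal(signed_distance(m), signed_distance_oracle(m))
  set.seed(33)
  for (i in 1:10) {
    mm <- matrix(rbinom(100, 1, 0.4), 10, 10)
    if (all(mm == 0) || all(mm == 1)) next
    expect_equal(signed_distance(mm), signed_distance_oracle(mm))
  }
})

test_that("signed distance sign structure and Lipschitz property", {
  m <- matrix(0L, 7, 7); m[4, 4] <- 1L
  phi <- signed_distance(m)
  expect_lte(phi[4, 4], 0)
  expect_true(all(phi[cbind(c(3, 5, 4, 4), c(4, 4, 3, 5))] > 0))
  set.seed(34)
  mm <- matrix(rbinom(144, 1, 0.5), 12, 12)
  mm[1, 1] <- 1L; mm[12, 12] <- 0L
  phi <- signed_distance(mm)
  expect_true(all(abs(diff(phi)) <= 1 + 1e-9))        # vertical neighbors
  expect_true(all(abs(t(diff(t(phi)))) <= 1 + 1e-9))  # horizontal neighbors
  # degenerate masks: all-zero map with a warning
  expect_warning(z <- signed_distance(matrix(1L, 4, 4)), "degenerate")
  expect_equal(z, matrix(0, 4, 4))
  expect_error(signed_distance(matrix(0.5, 4, 4)), "binary")
})

test_that("boundary loss: zero input, inside mass, and overlap monotonicity", {
  m <- matrix(0L, 8, 8); m[3:6, 3:6] <- 1L
  phi <- signed_distance(m)
  expect_equal(boundary_loss(matrix(0, 8, 8), phi), 0)
  probs_in <- matrix(0, 8, 8); probs_in[m == 1] <- 1
  expect_equal(boundary_loss(probs_in, phi), sum(phi[m == 1]) / 64)
  expect_lt(boundary_loss(probs_in, phi), 0)
  # moving probability mass from outside to inside strictly decreases it
  set.seed(35)
  for (i in 1:10) {
    p <- matrix(runif(64, 0.1, 0.9), 8, 8)
    out_px <- which(m == 0 & p > 0.2)[1]
    in_px <- which(m == 1 & p < 0.8)[1]
    p2 <- p
    p2[out_px] <- p[out_px] - 0.1
    p2[in_px] <- p[in_px] + 0.1
    expect_lt(boundary_loss(p2, phi), boundary_loss(p, phi))
  }
  expect_error(boundary_loss(matrix(0, 4, 4), phi), "shape")
})

test_that("combined loss endpoints and linearity in alpha", {
  set.seed(36)
  logits <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  truth <- array(0L, c(8, 8, 2)); truth[3:6, 3:6, ] <- 1L
  ce <- ce_loss(logits, truth)
  l1 <- combined_loss(logits, truth, alpha = 1)
  expect_identical(l1$loss, ce$loss)           # alpha = 1 is exactly CE
  expect_identical(l1$grad, ce$grad)
  l0 <- combined_loss(logits, truth, alpha = 0)
  probs <- array(0, c(8, 8, 2))
  for (n in 1:2) {
    p <- exp(logits[, , 2, n]) / (exp(logits[, , 1, n]) + exp(logits[, , 2, n]))
    probs[, , n] <- p
  }
  phi1 <- signed_distance(truth[, , 1])
  bl_manual <- (sum(phi1 * probs[, , 1]) + sum(phi1 * probs[, , 2])) / (64 * 2)
  expect_equal(l0$loss, bl_manual, tolerance = 1e-10)
  # collinearity across three alphas
  lm <- combined_loss(logits, truth, alpha = 0.4)
  expect_equal(lm$loss, 0.4 * l1$loss + 0.6 * l0$loss, tolerance = 1e-10)
  expect_error(combined_loss(logits, truth, alpha = 1.5), "alpha")
})

test_that("ce_loss gradient matches numeric differentiation", {
  set.seed(37)
  logits <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  truth <- array(rbinom(32, 1, 0.5), c(4, 4, 2))
  r <- ce_loss(logits, truth)
  f <- function(v) { ll <- logits; ll[] <- v; ce_loss(ll, truth)$loss }
  expect_equal(as.numeric(r$grad), numeric_grad(f, as.numeric(logits)),
               tolerance = 1e-7)
  rb <- combined_loss(logits, truth, alpha = 0.3)
  fb <- function(v) { ll <- logits; ll[] <- v; combined_loss(ll, truth, 0.3)$loss }
  expect_equal(as.numeric(rb$grad), numeric_grad(fb, as.numeric(logits)),
               tolerance = 1e-7)
})

test_that("micro and macro aggregation behave as documented", {
  p1 <- matrix(1L, 4, 4); t1 <- matrix(1L, 4, 4)
  p2 <- matrix(0L, 4, 4); t2 <- matrix(1L, 4, 4)
  micro <- evaluate_masks(list(p1, p2), list(t1, t2), average = "micro")
  macro <- evaluate_masks(list(p1, p2), list(t1, t2), average = "macro")
  expect_equal(micro$dice, 2 * 16 / (0 + 2 * 16 + 16))
  expect_equal(macro$dice, (1 + 0) / 2)
  expect_equal(nrow(micro$per_image), 2)
})
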