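test_that("scene generation is a pure function of its spec", {
  sp <- scene_spec(99, size = 48, tongue_shape = "tooth_marked",
                   scale_fraction = 0.2, n_spots = 2)
  s1 <- generate_scene(sp)
  s2 <- generate_scene(sp)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  # a different seed changes the scene
  s3 <- generate_scene(scene_spec(100, size = 48, tongue_shape = "tooth_marked",
                                  scale_fraction = 0.2, n_spots = 2))
  expect_false(identical(s1$mask, s3$mask))
  # generation does not disturb the global RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(generate_scene(sp)); b <- runif(1)
  expect_identical(a, b)
})

test_that("spec validation rejects out-of-range scale fractions", {
  expect_error(scene_spec(1, scale_fraction = 0.01), "scale_fraction")
  expect_error(scene_spec(1, scale_fraction = 0.7), "scale_fraction")
  expect_error(scene_spec(1, tongue_shape = "octopus"))
})

test_that("mask area tracks the requested scale fraction within 10%", {
  for (seed in 1:6) {
    for (frac in c(0.1, 0.2, 0.3)) {
      sp <- scene_spec(seed, size = 96, scale_fraction = frac,
                       tongue_shape = TONGUE_SHAPES[(seed %% 4) + 1])
      m <- generate_scene(sp)$mask
      expect_lt(abs(sum(m) / length(m) - frac) / frac, 0.10,
                label = sprintf("seed %d frac %.2f rel err", seed, frac))
    }
  }
})

test_that("tooth-marked boundaries are longer than smooth ones at equal area", {
  perimeter <- function(mask) {
    H <- nrow(mask); W <- ncol(mask)
    p <- 0L
    for (i in seq_len(H)) for (j in seq_len(W)) {
      if (mask[i, j] != 1) next
      if (i == 1 || mask[i - 1, j] == 0 || i == H || mask[i + 1, j] == 0 ||
          j == 1 || mask[i, j - 1] == 0 || j == W || mask[i, j + 1] == 0)
        p <- p + 1L
    }
    p
  }
  wins <- 0L
  for (seed in 1:5) {
    ms <- generate_scene(scene_spec(seed, 96, "smooth", 0.25))$mask
    mt <- generate_scene(scene_spec(seed, 96, "tooth_marked", 0.25))$mask
    # areas match by construction (same scale fraction)
    expect_lt(abs(sum(ms) - sum(mt)) / sum(ms), 0.1)
    if (perimeter(mt) > perimeter(ms)) wins <- wins + 1L
  }
  expect_gte(wins, 4L)   # scalloping lengthens the boundary
})

test_that("each shape family renders a mask consistent with its image", {
  for (shape in TONGUE_SHAPES) {
    sc <- generate_scene(scene_spec(3, 64, shape, 0.25))
    expect_equal(dim(sc$image), c(64, 64, 3))
    expect_equal(dim(sc$mask), c(64, 64))
    expect_true(all(sc$mask %in% c(0L, 1L)))
    expect_true(all(sc$image >= 0 & sc$image <= 1))
    expect_gt(sum(sc$mask), 0)
    expect_lt(sum(sc$mask), length(sc$mask))
  }
})

test_that("make_dataset writes a complete, reloadable on-disk layout", {
  dir <- file.path(tempdir(), "ts_ds_test")
  on.exit(unlink(dir, recursive = TRUE))
  ds <- make_dataset(10, size = 32, seed = 5, dir = dir)
  expect_length(ds$images, 10)
  expect_equal(nrow(ds$manifest), 10)
  expect_length(list.files(file.path(dir, "images")), 10)
  expect_length(list.files(file.path(dir, "masks")), 10)
  # masks reload losslessly ({0,255} PNG -> {0,1})
  back <- load_dataset_dir(dir)
  for (i in 1:10) expect_identical(back$masks[[i]], ds$masks[[i]])
  # dataset generation is a pure function of (n, size, seed)
  ds2 <- make_dataset(10, size = 32, seed = 5)
  expect_identical(ds2$images, ds$images)
  expect_identical(ds2$masks, ds$masks)
  expect_error(make_dataset(0), "n must be")
})

test_that("shape families are drawn uniformly enough at n = 400", {
  ds <- make_dataset(400, size = 8, seed = 9)
  counts <- table(ds$manifest$shape_family)
  expect_setequal(names(counts), TONGUE_SHAPES)
  expect_true(all(counts >= 60))
})

test_that("split_dataset honors the 8:2 convention and is reproducible", {
  sp <- split_dataset(416, ratio = 0.8, seed = 4)
  expect_length(sp$train, 333)   # round-half-up of 332.8
  expect_length(sp$test, 83)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:416)
  expect_identical(sp, split_dataset(416, ratio = 0.8, seed = 4))
  expect_false(identical(sp$train, split_dataset(416, 0.8, seed = 5)$train))
  expect_error(split_dataset(1), "at least 2")
  expect_error(split_dataset(10, ratio = 1.2), "ratio")
})

test_that("image and mask I/O round-trips through PNG", {
  set.seed(71)
  img <- array(runif(20 * 30 * 3), c(20, 30, 3))
  p <- tempfile(fileext = ".png")
  write_image(p, img)
  back <- read_image(p)
  expect_equal(dim(back), c(20, 30, 3))
  expect_lt(max(abs(back - img)), 1 / 255)      # 8-bit quantization only
  mask <- matrix(rbinom(600, 1, 0.5), 20, 30)
  pm <- tempfile(fileext = ".png")
  write_mask(pm, mask)
  expect_identical(read_mask(pm), matrix(as.integer(mask), 20, 30))
  expect_error(read_image(tempfile(fileext = ".png")), "no such file")
  unlink(c(p, pm))
})

test_that("grayscale images are promoted to RGB on read", {
  g <- matrix(runif(64), 8, 8)
  p <- tempfile(fileext = ".png")
  png::writePNG(g, p)
  img <- read_image(p)
  expect_equal(dim(img), c(8, 8, 3))
  expect_equal(img[, , 1], img[, , 2])
  unlink(p)
})

test_that("resize helpers preserve geometry contracts", {
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  r <- resize_bilinear(img, 32, 24)
  expect_equal(dim(r), c(32, 24, 3))
  expect_true(all(r >= min(img) - 1e-9 & r <= max(img) + 1e-9))
  # upscaling a constant image is exact
  cimg <- array(0.4, c(8, 8, 1))
  expect_equal(resize_bilinear(cimg, 16, 16), array(0.4, c(16, 16, 1)))
  m <- matrix(rbinom(64, 1, 0.5), 8, 8)
  rm2 <- resize_mask(m, 16, 16)
  expect_true(all(rm2 %in% c(0L, 1L)))
  expect_identical(resize_mask(m, 8, 8), matrix(as.integer(m), 8, 8))
})
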