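# Seeded generator of tongue-like scenes. The generator does not attempt
# photo-realism; it targets the failure modes that make phone-photo tongue
# segmentation hard: scalloped (tooth-marked) edges, an inward tip notch,
# twisted/sheared poses, whitish coating, pigment spots, lip-colored
# distractor bands, face-tone background clutter and illumination jitter.

TONGUE_SHAPES <- c("smooth", "tooth_marked", "w_tip", "twisted")

#' Scene specification for the synthetic generator
#'
#' @param seed RNG seed; the same spec renders bit-identical scenes.
#' @param size output size in pixels (scalar for square, or c(H, W)).
#' @param tongue_shape one of `"smooth"`, `"tooth_marked"` (scalloped edge),
#'   `"w_tip"` (inward tip notch), `"twisted"` (sheared/rotated).
#' @param scale_fraction tongue area as a fraction of the frame, in
#'   (0.02, 0.6).
#' @param coating logical; render a whitish central coating.
#' @param n_spots number of dark pigment spots on the tongue.
#' @param distractors logical; render lip-colored bands and background
#'   clutter.
#' @param illumination logical; apply brightness/color-temperature jitter.
#' @return A list of class `SceneSpec`.
#' @export
scene_spec <- function(seed, size = 64L, tongue_shape = "smooth",
                       scale_fraction = 0.2, coating = TRUE, n_spots = 0L,
                       distractors = TRUE, illumination = TRUE) {
  tongue_shape <- match.arg(tongue_shape, TONGUE_SHAPES)
  if (length(size) == 1) size <- c(size, size)
  if (scale_fraction <= 0.02 || scale_fraction >= 0.6)
    stop("scene_spec: scale_fraction must lie in (0.02, 0.6)")
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 tongue_shape = tongue_shape,
                 scale_fraction = scale_fraction, coating = isTRUE(coating),
                 n_spots = as.integer(n_spots),
                 distractors = isTRUE(distractors),
                 illumination = isTRUE(illumination)),
            class = "SceneSpec")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

soft_disc <- function(X, Y, cx, cy, r) {
  d2 <- (X - cx)^2 + (Y - cy)^2
  pmax(0, 1 - d2 / r^2)
}

#' Render a synthetic tongue scene
#'
#' @param spec a [scene_spec()].
#' @return List with `image` (H x W x 3 array in \[0, 1\]) and `mask`
#'   (integer H x W matrix, 1 = tongue).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "SceneSpec"))
  H <- spec$size[1]; W <- spec$size[2]
  with_local_seed(spec$seed, {
    # --- tongue geometry: superellipse radius with edge modifiers ---
    p <- runif(1, 1.8, 3)
    rho <- runif(1, 0.75, 1.35)                 # b / a aspect
    gp <- gamma(1 + 1 / p)^2 / gamma(1 + 2 / p) # superellipse area factor
    area <- spec$scale_fraction * H * W
    amp <- 0; kscall <- 0; notch_depth <- 0; notch_w <- 0
    if (spec$tongue_shape == "tooth_marked") {
      amp <- runif(1, 0.05, 0.09)
      kscall <- sample(8:14, 1)
    }
    if (spec$tongue_shape == "w_tip") {
      notch_depth <- runif(1, 0.25, 0.4)
      notch_w <- runif(1, 0.18, 0.28)
    }
    radial_mod <- function(theta) {
      m <- rep(1, length(theta))
      if (amp > 0) m <- m * (1 + amp * sin(kscall * theta))
      if (notch_depth > 0)
        m <- m * (1 - notch_depth * exp(-((theta - pi / 2) / notch_w)^2))
      m
    }
    # renormalize semi-axes so the rendered area matches scale_fraction
    thg <- seq(0, 2 * pi, length.out = 721)[-721]
    mod_area_factor <- mean(radial_mod(thg)^2)
    ab <- area / (4 * gp * mod_area_factor)
    a <- sqrt(ab / rho); b <- a * rho
    shear <- 0; rot <- 0
    if (spec$tongue_shape == "twisted") {
      shear <- runif(1, 0.25, 0.45) * sample(c(-1, 1), 1)
      rot <- runif(1, 0.15, 0.35) * sample(c(-1, 1), 1)
    }
    sup_radius <- function(theta) {
      (abs(cos(theta) / a)^p + abs(sin(theta) / b)^p)^(-1 / p)
    }
    rmax <- max(sup_radius(thg) * radial_mod(thg)) * (1 + abs(shear))
    cx <- runif(1, min(rmax + 1, W / 2), max(W - rmax - 1, W / 2))
    cy <- runif(1, min(rmax + 1, H / 2), max(H - rmax - 1, H / 2))

    X <- matrix(rep(seq_len(W), each = H), H, W)   # column coordinate
    Y <- matrix(rep(seq_len(H), W), H, W)          # row coordinate
    U <- X - cx; V <- Y - cy
    if (spec$tongue_shape == "twisted") {
      # inverse of rotate-then-shear (both area preserving)
      U1 <- U - shear * V; V1 <- V
      U2 <- cos(rot) * U1 + sin(rot) * V1
      V2 <- -sin(rot) * U1 + cos(rot) * V1
      U <- U2; V <- V2
    }
    theta <- atan2(V, U)
    rr <- sqrt(U^2 + V^2)
    Rb <- sup_radius(theta) * radial_mod(theta)
    mask <- matrix(0L, H, W)
    mask[rr <= Rb] <- 1L
    if (sum(mask) == 0) stop("generate_scene: degenerate spec (zero-area tongue)")

    # --- colors ---
    img <- array(0, dim = c(H, W, 3))
    skin <- c(0.84, 0.70, 0.60) + runif(3, -0.05, 0.05)
    grad <- (Y / H - 0.5) * runif(1, -0.15, 0.15)
    for (ch in 1:3) img[, , ch] <- skin[ch] + grad
    if (spec$distractors) {
      nblob <- sample(2:5, 1)
      for (i in seq_len(nblob)) {
        col <- runif(3, 0.2, 0.8)
        wblob <- soft_disc(X, Y, runif(1, 1, W), runif(1, 1, H),
                           runif(1, 0.1, 0.3) * min(H, W))
        for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - 0.6 * wblob) +
            0.6 * wblob * col[ch]
      }
    }
    tongue_col <- c(0.78, 0.46, 0.50) + runif(3, -0.04, 0.04)
    if (spec$distractors) {
      # lip-colored band just outside the tongue boundary, upper half:
      # similar hue to the tongue but darker/more saturated, as real lips
      # are (identical color with no luminance edge would make the boundary
      # unrecoverable even for an expert annotator)
      lip_col <- 0.6 * tongue_col + 0.4 * c(0.52, 0.22, 0.28) +
        runif(3, -0.03, 0.03)
      ring <- rr > Rb & rr <= Rb * runif(1, 1.15, 1.3) & V < 0
      for (ch in 1:3) img[, , ch][ring] <- lip_col[ch]
    }
    shade <- 0.8 + 0.2 * pmax(0, 1 - rr / pmax(Rb, 1e-9))
    inside <- mask == 1L
    for (ch in 1:3) img[, , ch][inside] <- (tongue_col[ch] * shade)[inside]
    if (spec$coating && runif(1) < 0.7) {
      coat_col <- c(0.87, 0.85, 0.78) + runif(3, -0.03, 0.03)
      wcoat <- pmax(0, 1 - (rr / pmax(Rb, 1e-9)) / runif(1, 0.55, 0.75))
      wcoat[!inside] <- 0
      wcoat <- wcoat * runif(1, 0.4, 0.85)
      for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - wcoat) + coat_col[ch] * wcoat
    }
    if (spec$n_spots > 0) {
      idx <- which(inside & rr < 0.7 * Rb)
      if (length(idx) > 0) {
        pts <- sample(idx, min(spec$n_spots, length(idx)))
        spot_col <- c(0.25, 0.12, 0.15)
        for (pt in pts) {
          wspot <- soft_disc(X, Y, X[pt], Y[pt], runif(1, 0.02, 0.05) * min(H, W))
          for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - wspot) +
              spot_col[ch] * wspot
        }
      }
    }
    if (spec$illumination) {
      br <- runif(1, 0.8, 1.2)
      temp <- runif(1, 0.95, 1.05)
      img[, , 1] <- img[, , 1] * br * temp
      img[, , 2] <- img[, , 2] * br
      img[, , 3] <- img[, , 3] * br / temp
    }
    img <- img + array(rnorm(H * W * 3, sd = 0.02), dim = dim(img))
    img <- pmin(pmax(img, 0), 1)
    list(image = img, mask = mask, spec = spec)
  })
}

#' Generate a synthetic dataset (and optionally write it to disk)
#'
#' Shape families are drawn uniformly; per-item seeds, scale fractions and
#' spot counts derive deterministically from `seed`. When `dir` is given,
#' writes `images/*.png`, `masks/*.png` and `manifest.csv` (columns: id,
#' image_path, mask_path, shape_family, seed).
#'
#' @param n number of scenes (>= 1).
#' @param size pixel size passed to [scene_spec()].
#' @param seed master seed.
#' @param dir optional output directory.
#' @return List of class `SegmentationBatch` with `images`, `masks`,
#'   `specs` and `manifest`.
#' @export
make_dataset <- function(n, size = 64L, seed = 0L, dir = NULL) {
  if (n < 1) stop("make_dataset: n must be >= 1")
  meta <- with_local_seed(seed, {
    list(family = sample(TONGUE_SHAPES, n, replace = TRUE),
         frac = runif(n, 0.08, 0.35),
         spots = sample(0:3, n, replace = TRUE, prob = c(0.55, 0.2, 0.15, 0.1)),
         item_seed = sample.int(10000000L, n))
  })
  images <- vector("list", n)
  masks <- vector("list", n)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- scene_spec(meta$item_seed[i], size = size,
                     tongue_shape = meta$family[i],
                     scale_fraction = meta$frac[i], n_spots = meta$spots[i])
    sc <- generate_scene(sp)
    images[[i]] <- sc$image
    masks[[i]] <- sc$mask
    specs[[i]] <- sp
  }
  manifest <- data.frame(id = seq_len(n),
                         image_path = sprintf("images/img_%04d.png", seq_len(n)),
                         mask_path = sprintf("masks/mask_%04d.png", seq_len(n)),
                         shape_family = meta$family,
                         seed = meta$item_seed,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
    if (!ok) stop("make_dataset: cannot create output directory ", dir)
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_image(file.path(dir, manifest$image_path[i]), images[[i]])
      write_mask(file.path(dir, manifest$mask_path[i]), masks[[i]])
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(images = images, masks = masks, specs = specs,
                 manifest = manifest),
            class = "SegmentationBatch")
}

#' Seeded train/test split
#'
#' Shuffles ids with the given seed and splits at `round(n * ratio)`
#' (round-half-up). The two id sets are disjoint and exhaustive.
#'
#' @param manifest a manifest data frame (or an integer count of items).
#' @param ratio train fraction in (0, 1); default 0.8 for an 8:2 split.
#' @param seed RNG seed.
#' @return List with integer vectors `train` and `test`.
#' @export
split_dataset <- function(manifest, ratio = 0.8, seed = 0L) {
  n <- if (is.data.frame(manifest)) nrow(manifest) else as.integer(manifest)
  if (n < 2) stop("split_dataset: need at least 2 items")
  if (ratio <= 0 || ratio >= 1) stop("split_dataset: ratio must be in (0, 1)")
  ids <- with_local_seed(seed, sample.int(n))
  ntrain <- floor(n * ratio + 0.5)   # round-half-up
  ntrain <- max(1L, min(n - 1L, ntrain))
  list(train = sort(ids[seq_len(ntrain)]), test = sort(ids[-seq_len(ntrain)]))
}
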