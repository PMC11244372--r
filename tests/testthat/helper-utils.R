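# Shared fixtures and oracles for the test suite.

# Internal layers exercised directly by the unit tests.
layer_conv2d <- tongueseg:::layer_conv2d
layer_convt2 <- tongueseg:::layer_convt2
layer_bn <- tongueseg:::layer_bn
layer_gelu <- tongueseg:::layer_gelu
layer_droppath <- tongueseg:::layer_droppath
walk_modules <- tongueseg:::walk_modules
TONGUE_SHAPES <- tongueseg:::TONGUE_SHAPES

# Central-difference numeric gradient of a scalar function of a flat vector.
numeric_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Small encoder/decoder configurations that keep unit tests fast while
# exercising every code path (four stages, S4 on, all branch kernels).
tiny_enc_cfg <- function(use_s4 = TRUE, drop_path = 0) {
  encoder_config(channels = c(8L, 12L, 16L, 24L), depths = c(1L, 1L, 1L, 1L),
                 expansion_ratios = c(2L, 2L, 2L, 2L), use_s4 = use_s4,
                 state_dim = 4L, drop_path_rate = drop_path)
}

tiny_model <- function(seed = 1, use_s4 = TRUE) {
  set.seed(seed)
  cfg <- tiny_enc_cfg(use_s4 = use_s4)
  seg_model(cfg, decoder_config(skip_channels = cfg$channels,
                                head_channels = 6L))
}

# Random stable discrete SSM (continuous eigenvalues in the left half plane).
random_stable_dssm <- function(N, delta = NULL) {
  A <- matrix(rnorm(N * N, sd = 0.5), N, N)
  A <- A - (max(Re(eigen(A, only.values = TRUE)$values)) + 0.5) * diag(N)
  if (is.null(delta)) delta <- runif(1, 0.01, 0.5)
  discretize(continuous_ssm(A, rnorm(N), rnorm(N)), delta)
}

# O(L^2) triangular-sum causal convolution oracle.
causal_conv_oracle <- function(u, k) {
  L <- length(u)
  y <- numeric(L)
  for (t in seq_len(L))
    for (i in seq_len(t))
      y[t] <- y[t] + k[i] * u[t - i + 1]
  y
}

# Nested-loop oracle for the 2D causal convolution (full-extent kernel).
conv2d_oracle <- function(x, K) {
  H <- nrow(x); W <- ncol(x)
  y <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    for (a in seq_len(i)) for (b in seq_len(j))
      y[i, j] <- y[i, j] + K[a, b] * x[i - a + 1, j - b + 1]
  y
}

# Per-pixel double-loop confusion oracle.
confusion_oracle <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j]; t <- truth[i, j]
    if (p == 1 && t == 1) tp <- tp + 1L
    else if (p == 0 && t == 0) tn <- tn + 1L
    else if (p == 1 && t == 0) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# Brute-force signed distance oracle (same boundary definition as the
# implementation: foreground pixels with a background 4-neighbor).
signed_distance_oracle <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bnd <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] != 1) next
    nb <- c(if (i > 1) mask[i - 1, j] else 1L,
            if (i < H) mask[i + 1, j] else 1L,
            if (j > 1) mask[i, j - 1] else 1L,
            if (j < W) mask[i, j + 1] else 1L)
    if (any(nb == 0)) bnd <- rbind(bnd, c(i, j))
  }
  phi <- matrix(0, H, W)
  if (is.null(bnd)) return(phi)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    d <- sqrt(min((i - bnd[, 1])^2 + (j - bnd[, 2])^2))
    phi[i, j] <- if (mask[i, j] == 1) -d else d
  }
  phi
}

batch1 <- function(img) array(img, dim = c(dim(img), 1L))
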