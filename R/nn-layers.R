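# Primitive layers. Tensors are numeric arrays with dim = c(H, W, C, N).

layer_conv2d <- function(cin, cout, kh, kw = kh, stride = 1L,
                         padh = (kh - 1L) %/% 2L, padw = (kw - 1L) %/% 2L,
                         groups = 1L, bias = TRUE) {
  m <- new_module(sprintf("conv%dx%d", kh, kw))
  fan_in <- kh * kw * cin / groups
  m$params$w <- array(rnorm(kh * kw * (cin / groups) * cout,
                            sd = sqrt(2 / fan_in)),
                      dim = c(kh, kw, cin / groups, cout))
  if (bias) m$params$b <- numeric(cout)
  m$meta <- list(stride = as.integer(stride), padh = as.integer(padh),
                 padw = as.integer(padw), groups = as.integer(groups),
                 bias = bias, cin = cin, cout = cout)
  m$forward <- function(x) {
    m$cache_x <- x
    cpp_conv2d_fwd(x, m$params$w,
                   if (m$meta$bias) m$params$b else NULL,
                   m$meta$stride, m$meta$padh, m$meta$padw, m$meta$groups)
  }
  m$backward <- function(g) {
    r <- cpp_conv2d_bwd(m$cache_x, m$params$w, g, m$meta$stride, m$meta$padh,
                        m$meta$padw, m$meta$groups, m$meta$bias)
    accum_grad(m, "w", r$gw)
    if (m$meta$bias) accum_grad(m, "b", r$gb)
    r$gx
  }
  m
}

layer_convt2 <- function(cin, cout, bias = TRUE) {
  m <- new_module("convT2x2")
  m$params$w <- array(rnorm(4 * cin * cout, sd = sqrt(2 / (4 * cin))),
                      dim = c(2, 2, cin, cout))
  if (bias) m$params$b <- numeric(cout)
  m$meta <- list(bias = bias)
  m$forward <- function(x) {
    m$cache_x <- x
    cpp_convt2_fwd(x, m$params$w, if (m$meta$bias) m$params$b else NULL)
  }
  m$backward <- function(g) {
    r <- cpp_convt2_bwd(m$cache_x, m$params$w, g, m$meta$bias)
    accum_grad(m, "w", r$gw)
    if (m$meta$bias) accum_grad(m, "b", r$gb)
    r$gx
  }
  m
}

layer_bn <- function(C, eps = 1e-5, momentum = 0.1) {
  m <- new_module("bn")
  m$params$gamma <- rep(1, C)
  m$params$beta <- numeric(C)
  m$buffers$running_mean <- numeric(C)
  m$buffers$running_var <- rep(1, C)
  m$meta <- list(C = C, eps = eps, momentum = momentum)
  m$forward <- function(x) {
    r <- cpp_bn_fwd(x, m$params$gamma, m$params$beta,
                    m$buffers$running_mean, m$buffers$running_var,
                    m$meta$eps, m$training)
    if (m$training) {
      m$buffers$running_mean <- (1 - m$meta$momentum) * m$buffers$running_mean +
        m$meta$momentum * r$mu
      m$buffers$running_var <- (1 - m$meta$momentum) * m$buffers$running_var +
        m$meta$momentum * r$va
    }
    m$cache <- list(xhat = r$xhat, invstd = r$invstd, train = m$training)
    r$y
  }
  m$backward <- function(g) {
    cc <- m$cache
    r <- cpp_bn_bwd(cc$xhat, g, m$params$gamma, cc$invstd, cc$train)
    accum_grad(m, "gamma", r$ggamma)
    accum_grad(m, "beta", r$gbeta)
    r$gx
  }
  m
}

layer_gelu <- function() {
  m <- new_module("gelu")
  m$forward <- function(x) {
    m$cache_x <- x
    cpp_gelu_fwd(x)
  }
  m$backward <- function(g) {
    cpp_gelu_bwd(m$cache_x, g)
  }
  m
}

layer_droppath <- function(rate = 0) {
  m <- new_module("droppath")
  m$meta <- list(rate = rate)
  m$forward <- function(x) {
    d <- dim(x)
    if (m$training && m$meta$rate > 0) {
      keep <- (runif(d[4]) >= m$meta$rate) / (1 - m$meta$rate)
      m$cache_keep <- keep
      x * bcast_n(keep, d[1] * d[2] * d[3])
    } else {
      m$cache_keep <- NULL
      x
    }
  }
  m$backward <- function(g) {
    if (is.null(m$cache_keep)) return(g)
    d <- dim(g)
    g * bcast_n(m$cache_keep, d[1] * d[2] * d[3])
  }
  m
}

# ---------------------------------------------------------------------------
# Depthwise 2D S4 layer. One pair of independent axis SSMs per feature
# channel; the HiPPO (A, B) pair is fixed, while the per-channel contraction
# weights and log step sizes are learned. Kernels are re-materialized from
# the continuous parameters at the incoming (H, W), which is what makes the
# layer resolution-flexible.
# ---------------------------------------------------------------------------

layer_s4_2d <- function(C, state_dim = 16L, delta_range = c(0.001, 0.1),
                        bidirectional = FALSE) {
  m <- new_module("s4_2d")
  hip <- init_hippo(state_dim)
  m$buffers$A <- hip$A
  m$buffers$B <- hip$B
  m$params$contr <- matrix(rnorm(state_dim * C, sd = 1 / state_dim),
                           state_dim, C)
  lo <- log(delta_range[1]); hi <- log(delta_range[2])
  m$params$logdx <- runif(C, lo, hi)
  m$params$logdy <- runif(C, lo, hi)
  m$meta <- list(C = C, Ns = as.integer(state_dim),
                 bidirectional = bidirectional)
  m$materialize <- function(H, W) {
    dx <- exp(m$params$logdx)
    dy <- exp(m$params$logdy)
    stx <- cpp_s4_states(m$buffers$A, m$buffers$B, dx, H)
    sty <- cpp_s4_states(m$buffers$A, m$buffers$B, dy, W)
    C <- m$meta$C
    Ns <- m$meta$Ns
    K <- array(0, dim = c(H, W, C))
    for (c in seq_len(C)) {
      Sx <- matrix(stx$S[, , c], Ns, H)
      Sy <- matrix(sty$S[, , c], Ns, W)
      K[, , c] <- crossprod(Sx, m$params$contr[, c] * Sy)
    }
    list(K = K, stx = stx, sty = sty, dx = dx, dy = dy)
  }
  m$forward <- function(x) {
    d <- dim(x)
    if (d[3] != m$meta$C)
      stop(sprintf("s4_2d layer: expected %d channels, got %d", m$meta$C, d[3]))
    mat <- m$materialize(d[1], d[2])
    m$cache <- c(mat, list(x = x))
    if (m$meta$bidirectional) {
      Kb <- bidir_kernel(mat$K)
      m$cache$Kb <- Kb
      y <- cpp_fftconv2d_fwd(x, Kb, d[1] - 1L, d[2] - 1L)
    } else {
      y <- cpp_fftconv2d_fwd(x, mat$K)
    }
    if (!all(is.finite(y)))
      stop("s4_2d layer: non-finite activations")
    y
  }
  m$backward <- function(g) {
    cc <- m$cache
    d <- dim(cc$x)
    H <- d[1]; W <- d[2]; C <- m$meta$C
    if (m$meta$bidirectional) {
      r <- cpp_fftconv2d_bwd(cc$x, cc$Kb, g, H - 1L, W - 1L)
      gK <- bidir_kernel_bwd(r$gK, H, W)
    } else {
      r <- cpp_fftconv2d_bwd(cc$x, cc$K, g)
      gK <- r$gK
    }
    gcontr <- matrix(0, m$meta$Ns, C)
    glogdx <- numeric(C)
    glogdy <- numeric(C)
    Ns <- m$meta$Ns
    for (c in seq_len(C)) {
      Sx <- matrix(cc$stx$S[, , c], Ns, H)
      Sy <- matrix(cc$sty$S[, , c], Ns, W)
      Gc <- matrix(gK[, , c], H, W)
      M <- Sx %*% Gc                          # Ns x W
      gcontr[, c] <- rowSums(M * Sy)
      w <- m$params$contr[, c]
      dSx <- matrix(cc$stx$dS[, , c], Ns, H)
      dSy <- matrix(cc$sty$dS[, , c], Ns, W)
      glogdx[c] <- sum(w * rowSums((dSx %*% Gc) * Sy)) * cc$dx[c]
      glogdy[c] <- sum(w * rowSums(M * dSy)) * cc$dy[c]
    }
    accum_grad(m, "contr", gcontr)
    accum_grad(m, "logdx", glogdx)
    accum_grad(m, "logdy", glogdy)
    r$gx
  }
  m
}

# forward + mirrored kernel along each axis, anchored at (H-1, W-1) in a
# (2H-1) x (2W-1) extent, i.e. the product of two bidirectional 1D kernels.
bidir_kernel <- function(K) {
  d <- dim(K)
  H <- d[1]; W <- d[2]; C <- d[3]
  Kb <- array(0, dim = c(2 * H - 1, 2 * W - 1, C))
  for (c in seq_len(C)) {
    k <- K[, , c, drop = TRUE]
    Kb[H:(2 * H - 1), W:(2 * W - 1), c] <- Kb[H:(2 * H - 1), W:(2 * W - 1), c] + k
    Kb[H:1, W:(2 * W - 1), c] <- Kb[H:1, W:(2 * W - 1), c] + k
    Kb[H:(2 * H - 1), W:1, c] <- Kb[H:(2 * H - 1), W:1, c] + k
    Kb[H:1, W:1, c] <- Kb[H:1, W:1, c] + k
  }
  Kb
}

bidir_kernel_bwd <- function(gKb, H, W) {
  C <- dim(gKb)[3]
  gK <- array(0, dim = c(H, W, C))
  for (c in seq_len(C)) {
    g <- gKb[, , c, drop = TRUE]
    gK[, , c] <- g[H:(2 * H - 1), W:(2 * W - 1)] + g[H:1, W:(2 * W - 1)] +
      g[H:(2 * H - 1), W:1] + g[H:1, W:1]
  }
  gK
}
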