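#' @useDynLib tongueseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft rnorm runif
NULL

next_pow2 <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

#' Continuous-time state-space model
#'
#' Bundles the matrices of the linear system x'(t) = A x(t) + B u(t),
#' y(t) = C x(t) + D u(t) with state dimension `N`.
#'
#' @param A N x N state matrix.
#' @param B length-N input vector.
#' @param C length-N output (read-out) vector.
#' @param D feedthrough scalar, conventionally 0.
#' @return An object of class `ContinuousSSM`.
#' @export
continuous_ssm <- function(A, B, C = NULL, D = 0) {
  A <- as.matrix(A)
  N <- nrow(A)
  if (ncol(A) != N) stop("A must be square")
  B <- as.numeric(B)
  if (length(B) != N) stop("B must have length nrow(A)")
  if (is.null(C)) C <- rep(1, N)
  C <- as.numeric(C)
  if (length(C) != N) stop("C must have length nrow(A)")
  structure(list(A = A, B = B, C = C, D = as.numeric(D)[1], N = N),
            class = "ContinuousSSM")
}

#' @export
print.ContinuousSSM <- function(x, ...) {
  cat(sprintf("<ContinuousSSM N=%d, D=%g>\n", x$N, x$D))
  invisible(x)
}

#' HiPPO (LegS) initialization of a state-space model
#'
#' Builds the dense HiPPO state matrix whose entries have magnitude
#' sqrt((2n+1)(2k+1)) below the diagonal, n+1 on the diagonal and 0 above
#' (0-based indices), with input vector B\[n\] = sqrt(2n+1). The matrix is
#' stored negated (`A = -A_magnitudes`) so that the continuous system is
#' stable, following the HiPPO/S4 convention; callers that only care about
#' magnitudes can take `abs()`.
#'
#' @param N state dimension, positive integer.
#' @param C optional read-out vector; defaults to all ones.
#' @return A `ContinuousSSM`.
#' @export
init_hippo <- function(N, C = NULL) {
  if (length(N) != 1 || is.na(N) || N < 1 || N != round(N))
    stop("N must be a positive integer")
  N <- as.integer(N)
  n <- 0:(N - 1)
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (k in seq_len(i)) {
      A[i, k] <- if (i == k) i else sqrt((2 * (i - 1) + 1) * (2 * (k - 1) + 1))
    }
  }
  B <- sqrt(2 * n + 1)
  continuous_ssm(-A, B, C)
}

#' Bilinear (Tustin) discretization of a continuous SSM
#'
#' Computes Abar = (I - d/2 A)^-1 (I + d/2 A), Bbar = (I - d/2 A)^-1 (d B)
#' and Cbar = C for step size `delta`. The step-size factor on Bbar follows
#' the S4-family convention (it makes the d -> 0 limit degenerate to the
#' identity system with vanishing input gain).
#'
#' @param ssm a `ContinuousSSM`.
#' @param delta positive step size.
#' @param method discretization method; only `"bilinear"` is implemented
#'   (kept as an enum so that zero-order hold can be added without an API
#'   change).
#' @return An object of class `DiscreteSSM`.
#' @export
discretize <- function(ssm, delta, method = c("bilinear")) {
  method <- match.arg(method)
  stopifnot(inherits(ssm, "ContinuousSSM"))
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0)
    stop("delta must be a positive scalar")
  M <- diag(ssm$N) - (delta / 2) * ssm$A
  rc <- rcond(M)
  if (!is.finite(rc) || rc < 1e-14)
    stop(sprintf("discretize: (I - delta/2 A) is numerically singular (rcond=%.3g, delta=%.3g)",
                 rc, delta))
  Minv <- solve(M)
  structure(list(
    Abar = Minv %*% (diag(ssm$N) + (delta / 2) * ssm$A),
    Bbar = as.numeric(Minv %*% (delta * ssm$B)),
    Cbar = ssm$C,
    delta = delta,
    N = ssm$N
  ), class = "DiscreteSSM")
}

#' @export
print.DiscreteSSM <- function(x, ...) {
  cat(sprintf("<DiscreteSSM N=%d, delta=%g>\n", x$N, x$delta))
  invisible(x)
}

#' Stepwise recurrence evaluation of a discrete SSM
#'
#' Runs x_k = Abar x_{k-1} + Bbar u_k, y_k = Cbar x_k from the zero initial
#' state. This is the brute-force oracle for the convolutional evaluation
#' path.
#'
#' @param dssm a `DiscreteSSM`.
#' @param u numeric input sequence.
#' @return Numeric output sequence of the same length as `u`.
#' @export
ssm_recurrence <- function(dssm, u) {
  stopifnot(inherits(dssm, "DiscreteSSM"))
  u <- as.numeric(u)
  L <- length(u)
  if (L == 0) return(numeric(0))
  y <- numeric(L)
  x <- numeric(dssm$N)
  for (k in seq_len(L)) {
    x <- as.numeric(dssm$Abar %*% x) + dssm$Bbar * u[k]
    y[k] <- sum(dssm$Cbar * x)
  }
  y
}

#' Materialize the S4 convolution kernel
#'
#' Computes the length-L impulse response (Cbar Bbar, Cbar Abar Bbar, ...,
#' Cbar Abar^(L-1) Bbar) by iterated state propagation (no explicit matrix
#' powers).
#'
#' @param dssm a `DiscreteSSM`.
#' @param L kernel length (= signal length), >= 1.
#' @return An object of class `Kernel1D` with fields `values` and `L`.
#' @export
ssm_kernel <- function(dssm, L) {
  stopifnot(inherits(dssm, "DiscreteSSM"))
  if (L < 1) stop("L must be >= 1")
  L <- as.integer(L)
  values <- numeric(L)
  s <- dssm$Bbar
  for (i in seq_len(L)) {
    values[i] <- sum(dssm$Cbar * s)
    if (i < L) s <- as.numeric(dssm$Abar %*% s)
  }
  kernel1d(values)
}

#' @rdname ssm_kernel
#' @param values numeric kernel values.
#' @export
kernel1d <- function(values) {
  structure(list(values = as.numeric(values), L = length(values)),
            class = "Kernel1D")
}

#' Causal 1D convolution via zero-padded FFT
#'
#' y\[k\] = sum_i kernel\[i\] * u\[k - i\] (lower-triangular convolution); the
#' kernel length must equal the signal length.
#'
#' @param u numeric input sequence.
#' @param k a `Kernel1D` (or plain numeric vector) of the same length.
#' @return Numeric sequence of length `length(u)`.
#' @export
causal_conv <- function(u, k) {
  kv <- if (inherits(k, "Kernel1D")) k$values else as.numeric(k)
  u <- as.numeric(u)
  L <- length(u)
  if (length(kv) != L) stop("causal_conv: kernel length must match signal length")
  if (L == 0) return(numeric(0))
  P <- next_pow2(2L * L - 1L)
  fu <- fft(c(u, numeric(P - L)))
  fk <- fft(c(kv, numeric(P - L)))
  Re(fft(fu * fk, inverse = TRUE) / P)[seq_len(L)]
}

#' Diagonal-plus-low-rank decomposition of the HiPPO matrix
#'
#' Splits the (stabilized) HiPPO matrix as A = V^-1 Lambda V - P Q^T where
#' the normal part A + P P^T is diagonalized with a well-conditioned
#' (unitary, up to scaling) eigenbasis. For HiPPO the rank is 1 with
#' P = Q = sqrt(n + 1/2).
#'
#' @param ssm a `ContinuousSSM` produced by [init_hippo()].
#' @param tol relative Frobenius tolerance for the reconstruction check.
#' @return An object of class `DPLRParams` with fields `Lambda` (complex
#'   length-N), `P`, `Q` (N x 1), `V` (N x N complex, the change of basis
#'   such that the normal part equals `solve(V) %*% diag(Lambda) %*% V`) and
#'   `r = 1`.
#' @export
dplr_decompose <- function(ssm, tol = 1e-6) {
  stopifnot(inherits(ssm, "ContinuousSSM"))
  N <- ssm$N
  n <- 0:(N - 1)
  p <- sqrt(n + 0.5)
  An <- ssm$A + outer(p, p)              # normal part: -1/2 I + skew
  eg <- eigen(An)
  V <- solve(eg$vectors)                 # so that An = V^-1 Lambda V
  out <- structure(list(Lambda = eg$values, P = matrix(p, ncol = 1),
                        Q = matrix(p, ncol = 1), V = V, r = 1L, N = N),
                   class = "DPLRParams")
  A_rec <- dplr_reconstruct(out)
  res <- norm(A_rec - ssm$A, "F") / max(norm(ssm$A, "F"), .Machine$double.eps)
  if (!is.finite(res) || res > tol)
    stop(sprintf("dplr_decompose: reconstruction residual %.3g exceeds %.3g", res, tol))
  out
}

#' @rdname dplr_decompose
#' @param dplr a `DPLRParams` object.
#' @export
dplr_reconstruct <- function(dplr) {
  stopifnot(inherits(dplr, "DPLRParams"))
  A <- solve(dplr$V) %*% diag(dplr$Lambda, dplr$N) %*% dplr$V -
    dplr$P %*% t(dplr$Q)
  Re(A)
}

#' S4 kernel via the DPLR / Cauchy generating-function path
#'
#' Evaluates the truncated kernel generating function at the L-th roots of
#' unity using the Woodbury identity on the diagonal-plus-low-rank resolvent
#' (Cauchy dot products), then recovers the kernel by inverse FFT. Validated
#' against the naive path of [ssm_kernel()].
#'
#' @param ssm a `ContinuousSSM` (HiPPO-structured).
#' @param delta step size.
#' @param L kernel length.
#' @return A `Kernel1D`.
#' @export
ssm_kernel_dplr <- function(ssm, delta, L) {
  stopifnot(inherits(ssm, "ContinuousSSM"))
  dp <- dplr_decompose(ssm)
  ds <- discretize(ssm, delta)
  # truncation correction: Ctilde = C (I - Abar^L)
  AL <- diag(ssm$N)
  Apow <- ds$Abar
  e <- L
  while (e > 0) {
    if (e %% 2 == 1) AL <- AL %*% Apow
    Apow <- Apow %*% Apow
    e <- e %/% 2
  }
  Ct <- as.numeric(ssm$C %*% (diag(ssm$N) - AL))
  Vi <- solve(dp$V)
  cc <- as.complex(Ct %*% Vi)                    # row vector in eigenbasis
  bb <- as.complex(dp$V %*% ssm$B)
  pp <- as.complex(dp$V %*% dp$P)
  qq <- as.complex(t(Vi) %*% dp$Q)               # (Q^T V^-1)^T
  z <- exp(-2i * pi * (0:(L - 1)) / L)
  khat <- complex(length.out = L)
  for (k in seq_len(L)) {
    if (abs(1 + z[k]) < 1e-9) {
      # z = -1 (even L): the Cauchy form is 0/0; fall back to the dense
      # resolvent, which is regular there.
      khat[k] <- sum(Ct * solve(diag(ssm$N) - z[k] * ds$Abar, ds$Bbar))
      next
    }
    g <- (2 / delta) * (1 - z[k]) / (1 + z[k])
    d <- 1 / (g - dp$Lambda)                     # diagonal resolvent
    cb <- sum(cc * d * bb)
    cp <- sum(cc * d * pp)
    qb <- sum(qq * d * bb)
    qp <- sum(qq * d * pp)
    khat[k] <- (2 / (1 + z[k])) * (cb - cp * qb / (1 + qp))
  }
  vals <- Re(fft(khat, inverse = TRUE) / L)
  imag_norm <- max(abs(Im(fft(khat, inverse = TRUE) / L)))
  if (imag_norm > 1e-6 * max(1, max(abs(vals))))
    warning(sprintf("ssm_kernel_dplr: imaginary residue %.3g", imag_norm))
  kernel1d(vals)
}
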