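# Minimal static-graph neural-network framework: every layer is an
# environment holding parameters, gradient accumulators and forward/backward
# closures. There is no autodiff; composite blocks chain backward passes by
# hand, mirroring how the forward pass was composed.

new_module <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$params <- list()
  m$grads <- list()
  m$buffers <- list()
  m$children <- list()
  m$training <- FALSE
  class(m) <- "ts_module"
  m
}

#' @export
print.ts_module <- function(x, ...) {
  cat(sprintf("<ts_module %s: %d parameters, %d children>\n",
              x$type, n_params(x), length(x$children)))
  invisible(x)
}

walk_modules <- function(m, fn, prefix = "") {
  fn(m, prefix)
  for (nm in names(m$children)) {
    walk_modules(m$children[[nm]],
                 fn,
                 if (nzchar(prefix)) paste0(prefix, ".", nm) else nm)
  }
  invisible(NULL)
}

#' Number of trainable parameters in a module tree
#' @param m a module.
#' @return Integer count.
#' @export
n_params <- function(m) {
  total <- 0L
  walk_modules(m, function(mod, path) {
    for (p in mod$params) total <<- total + length(p)
  })
  total
}

#' Fully qualified parameter names of a module tree
#'
#' Names have the form `path.to.module.param`; used by the ablation audits
#' to diff architectures parameter-block by parameter-block.
#' @param m a module.
#' @return Sorted character vector.
#' @export
param_names <- function(m) {
  out <- character(0)
  walk_modules(m, function(mod, path) {
    for (nm in names(mod$params)) {
      out <<- c(out, if (nzchar(path)) paste0(path, ".", nm) else nm)
    }
  })
  sort(out)
}

#' Toggle training mode recursively (affects batch norm and drop-path)
#' @param m a module.
#' @param flag logical.
#' @export
set_training <- function(m, flag) {
  walk_modules(m, function(mod, path) mod$training <- flag)
  invisible(m)
}

#' Reset all gradient accumulators to zero
#' @param m a module.
#' @export
zero_grads <- function(m) {
  # lazy reset: the first accum_grad() after this assigns instead of adding
  walk_modules(m, function(mod, path) mod$grads <- list())
  invisible(m)
}

accum_grad <- function(m, name, g) {
  if (is.null(m$grads[[name]])) {
    m$grads[[name]] <- g
  } else {
    m$grads[[name]] <- m$grads[[name]] + g
  }
  invisible(NULL)
}

#' Extract / restore all parameters and buffers as a plain list
#'
#' The state dict is an ordinary named list of numeric arrays, suitable for
#' `saveRDS()` checkpointing.
#' @param m a module.
#' @return Named list with `params` and `buffers` entries keyed by path.
#' @export
state_dict <- function(m) {
  params <- list()
  buffers <- list()
  walk_modules(m, function(mod, path) {
    for (nm in names(mod$params))
      params[[if (nzchar(path)) paste0(path, ".", nm) else nm]] <<- mod$params[[nm]]
    for (nm in names(mod$buffers))
      buffers[[if (nzchar(path)) paste0(path, ".", nm) else nm]] <<- mod$buffers[[nm]]
  })
  list(params = params, buffers = buffers)
}

#' @rdname state_dict
#' @param sd a state dict produced by [state_dict()].
#' @export
load_state_dict <- function(m, sd) {
  walk_modules(m, function(mod, path) {
    for (nm in names(mod$params)) {
      key <- if (nzchar(path)) paste0(path, ".", nm) else nm
      if (is.null(sd$params[[key]]))
        stop("load_state_dict: missing parameter ", key)
      if (!identical(dim(mod$params[[nm]]), dim(sd$params[[key]])) &&
          length(mod$params[[nm]]) != length(sd$params[[key]]))
        stop("load_state_dict: shape mismatch for ", key)
      mod$params[[nm]] <- sd$params[[key]]
    }
    for (nm in names(mod$buffers)) {
      key <- if (nzchar(path)) paste0(path, ".", nm) else nm
      if (!is.null(sd$buffers[[key]])) mod$buffers[[nm]] <- sd$buffers[[key]]
    }
  })
  invisible(m)
}

# ---------------------------------------------------------------------------
# AdamW: decoupled weight decay; decay applies only to >=2-D weight tensors
# (matrices/filters), never to biases, norm affines or S4 step sizes.
# ---------------------------------------------------------------------------

#' AdamW optimizer over a module tree
#' @param model the module whose parameters are optimized.
#' @param lr learning rate.
#' @param betas first/second moment decay pair.
#' @param eps numerical floor.
#' @param weight_decay decoupled decay coefficient.
#' @return Optimizer state environment; advance it with [adamw_step()].
#' @export
adamw_new <- function(model, lr = 1e-4, betas = c(0.9, 0.999), eps = 1e-8,
                      weight_decay = 0.01) {
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr
  opt$b1 <- betas[1]
  opt$b2 <- betas[2]
  opt$eps <- eps
  opt$wd <- weight_decay
  opt$t <- 0L
  opt$m <- list()
  opt$v <- list()
  opt$model <- model
  opt
}

#' @rdname adamw_new
#' @param opt optimizer state from [adamw_new()].
#' @export
adamw_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  walk_modules(opt$model, function(mod, path) {
    for (nm in names(mod$params)) {
      key <- paste0(path, ".", nm)
      g <- mod$grads[[nm]]
      if (is.null(g)) next
      p <- mod$params[[nm]]
      m1 <- opt$m[[key]]
      v1 <- opt$v[[key]]
      if (is.null(m1)) { m1 <- g * 0; v1 <- g * 0 }
      m1 <- opt$b1 * m1 + (1 - opt$b1) * g
      v1 <- opt$b2 * v1 + (1 - opt$b2) * g * g
      opt$m[[key]] <- m1
      opt$v[[key]] <- v1
      upd <- (m1 / bc1) / (sqrt(v1 / bc2) + opt$eps)
      if (opt$wd > 0 && length(dim(p)) >= 2) upd <- upd + opt$wd * p
      mod$params[[nm]] <- p - opt$lr * upd
    }
  })
  invisible(opt)
}

# broadcast a per-channel vector over an (H,W,C,N) tensor layout
bcast_c <- function(v, hw, N) rep(rep(v, each = hw), N)
# broadcast a per-sample vector
bcast_n <- function(v, hwc) rep(v, each = hwc)
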