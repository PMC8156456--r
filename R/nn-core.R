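#' @useDynLib csagnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif
NULL

# ---------------------------------------------------------------------------
# Minimal neural-network layer framework.
#
# A module is an environment with class c("nn_<type>", "nn_module") holding
# `params` (named list of numeric arrays), `grads` (same shapes, accumulated
# by the backward pass), optional `buffers` (batch-norm running statistics)
# and `cache` (forward intermediates).  Feature maps are arrays with
# dim c(H, W, C, N).  All layers implement nn_forward() / nn_backward().
# ---------------------------------------------------------------------------

new_module <- function(type) {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e$grads <- list()
  e$buffers <- list()
  e$cache <- NULL
  e$children <- list()
  class(e) <- c(paste0("nn_", type), "nn_module")
  e
}

nn_forward <- function(m, x, training = FALSE) UseMethod("nn_forward")
nn_backward <- function(m, dy) UseMethod("nn_backward")

#' @keywords internal
as_nchw <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature map must be an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("feature map must have 2-4 dimensions")
  x
}

zeros_like <- function(p) {
  z <- array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
  if (is.null(dim(p))) z <- as.numeric(z)
  z
}

# Recursively walk a module tree, returning the module environments.
module_list <- function(m) {
  out <- list(m)
  for (ch in m$children) out <- c(out, module_list(ch))
  out
}

#' Count trainable parameters of a model
#'
#' Sums the lengths of every trainable parameter array (convolution kernels
#' and biases, batch-norm scale/shift, attention perceptron weights).
#' Batch-norm running statistics are buffers, not parameters.
#'
#' @param model a model built by [build_model()] or any `nn_module`.
#' @return integer scalar, the exact number of trainable scalars.
#' @export
count_parameters <- function(model) {
  tot <- 0
  for (m in module_list(model))
    for (p in m$params) tot <- tot + length(p)
  as.integer(tot)
}

zero_grads <- function(model) {
  for (m in module_list(model))
    for (nm in names(m$params)) m$grads[[nm]] <- zeros_like(m$params[[nm]])
  invisible(model)
}

# PyTorch-style SGD with momentum and (decoupled-into-gradient) weight decay:
#   v <- mom * v + g + wd * p ;  p <- p - lr * v
sgd_step <- function(model, lr, momentum = 0.9, weight_decay = 5e-4) {
  for (m in module_list(model)) {
    for (nm in names(m$params)) {
      g <- m$grads[[nm]] + weight_decay * m$params[[nm]]
      v <- m$buffers[[paste0("mom_", nm)]]
      if (is.null(v)) v <- zeros_like(g)
      v <- momentum * v + g
      m$buffers[[paste0("mom_", nm)]] <- v
      m$params[[nm]] <- m$params[[nm]] - lr * v
    }
  }
  invisible(model)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---------------------------------------------------------------------------
# Convolution block: conv (+ batch norm) (+ ReLU) as one fused module.
# ---------------------------------------------------------------------------

nn_conv <- function(cin, cout, k = 3L, pad = (k - 1L) %/% 2L,
                    bn = TRUE, act = c("relu", "none")) {
  act <- match.arg(act)
  m <- new_module("conv")
  m$k <- as.integer(k); m$pad <- as.integer(pad)
  m$cin <- as.integer(cin); m$cout <- as.integer(cout)
  m$bn <- bn; m$act <- act
  m$need_dx <- TRUE       # first-layer convs (image inputs) clear this
  sd <- sqrt(2 / (k * k * cin))                      # He initialisation
  m$params$W <- array(rnorm(k * k * cin * cout, sd = sd),
                      dim = c(k, k, cin, cout))
  m$params$b <- numeric(cout)
  if (bn) {
    m$params$gamma <- rep(1, cout)
    m$params$beta <- numeric(cout)
    m$buffers$run_mean <- numeric(cout)
    m$buffers$run_var <- rep(1, cout)
  }
  m
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' @export
nn_forward.nn_conv <- function(m, x, training = FALSE) {
  x <- as_nchw(x)
  y <- cpp_conv2d(x, m$params$W, m$params$b, m$pad)
  cache <- list(x = x)
  if (m$bn) {
    # statistics per channel over (H, W, N); work on the (HW, C*N) matrix
    # whose column (c, n) is channel c of sample n
    d <- dim(y)
    C <- d[3]; N <- d[4]
    ym <- matrix(y, ncol = C * N)
    if (training) {
      stat <- cpp_bn_stats(ym, C)
      mu <- stat$mean; va <- stat$var
      M <- nrow(ym) * N
      m$buffers$run_mean <- (1 - BN_MOMENTUM) * m$buffers$run_mean +
        BN_MOMENTUM * mu
      m$buffers$run_var <- (1 - BN_MOMENTUM) * m$buffers$run_var +
        BN_MOMENTUM * va * M / max(M - 1, 1)
    } else {
      mu <- m$buffers$run_mean
      va <- m$buffers$run_var
    }
    istd <- 1 / sqrt(va + BN_EPS)
    bn <- cpp_bn_forward(ym, mu, istd, m$params$gamma, m$params$beta, C)
    cache$xhat <- bn$xhat; cache$istd <- istd
    cache$bn_training <- training
    cache$ydim <- d
    y <- array(bn$y, dim = d)
  }
  if (m$act == "relu") {
    cache$mask <- y > 0
    y[!cache$mask] <- 0
  }
  m$cache <- cache
  y
}

#' @export
nn_backward.nn_conv <- function(m, dy) {
  cache <- m$cache
  dy <- as_nchw(dy)
  if (m$act == "relu") dy <- dy * cache$mask
  if (m$bn) {
    d <- cache$ydim
    C <- d[3]; N <- d[4]
    dym <- matrix(dy, ncol = C * N)
    bn <- cpp_bn_backward(dym, cache$xhat, m$params$gamma, cache$istd, C,
                          isTRUE(cache$bn_training))
    m$grads$gamma <- m$grads$gamma + bn$dgamma
    m$grads$beta <- m$grads$beta + bn$dbeta
    dy <- array(bn$dx, dim = d)
  }
  bk <- cpp_conv2d_backward(cache$x, m$params$W, dy, m$pad,
                            isTRUE(m$need_dx))
  m$grads$W <- m$grads$W + bk$dw
  m$grads$b <- m$grads$b + bk$db
  bk$dx
}

# ---------------------------------------------------------------------------
# Stateless spatial ops (wrapped as plain functions; caches kept by caller).
# ---------------------------------------------------------------------------

maxpool2 <- function(x) cpp_maxpool2(as_nchw(x))
maxpool2_backward <- function(dy, idx, H, W) cpp_maxpool2_backward(dy, idx, H, W)
avgpool2 <- function(x) cpp_avgpool2(as_nchw(x))
avgpool2_backward <- function(dy, H, W) cpp_avgpool2_backward(dy, H, W)

bilinear_resize <- function(x, out_h, out_w)
  cpp_bilinear_resize(as_nchw(x), as.integer(out_h), as.integer(out_w))
bilinear_resize_backward <- function(dy, in_h, in_w)
  cpp_bilinear_resize_backward(as_nchw(dy), as.integer(in_h), as.integer(in_w))

#' Box-window sum with exact border clipping
#'
#' Sum of `x` over the square window of radius `r` centred at each pixel,
#' windows clipped at the image border.  Computed with integral images in
#' O(N) per channel.
#'
#' @param x array with dim c(H, W, ...); trailing dimensions are treated as
#'   independent slabs.
#' @param r window radius in pixels.
#' @return array of the same shape as `x`.
#' @export
boxsum <- function(x, r) {
  if (is.null(dim(x))) stop("x must be an array")
  cpp_boxsum(x, as.integer(r))
}

# Per-pixel clipped window pixel counts (2D matrix H x W).
box_counts <- function(H, W, r) {
  ones <- array(1, dim = c(H, W, 1L, 1L))
  n <- cpp_boxsum(ones, as.integer(r))
  matrix(n, H, W)
}

# Broadcast an (H, W, 1, N) map across C channels.
bcast_ch <- function(a, C) {
  if (dim(a)[3] == C) return(a)
  a[, , rep(1L, C), , drop = FALSE]
}

# Channel-wise softmax of an (H, W, C, N) logit array.
softmax_ch <- function(x) {
  d <- dim(x); C <- d[3]
  mx <- x[, , 1, , drop = FALSE]
  if (C > 1) for (cc in 2:C) mx <- pmax(mx, x[, , cc, , drop = FALSE])
  e <- array(0, d)
  s <- array(0, dim = c(d[1], d[2], 1L, d[4]))
  for (cc in 1:C) {
    e[, , cc, ] <- exp(x[, , cc, , drop = FALSE] - mx)
    s <- s + e[, , cc, , drop = FALSE]
  }
  for (cc in 1:C) e[, , cc, ] <- e[, , cc, , drop = FALSE] / s
  e
}
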