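# Channel and spatial attention (CBAM-style) and the fusion branch that
# turns a pair of feature maps into a single-channel attention map for the
# attention-guided filter.
#
# Channel attention: global average and max pooling per channel, a shared
# two-layer perceptron with reduction ratio rho (hidden ReLU), summed and
# squashed by a logistic sigmoid into per-channel gates in (0,1).
# Spatial attention: channel-wise average and max maps, concatenated and
# convolved (k x k, 2 -> 1 channels) into per-pixel gates in (0,1).

attn_hidden_width <- function(C, rho) max(as.integer(C %/% rho), 1L)

# --- channel attention module ----------------------------------------------

nn_channel_attn <- function(C, rho = 16L) {
  m <- new_module("channel_attn")
  m$C <- as.integer(C); m$rho <- as.integer(rho)
  h <- attn_hidden_width(C, rho)
  m$h <- h
  sd1 <- sqrt(2 / C)
  m$params$W1 <- matrix(rnorm(h * C, sd = sd1), h, C)
  m$params$b1 <- numeric(h)
  m$params$W2 <- matrix(rnorm(C * h, sd = sqrt(2 / h)), C, h)
  m$params$b2 <- numeric(C)
  m
}

#' @export
nn_forward.nn_channel_attn <- function(m, x, training = FALSE) {
  x <- as_nchw(x)
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xm <- array(x, dim = c(H * W, C, N))
  avg <- matrix(0, C, N); mx <- matrix(0, C, N)
  amax <- matrix(0L, C, N)
  for (n in seq_len(N)) {
    sl <- matrix(xm[, , n], nrow = H * W, ncol = C)
    avg[, n] <- colMeans(sl)
    for (cc in seq_len(C)) {
      i <- which.max(sl[, cc])
      amax[cc, n] <- i
      mx[cc, n] <- sl[i, cc]
    }
  }
  mlp <- function(v) {
    pre <- m$params$W1 %*% v + m$params$b1
    hid <- pmax(pre, 0)
    list(pre = pre, hid = hid, out = m$params$W2 %*% hid + m$params$b2)
  }
  pa <- mlp(avg); pm <- mlp(mx)
  logits <- pa$out + pm$out
  gate <- sigmoid(logits)                              # C x N
  y <- x * array(rep(gate, each = H * W), dim = d)
  m$cache <- list(x = x, avg = avg, mx = mx, amax = amax, pa = pa, pm = pm,
                  logits = logits, gate = gate)
  y
}

#' @export
nn_backward.nn_channel_attn <- function(m, dy) {
  cc <- m$cache
  x <- cc$x; d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  gate4 <- array(rep(cc$gate, each = H * W), dim = d)
  dx <- dy * gate4
  # dgate[c, n] = sum_{h,w} dy * x
  prod_ <- array(dy * x, dim = c(H * W, C, N))
  dgate <- matrix(0, C, N)
  for (n in seq_len(N)) dgate[, n] <- colSums(prod_[, , n, drop = TRUE])
  dlog <- dgate * cc$gate * (1 - cc$gate)
  back_mlp <- function(p, v, ds) {
    dhid <- crossprod(m$params$W2, ds)
    dhid[p$pre <= 0] <- 0
    m$grads$W2 <<- m$grads$W2 + ds %*% t(p$hid)
    m$grads$b2 <<- m$grads$b2 + rowSums(ds)
    m$grads$W1 <<- m$grads$W1 + dhid %*% t(v)
    m$grads$b1 <<- m$grads$b1 + rowSums(dhid)
    crossprod(m$params$W1, dhid)                       # C x N
  }
  davg <- back_mlp(cc$pa, cc$avg, dlog)
  dmax <- back_mlp(cc$pm, cc$mx, dlog)
  dx <- dx + array(rep(davg / (H * W), each = H * W), dim = d)
  dxm <- array(0, dim = c(H * W, C, N))
  for (n in seq_len(N))
    for (ch in seq_len(C))
      dxm[cc$amax[ch, n], ch, n] <- dmax[ch, n]
  dx + array(dxm, dim = d)
}

# --- spatial attention module ----------------------------------------------

nn_spatial_attn <- function(k = 7L) {
  if (k %% 2L == 0L) stop("spatial attention kernel size must be odd")
  m <- new_module("spatial_attn")
  m$k <- as.integer(k)
  sd <- sqrt(2 / (k * k * 2))
  m$params$W <- array(rnorm(k * k * 2, sd = sd), dim = c(k, k, 2L, 1L))
  m$params$b <- numeric(1)
  m
}

#' @export
nn_forward.nn_spatial_attn <- function(m, x, training = FALSE) {
  x <- as_nchw(x)
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  favg <- array(0, dim = c(H, W, 1L, N))
  fmax <- array(0, dim = c(H, W, 1L, N))
  amax <- array(1L, dim = c(H, W, 1L, N))
  for (n in seq_len(N)) {
    sl <- x[, , , n, drop = FALSE]
    favg[, , 1, n] <- rowMeans(array(sl, dim = c(H * W, C)))
    mxv <- sl[, , 1, 1]; mxi <- array(1L, dim = c(H, W))
    if (C > 1) for (ch in 2:C) {
      upd <- sl[, , ch, 1] > mxv
      mxv[upd] <- sl[, , ch, 1][upd]
      mxi[upd] <- ch
    }
    fmax[, , 1, n] <- mxv
    amax[, , 1, n] <- mxi
  }
  cat2 <- array(0, dim = c(H, W, 2L, N))
  cat2[, , 1, ] <- favg; cat2[, , 2, ] <- fmax
  logits <- cpp_conv2d(cat2, m$params$W, m$params$b, (m$k - 1L) %/% 2L)
  gate <- sigmoid(logits)                              # H, W, 1, N
  y <- x * bcast_ch(gate, C)
  m$cache <- list(x = x, cat2 = cat2, amax = amax, gate = gate)
  y
}

#' @export
nn_backward.nn_spatial_attn <- function(m, dy) {
  cc <- m$cache
  x <- cc$x; d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  gate <- cc$gate
  dx <- dy * bcast_ch(gate, C)
  dgate <- array(0, dim = c(H, W, 1L, N))
  prod_ <- dy * x
  for (ch in seq_len(C)) dgate <- dgate + prod_[, , ch, , drop = FALSE]
  dlog <- dgate * gate * (1 - gate)
  bk <- cpp_conv2d_backward(cc$cat2, m$params$W, dlog, (m$k - 1L) %/% 2L)
  m$grads$W <- m$grads$W + bk$dw
  m$grads$b <- m$grads$b + bk$db
  dcat <- bk$dx
  davg <- dcat[, , 1, , drop = FALSE]
  dmax <- dcat[, , 2, , drop = FALSE]
  dx <- dx + bcast_ch(davg, C) / C
  for (n in seq_len(N)) {
    mxi <- cc$amax[, , 1, n]
    dm <- dmax[, , 1, n]
    for (ch in seq_len(C)) {
      sel <- mxi == ch
      if (any(sel)) {
        sl <- dx[, , ch, n]
        sl[sel] <- sl[sel] + dm[sel]
        dx[, , ch, n] <- sl
      }
    }
  }
  dx
}

# --- fused attention branch of the guided filter ---------------------------
#
# Algorithm: each input (the filtered map F and the low-resolution guide Gl)
# passes through channel attention then spatial attention; the two gated
# maps are reduced to one channel by the channel mean, summed, rectified,
# convolved (3x3, 1 -> 1) and squashed by a sigmoid.  Output strictly in
# (0,1), shape (h, w, 1, N).

nn_csfag_attn <- function(C, rho = 16L, ks = 7L) {
  m <- new_module("csfag_attn")
  m$C <- as.integer(C)
  m$children$caF <- nn_channel_attn(C, rho)
  m$children$saF <- nn_spatial_attn(ks)
  m$children$caG <- nn_channel_attn(C, rho)
  m$children$saG <- nn_spatial_attn(ks)
  m$children$fuse <- nn_conv(1L, 1L, k = 3L, bn = FALSE, act = "none")
  m
}

csfag_attn_forward <- function(m, Fp, Gl, training = FALSE) {
  C <- dim(Fp)[3]
  FSA <- nn_forward(m$children$saF, nn_forward(m$children$caF, Fp, training),
                    training)
  GSA <- nn_forward(m$children$saG, nn_forward(m$children$caG, Gl, training),
                    training)
  chmean <- function(z) {
    out <- z[, , 1, , drop = FALSE]
    if (C > 1) for (ch in 2:C) out <- out + z[, , ch, , drop = FALSE]
    out / C
  }
  A0 <- chmean(FSA) + chmean(GSA)
  A1 <- pmax(A0, 0)
  A2 <- nn_forward(m$children$fuse, A1, training)
  A <- sigmoid(A2)
  m$cache <- list(A0 = A0, A = A, C = C)
  list(A = A, A0 = A0, A1 = A1, A2 = A2)
}

csfag_attn_backward <- function(m, dA) {
  cc <- m$cache
  dA2 <- dA * cc$A * (1 - cc$A)
  dA1 <- nn_backward(m$children$fuse, dA2)
  dA0 <- dA1 * (cc$A0 > 0)
  dchmean <- bcast_ch(dA0, cc$C) / cc$C
  dF <- nn_backward(m$children$caF, nn_backward(m$children$saF, dchmean))
  dG <- nn_backward(m$children$caG, nn_backward(m$children$saG, dchmean))
  list(dF = dF, dGl = dG)
}

# --- functional API --------------------------------------------------------

#' Attention parameter containers
#'
#' Creates randomly initialised weights for the attention branch used by the
#' guided filter: two CBAM-style channel+spatial attention stacks (one for
#' the filtered map, one for the low-resolution guide) plus the 3x3 fusion
#' convolution.
#'
#' @param C channel count of the feature maps entering the attention branch.
#' @param rho reduction ratio of the shared channel perceptron (default 16).
#' @param ks spatial-attention kernel size, odd (default 7).
#' @return an opaque parameter object consumed by [csfag_forward()] and
#'   [csfag_attention_fusion()].
#' @export
make_attention_params <- function(C, rho = 16L, ks = 7L) {
  nn_csfag_attn(C, rho, ks)
}

check_feature_map <- function(x, name = "x") {
  if (is.null(dim(x)) || !(length(dim(x)) %in% c(2L, 3L)))
    stop(name, " must be an (H, W) or (H, W, C) array")
  if (any(dim(x)[1:2] < 1L)) stop(name, " has empty spatial extent")
  if (!all(is.finite(x))) stop(name, " contains non-finite values")
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

#' Channel attention gate
#'
#' Global average and max pooling per channel through a shared two-layer
#' perceptron (hidden ReLU, reduction ratio `rho`); the two outputs are
#' summed and passed through a sigmoid, giving one multiplicative gate per
#' channel in (0,1).
#'
#' @param x feature map, array (H, W, C).
#' @param rho reduction ratio; hidden width is `max(C %/% rho, 1)`.
#' @param params optional list with `W1` (h x C), `b1`, `W2` (C x h), `b2`;
#'   random He-initialised weights are drawn when omitted.
#' @return list with `state` (pooled_avg, pooled_max, logits, weights) and
#'   `gated` (the input scaled per channel).
#' @export
channel_attention <- function(x, rho = 16L, params = NULL) {
  x <- check_feature_map(x)
  C <- dim(x)[3]
  m <- nn_channel_attn(C, rho)
  if (!is.null(params)) {
    stopifnot(all(c("W1", "b1", "W2", "b2") %in% names(params)))
    m$params <- params[c("W1", "b1", "W2", "b2")]
  }
  y <- nn_forward(m, x)
  cc <- m$cache
  list(state = list(pooled_avg = drop(cc$avg), pooled_max = drop(cc$mx),
                    logits = drop(cc$logits), weights = drop(cc$gate)),
       gated = array(y, dim = dim(x)))
}

#' Spatial attention gate
#'
#' Channel-wise average and max maps concatenated and convolved
#' (`k_s` x `k_s`, 2 -> 1 channels, zero padding) then squashed by a
#' sigmoid, giving one multiplicative gate per pixel in (0,1).
#'
#' @param x feature map, array (H, W, C).
#' @param k_s odd convolution kernel size (default 7).
#' @param params optional list with `W` (k, k, 2, 1) and `b` (length 1).
#' @return list with `state` (pooled_avg, pooled_max, logits, weights) and
#'   `gated`.
#' @export
spatial_attention <- function(x, k_s = 7L, params = NULL) {
  x <- check_feature_map(x)
  if (k_s %% 2L == 0L) stop("k_s must be odd")
  m <- nn_spatial_attn(k_s)
  if (!is.null(params)) {
    stopifnot(all(c("W", "b") %in% names(params)))
    m$params <- params[c("W", "b")]
  }
  y <- nn_forward(m, x)
  cc <- m$cache
  logits <- cpp_conv2d(cc$cat2, m$params$W, m$params$b, (k_s - 1L) %/% 2L)
  list(state = list(pooled_avg = cc$cat2[, , 1, 1],
                    pooled_max = cc$cat2[, , 2, 1],
                    logits = logits[, , 1, 1],
                    weights = cc$gate[, , 1, 1]),
       gated = array(y, dim = dim(x)))
}

#' Fused attention map for the guided filter
#'
#' Applies channel-then-spatial attention independently to the filtered map
#' `F` and the low-resolution guide `Gl`, reduces each gated map to one
#' channel by the channel mean, sums, rectifies, convolves (3x3, 1 -> 1) and
#' applies a sigmoid.  All values of the result lie strictly in (0,1).
#'
#' @param F filtered feature map, array (h, w, C).
#' @param Gl low-resolution guide, same shape as `F`.
#' @param params attention weights from [make_attention_params()]; random
#'   when omitted.
#' @return list with `A` (h x w matrix in (0,1)) and intermediates
#'   `A0`, `A1`, `A2`.
#' @export
csfag_attention_fusion <- function(F, Gl, params = NULL) {
  F <- check_feature_map(F, "F"); Gl <- check_feature_map(Gl, "Gl")
  if (!identical(dim(F), dim(Gl))) stop("F and Gl must have the same shape")
  if (is.null(params)) params <- make_attention_params(dim(F)[3])
  out <- csfag_attn_forward(params, as_nchw(F), as_nchw(Gl))
  list(A = out$A[, , 1, 1], A0 = out$A0[, , 1, 1],
       A1 = out$A1[, , 1, 1], A2 = out$A2[, , 1, 1])
}
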