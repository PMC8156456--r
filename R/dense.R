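# Densely connected bottleneck.
#
# D dense blocks replace the plain bottleneck double conv.  Block i receives
# the channel concatenation (newest first) of all previous block outputs and
# the bottleneck input X0, applies two 3x3 conv + batch-norm + ReLU layers,
# and emits `growth` channels.  The final concatenation of every output with
# X0 passes through a 1x1 transition convolution.  D = 1 is the degenerate
# case: no dense connectivity, just the plain double conv (the standard
# U-Net bottleneck).

nn_dense_bottleneck <- function(c0, growth, D, transition, plain_width) {
  m <- new_module("dense_bottleneck")
  m$c0 <- as.integer(c0); m$growth <- as.integer(growth)
  m$D <- as.integer(D)
  if (D == 1L) {
    m$children$plain <- double_conv(c0, plain_width)
    m$out_channels <- as.integer(plain_width)
  } else {
    for (i in seq_len(D))
      m$children[[paste0("block", i)]] <-
        double_conv(c0 + (i - 1L) * growth, growth)
    m$children$trans <- nn_conv(c0 + D * growth, transition, k = 1L)
    m$out_channels <- as.integer(transition)
  }
  m
}

dense_forward <- function(m, x, training = FALSE) {
  if (m$D == 1L) return(dc_forward(m$children$plain, x, training))
  feats <- list(x)                       # oldest last; concat newest first
  for (i in seq_len(m$D)) {
    inp <- if (length(feats) == 1L) feats[[1]] else concat_ch(feats)
    xi <- dc_forward(m$children[[paste0("block", i)]], inp, training)
    feats <- c(list(xi), feats)
  }
  m$cache <- list(sizes = vapply(feats, function(z) dim(z)[3], 1L))
  nn_forward(m$children$trans, concat_ch(feats), training)
}

dense_backward <- function(m, dy) {
  if (m$D == 1L) return(dc_backward(m$children$plain, dy))
  dcat <- nn_backward(m$children$trans, dy)
  sizes <- m$cache$sizes                 # newest first, X0 last
  dfeats <- split_ch(dcat, sizes)
  # walk blocks newest to oldest, accumulating gradients into earlier feats
  for (i in m$D:1) {
    dxi <- dfeats[[m$D - i + 1L]]
    dinp <- dc_backward(m$children[[paste0("block", i)]], dxi)
    in_sizes <- sizes[(m$D - i + 2L):length(sizes)]
    dparts <- split_ch(dinp, in_sizes)
    for (j in seq_along(dparts)) {
      k <- m$D - i + 1L + j
      dfeats[[k]] <- dfeats[[k]] + dparts[[j]]
    }
  }
  dfeats[[length(dfeats)]]               # gradient w.r.t. X0
}

# --- functional API --------------------------------------------------------

#' Dense-block forward
#'
#' Concatenates the given feature maps (newest first) along the channel
#' axis and applies two 3x3 conv + batch-norm + ReLU layers emitting
#' `growth` channels.
#'
#' @param inputs list of feature maps (H, W, C_j), newest first; the last
#'   element is the initial feature X0.
#' @param block_params optional `double_conv` module with matching input
#'   width; freshly initialised when omitted.
#' @param growth output channel count when `block_params` is omitted.
#' @return the block output, (H, W, growth).
#' @export
dense_block_forward <- function(inputs, block_params = NULL, growth = 8L) {
  stopifnot(is.list(inputs), length(inputs) >= 1)
  inputs <- lapply(inputs, check_feature_map)
  sp <- dim(inputs[[1]])[1:2]
  for (x in inputs)
    if (!identical(dim(x)[1:2], sp)) stop("spatial shapes must match")
  cin <- sum(vapply(inputs, function(z) dim(z)[3], 1L))
  if (is.null(block_params)) block_params <- double_conv(cin, growth)
  x4 <- concat_ch(lapply(inputs, as_nchw))
  y <- dc_forward(block_params, x4)
  array(y, dim = dim(y)[1:3])
}

#' Densely connected bottleneck forward
#'
#' Runs D dense blocks with growth rate n on the input, concatenates all
#' block outputs with the input, and applies the 1x1 transition.
#'
#' @param x input feature map (H, W, c0).
#' @param D number of dense blocks (1 = plain double conv).
#' @param growth growth rate n.
#' @param transition transition output width.
#' @param plain_width output width of the degenerate D = 1 bottleneck.
#' @param module optional prebuilt `nn_dense_bottleneck` (reused across
#'   calls for fixed weights).
#' @return the bottleneck output feature map.
#' @export
bottleneck_forward <- function(x, D = 3L, growth = 8L, transition = 16L,
                               plain_width = 16L, module = NULL) {
  x <- check_feature_map(x)
  if (is.null(module))
    module <- nn_dense_bottleneck(dim(x)[3], growth, D, transition,
                                  plain_width)
  y <- dense_forward(module, as_nchw(x))
  array(y, dim = dim(y)[1:3])
}
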