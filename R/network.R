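# Architecture variants.
#
# All variants share a 4-level encoder/decoder (widths doubling per level)
# with 2x2 max pooling, bilinear upsampling + 3x3 conv in the decoder, and a
# 2-class softmax head.
#
#   unet         plain skips, plain bottleneck, single output head
#   mnet         + pyramid inputs (1/2, 1/4, 1/8 average-pooled copies,
#                  conv-embedded and concatenated at the matching encoder
#                  level) and side outputs at every decoder level, averaged
#                  into the final map
#   mnet_dc      mnet + densely connected bottleneck (D blocks, growth n,
#                  1x1 transition)
#   mnet_csfag   mnet + CSFAG modules on all four skip connections
#   csag_dccnet  mnet + dense bottleneck + CSFAG skips (the full model)
#
# The channel plan below ("calibrated" configs) is fixed by the published
# parameter budgets of the five variants; see calibrated_config().

VARIANTS <- c("unet", "mnet", "mnet_dc", "mnet_csfag", "csag_dccnet")

#' Network configuration
#'
#' @param variant one of `"unet"`, `"mnet"`, `"mnet_dc"`, `"mnet_csfag"`,
#'   `"csag_dccnet"`.
#' @param base_width encoder width at level 1; levels use
#'   `base_width * c(1, 2, 4, 8)` and the plain bottleneck
#'   `16 * base_width`.
#' @param pyramid_widths embed widths of the 1/2, 1/4, 1/8 pyramid inputs
#'   (mnet family).
#' @param growth dense-bottleneck growth rate n.
#' @param transition dense-bottleneck 1x1 transition output width.
#' @param dense_blocks number of dense blocks D (default 3; D = 1 is the
#'   degenerate plain bottleneck).
#' @param csfag_widths internal transform widths of the CSFAG modules at
#'   skip levels 1..4.
#' @param r,lambda guided-filter window radius and ridge regulariser.
#' @param rho,ks attention reduction ratio and spatial kernel size.
#' @param in_channels,classes,input_size input geometry.
#' @param csfag_weighted use attention-weighted window statistics (default)
#'   or the strict as-printed unweighted solve.
#' @return a list of class `net_config`.
#' @export
net_config <- function(variant = "csag_dccnet",
                       base_width = 8L,
                       pyramid_widths = c(8L, 16L, 32L),
                       growth = 8L,
                       transition = 64L,
                       dense_blocks = 3L,
                       csfag_widths = c(8L, 16L, 32L, 64L),
                       r = 4L, lambda = 0.001, rho = 16L, ks = 7L,
                       in_channels = 3L, classes = 2L, input_size = 256L,
                       csfag_weighted = TRUE) {
  variant <- match.arg(variant, VARIANTS)
  stopifnot(base_width >= 1, length(pyramid_widths) == 3,
            length(csfag_widths) == 4, dense_blocks >= 1)
  cfg <- list(variant = variant,
              base_width = as.integer(base_width),
              widths = as.integer(base_width * c(1L, 2L, 4L, 8L)),
              bottleneck_width = as.integer(16L * base_width),
              pyramid_widths = as.integer(pyramid_widths),
              growth = as.integer(growth),
              transition = as.integer(transition),
              dense_blocks = as.integer(dense_blocks),
              csfag_widths = as.integer(csfag_widths),
              r = as.integer(r), lambda = lambda,
              rho = as.integer(rho), ks = as.integer(ks),
              in_channels = as.integer(in_channels),
              classes = as.integer(classes),
              input_size = as.integer(input_size),
              csfag_weighted = isTRUE(csfag_weighted))
  cfg$pyramid <- variant != "unet"
  cfg$side_outputs <- variant != "unet"
  cfg$dense <- variant %in% c("mnet_dc", "csag_dccnet")
  cfg$csfag <- variant %in% c("mnet_csfag", "csag_dccnet")
  # width reaching the level-4 decoder from the bottleneck
  cfg$bottleneck_out <- if (cfg$dense && cfg$dense_blocks > 1L)
    cfg$transition else cfg$bottleneck_width
  class(cfg) <- "net_config"
  cfg
}

# Channel plan calibrated against the published per-variant parameter
# budgets (in millions): unet 8.6, mnet 10.92, mnet_dc 13.79,
# mnet_csfag 24.89, csag_dccnet 28.74.  The base width is fixed first by
# the unet budget, then the pyramid embeds by the mnet delta, then growth,
# transition and CSFAG transform widths jointly by the remaining three
# budgets (the bottleneck transition width couples the dense and CSFAG
# additions through the level-4 skip).  Values found by exhaustive integer
# search over the closed-form count; see count_parameters_config().

#' Calibrated full-size configuration for a variant
#'
#' Returns the [net_config()] whose exact trainable parameter count
#' reproduces the published budget of the given variant at printed
#' rounding.
#'
#' @param variant variant name.
#' @return a `net_config`.
#' @export
calibrated_config <- function(variant = VARIANTS) {
  variant <- match.arg(variant)
  do.call(net_config, c(list(variant = variant), CALIBRATED_PLAN))
}

#' Reduced-width configuration for desk-scale training
#'
#' Same topology as [calibrated_config()] but with small widths so the
#' model trains in minutes on one CPU.
#'
#' @param variant variant name.
#' @param input_size spatial input size (default 128).
#' @return a `net_config`.
#' @export
reduced_config <- function(variant = VARIANTS, input_size = 128L) {
  variant <- match.arg(variant)
  net_config(variant = variant, base_width = 8L,
             pyramid_widths = c(8L, 8L, 8L), growth = 16L, transition = 64L,
             csfag_widths = c(8L, 16L, 16L, 32L), rho = 4L,
             input_size = as.integer(input_size))
}

# --- model construction ----------------------------------------------------

double_conv <- function(cin, cmid, cout = cmid) {
  m <- new_module("double_conv")
  m$children$c1 <- nn_conv(cin, cmid)
  m$children$c2 <- nn_conv(cmid, cout)
  m
}

dc_forward <- function(m, x, training = FALSE)
  nn_forward(m$children$c2, nn_forward(m$children$c1, x, training), training)

dc_backward <- function(m, dy)
  nn_backward(m$children$c1, nn_backward(m$children$c2, dy))

concat_ch <- function(lst) {
  dims <- lapply(lst, dim)
  C <- sum(vapply(dims, `[`, 1L, 3L))
  d <- dims[[1]]
  out <- array(0, dim = c(d[1], d[2], C, d[4]))
  off <- 0L
  for (x in lst) {
    cx <- dim(x)[3]
    out[, , off + seq_len(cx), ] <- x
    off <- off + cx
  }
  out
}

split_ch <- function(x, sizes) {
  out <- vector("list", length(sizes))
  off <- 0L
  for (i in seq_along(sizes)) {
    out[[i]] <- x[, , off + seq_len(sizes[i]), , drop = FALSE]
    off <- off + sizes[i]
  }
  out
}

#' Build a segmentation model
#'
#' Instantiates the architecture described by a [net_config()] with
#' He-initialised weights (seed the R RNG beforehand for reproducibility).
#'
#' @param cfg a `net_config`.
#' @return an `nn_module` of class `nn_segnet`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "net_config"))
  w <- cfg$widths; wb <- cfg$bottleneck_width
  m <- new_module("segnet")
  m$cfg <- cfg
  # encoder
  m$children$enc1 <- double_conv(cfg$in_channels, w[1])
  m$children$enc1$children$c1$need_dx <- FALSE
  for (l in 2:4) {
    cin <- w[l - 1]
    if (cfg$pyramid) {
      p <- cfg$pyramid_widths[l - 1]
      m$children[[paste0("pyr", l)]] <- double_conv(cfg$in_channels, p)
      m$children[[paste0("pyr", l)]]$children$c1$need_dx <- FALSE
      cin <- cin + p
    }
    m$children[[paste0("enc", l)]] <- double_conv(cin, w[l])
  }
  # bottleneck
  if (cfg$dense) {
    m$children$bott <- nn_dense_bottleneck(w[4], cfg$growth,
                                           cfg$dense_blocks,
                                           cfg$transition, wb)
  } else {
    m$children$bott <- double_conv(w[4], wb)
  }
  # decoder
  for (l in 4:1) {
    cdeep <- if (l == 4) cfg$bottleneck_out else w[l + 1]
    m$children[[paste0("up", l)]] <- nn_conv(cdeep, w[l])
    if (cfg$csfag) {
      m$children[[paste0("csfag", l)]] <-
        nn_csfag(w[l], cdeep, cfg$csfag_widths[l], w[l], r = cfg$r,
                 lambda = cfg$lambda, rho = cfg$rho, ks = cfg$ks,
                 weighted = cfg$csfag_weighted)
    }
    m$children[[paste0("dec", l)]] <- double_conv(2L * w[l], w[l])
  }
  # heads
  if (cfg$side_outputs) {
    for (l in 1:4)
      m$children[[paste0("side", l)]] <-
        nn_conv(w[l], cfg$classes, k = 1L, bn = FALSE, act = "none")
  } else {
    m$children$head <- nn_conv(w[1], cfg$classes, k = 1L, bn = FALSE,
                               act = "none")
  }
  m
}

#' Forward pass
#'
#' @param model an `nn_segnet` from [build_model()].
#' @param x input batch, array (S, S, 3, N) (a single (S, S, 3) image is
#'   promoted).
#' @param training logical; enables batch-norm batch statistics and caches
#'   for [segnet_backward()].
#' @return a prediction bundle: list with `side_logits` (full-resolution
#'   logit arrays), `side_maps` (softmax probability arrays, one per side
#'   output), `final_map` (their element-wise mean) and `mask`
#'   (argmax lesion mask, (S, S, N) of 0/1).
#' @export
segnet_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  x <- as_nchw(x)
  S <- dim(x)[1]; N <- dim(x)[4]
  st <- list()
  # encoder
  e <- vector("list", 4)
  e[[1]] <- dc_forward(model$children$enc1, x, training)
  img <- x
  pool_idx <- vector("list", 4)
  cat_sizes <- vector("list", 4)
  cur <- e[[1]]
  for (l in 2:4) {
    pl <- maxpool2(cur)
    pool_idx[[l]] <- pl$idx
    inp <- pl$y
    if (cfg$pyramid) {
      img <- avgpool2(img)
      emb <- dc_forward(model$children[[paste0("pyr", l)]], img, training)
      cat_sizes[[l]] <- c(dim(inp)[3], dim(emb)[3])
      inp <- concat_ch(list(inp, emb))
    }
    e[[l]] <- dc_forward(model$children[[paste0("enc", l)]], inp, training)
    cur <- e[[l]]
  }
  pb <- maxpool2(e[[4]])
  st$pool_b_idx <- pb$idx
  b <- if (cfg$dense) dense_forward(model$children$bott, pb$y, training)
       else dc_forward(model$children$bott, pb$y, training)
  # decoder
  d <- vector("list", 4)
  deep <- b
  for (l in 4:1) {
    eh <- dim(e[[l]])[1]; ew <- dim(e[[l]])[2]
    up_rs <- bilinear_resize(deep, eh, ew)
    u <- nn_forward(model$children[[paste0("up", l)]], up_rs, training)
    skip <- if (cfg$csfag)
      csfag_layer_forward(model$children[[paste0("csfag", l)]],
                          e[[l]], deep, training)
    else e[[l]]
    cat_ <- concat_ch(list(u, skip))
    d[[l]] <- dc_forward(model$children[[paste0("dec", l)]], cat_, training)
    deep <- d[[l]]
  }
  # heads
  side_logits <- list(); side_maps <- list()
  if (cfg$side_outputs) {
    for (l in 1:4) {
      lg <- nn_forward(model$children[[paste0("side", l)]], d[[l]], training)
      lg_up <- if (dim(lg)[1] == S) lg else bilinear_resize(lg, S, S)
      side_logits[[l]] <- lg_up
      side_maps[[l]] <- softmax_ch(lg_up)
    }
  } else {
    lg <- nn_forward(model$children$head, d[[1]], training)
    side_logits[[1]] <- lg
    side_maps[[1]] <- softmax_ch(lg)
  }
  final_map <- side_maps[[1]]
  if (length(side_maps) > 1) {
    for (i in 2:length(side_maps)) final_map <- final_map + side_maps[[i]]
    final_map <- final_map / length(side_maps)
  }
  mask <- (final_map[, , 2, , drop = TRUE] > final_map[, , 1, , drop = TRUE]) * 1
  if (N == 1L) dim(mask) <- c(S, S) else dim(mask) <- c(S, S, N)
  st$e <- e; st$pool_idx <- pool_idx; st$cat_sizes <- cat_sizes
  st$d <- d; st$S <- S
  model$cache <- st
  list(side_logits = side_logits, side_maps = side_maps,
       final_map = final_map, mask = mask)
}

# Backward from per-side logit gradients (list aligned with side_logits).
segnet_backward <- function(model, dside_logits) {
  cfg <- model$cfg
  st <- model$cache
  e <- st$e; d <- st$d
  nlev <- if (cfg$side_outputs) 4L else 1L
  dd <- vector("list", 4)
  for (l in seq_len(nlev)) {
    dlg <- dside_logits[[l]]
    hl <- dim(d[[l]])[1]; wl <- dim(d[[l]])[2]
    if (dim(dlg)[1] != hl) dlg <- bilinear_resize_backward(dlg, hl, wl)
    g <- nn_backward(model$children[[if (cfg$side_outputs)
      paste0("side", l) else "head"]], dlg)
    dd[[l]] <- g
  }
  for (l in 1:4) if (is.null(dd[[l]]))
    dd[[l]] <- array(0, dim = dim(d[[l]]))
  de <- vector("list", 4)
  ddeep_next <- NULL                      # gradient flowing into d[[l+1]]
  for (l in 1:4) {
    dl <- dd[[l]]
    if (!is.null(ddeep_next)) dl <- dl + ddeep_next
    dcat <- dc_backward(model$children[[paste0("dec", l)]], dl)
    wl <- cfg$widths[l]
    parts <- split_ch(dcat, c(wl, wl))
    du <- parts[[1]]; dskip <- parts[[2]]
    dup_rs <- nn_backward(model$children[[paste0("up", l)]], du)
    deep_src <- if (l == 4) NULL else d[[l + 1]]
    hd <- if (l == 4) dim(st$pool_b_idx)[1] else dim(d[[l + 1]])[1]
    wd <- if (l == 4) dim(st$pool_b_idx)[2] else dim(d[[l + 1]])[2]
    ddeep <- bilinear_resize_backward(dup_rs, hd, wd)
    if (cfg$csfag) {
      cs <- csfag_layer_backward(model$children[[paste0("csfag", l)]], dskip)
      de[[l]] <- cs$dG
      ddeep <- ddeep + cs$dF
    } else {
      de[[l]] <- dskip
    }
    if (l == 4) dbott_out <- ddeep else ddeep_next <- ddeep
  }
  # bottleneck
  dpb <- if (cfg$dense) dense_backward(model$children$bott, dbott_out)
         else dc_backward(model$children$bott, dbott_out)
  de[[4]] <- de[[4]] + maxpool2_backward(dpb, st$pool_b_idx,
                                         dim(e[[4]])[1], dim(e[[4]])[2])
  # encoder, deepest first
  for (l in 4:2) {
    dinp <- dc_backward(model$children[[paste0("enc", l)]], de[[l]])
    if (cfg$pyramid) {
      parts <- split_ch(dinp, st$cat_sizes[[l]])
      dpool <- parts[[1]]
      dc_backward(model$children[[paste0("pyr", l)]], parts[[2]])
    } else {
      dpool <- dinp
    }
    de[[l - 1]] <- de[[l - 1]] +
      maxpool2_backward(dpool, st$pool_idx[[l]],
                        dim(e[[l - 1]])[1], dim(e[[l - 1]])[2])
  }
  dc_backward(model$children$enc1, de[[1]])
  invisible(NULL)
}

# --- loss ------------------------------------------------------------------

#' Multi-label segmentation loss
#'
#' Mean over side outputs of the per-pixel two-class cross-entropy between
#' each side probability map and the binary target mask (the averaged final
#' map is excluded: it is the mean of the side maps).  Probabilities are
#' clamped at 1e-7 before the logarithm.
#'
#' @param bundle prediction bundle from [segnet_forward()].
#' @param target binary mask, (S, S) or (S, S, N), values in {0, 1}.
#' @return scalar loss.
#' @export
multi_label_loss <- function(bundle, target) {
  if (!all(target %in% c(0, 1))) stop("target mask must be binary 0/1")
  loss_grad <- multi_label_loss_grad(bundle, target)
  loss_grad$loss
}

# Loss plus the gradients w.r.t. each side-logit array.
multi_label_loss_grad <- function(bundle, target) {
  sides <- bundle$side_maps
  ns <- length(sides)
  d <- dim(sides[[1]])
  S <- d[1]; N <- d[4]
  y <- array(target, dim = c(S, S, 1L, N))
  loss <- 0
  grads <- vector("list", ns)
  npx <- S * S * N
  for (i in seq_len(ns)) {
    p <- sides[[i]]
    p1 <- pmax(p[, , 2, , drop = FALSE], 1e-7)
    p0 <- pmax(p[, , 1, , drop = FALSE], 1e-7)
    loss <- loss - sum(y * log(p1) + (1 - y) * log(p0)) / npx
    g <- array(0, dim = d)
    g[, , 1, ] <- (p[, , 1, , drop = FALSE] - (1 - y)) / (npx * ns)
    g[, , 2, ] <- (p[, , 2, , drop = FALSE] - y) / (npx * ns)
    grads[[i]] <- g
  }
  list(loss = loss / ns, grads = grads)
}

# --- closed-form parameter accounting --------------------------------------

#' Exact parameter count from a configuration
#'
#' Closed-form count of trainable scalars, written independently of the
#' model builder (the test suite checks both routes agree).
#'
#' @param cfg a `net_config`.
#' @return numeric scalar (exact integer value).
#' @export
count_parameters_config <- function(cfg) {
  conv <- function(cin, cout, k = 3, bn = TRUE)
    k * k * cin * cout + cout + if (bn) 2 * cout else 0
  dconv <- function(cin, cmid, cout = cmid)
    conv(cin, cmid) + conv(cmid, cout)
  w <- cfg$widths; wb <- cfg$bottleneck_width
  tot <- 0
  # encoder
  tot <- tot + dconv(cfg$in_channels, w[1])
  for (l in 2:4) {
    cin <- w[l - 1]
    if (cfg$pyramid) {
      p <- cfg$pyramid_widths[l - 1]
      tot <- tot + dconv(cfg$in_channels, p)
      cin <- cin + p
    }
    tot <- tot + dconv(cin, w[l])
  }
  # bottleneck
  if (cfg$dense && cfg$dense_blocks > 1L) {
    n <- cfg$growth
    for (i in seq_len(cfg$dense_blocks))
      tot <- tot + dconv(w[4] + (i - 1) * n, n)
    tot <- tot + conv(w[4] + cfg$dense_blocks * n, cfg$transition, k = 1)
  } else {
    tot <- tot + dconv(w[4], wb)
  }
  # decoder (+ CSFAG)
  for (l in 4:1) {
    cdeep <- if (l == 4) cfg$bottleneck_out else w[l + 1]
    tot <- tot + conv(cdeep, w[l])                 # up conv
    tot <- tot + dconv(2 * w[l], w[l])
    if (cfg$csfag) {
      m <- cfg$csfag_widths[l]
      h <- max(m %/% cfg$rho, 1)
      mlp <- 2 * m * h + h + m
      attn_branch <- mlp + (cfg$ks^2 * 2 + 1)
      tot <- tot + conv(w[l], m) + conv(cdeep, m) + conv(m, w[l]) +
        2 * attn_branch + (9 + 1)                  # two branches + fusion
    }
  }
  # heads
  nheads <- if (cfg$side_outputs) 4 else 1
  for (l in seq_len(nheads))
    tot <- tot + conv(w[l], cfg$classes, k = 1, bn = FALSE)
  tot
}
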