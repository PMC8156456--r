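# Input standardisation and the 8x training-set expansion:
# width scaled to 256 px preserving aspect ratio, black padding split
# top/bottom (extra row to the bottom), an HSV copy of every image, and the
# 4-member flip family (identity, horizontal, vertical, both), giving
# 8 training pairs per source pair.

#' @importFrom grDevices rgb2hsv col2rgb hsv
NULL

STD_SIZE <- 256L

round_half_up <- function(x) floor(x + 0.5)

nearest_resize <- function(img, out_h, out_w) {
  d <- dim(img)
  sy <- d[1] / out_h; sx <- d[2] / out_w
  yi <- pmin(pmax(floor((seq_len(out_h) - 0.5) * sy) + 1, 1), d[1])
  xi <- pmin(pmax(floor((seq_len(out_w) - 0.5) * sx) + 1, 1), d[2])
  if (length(d) == 2L) img[yi, xi, drop = FALSE]
  else img[yi, xi, , drop = FALSE]
}

#' Standardise an image (and mask) to 256 x 256
#'
#' Scales the width to 256 px preserving the aspect ratio (bilinear for
#' images, nearest-neighbour for masks), then pads to 256 px height with
#' black, split top/bottom with the extra row at the bottom.  Portrait
#' images (scaled height > 256) are scaled to height 256 and padded
#' left/right instead.  Already-standardised inputs pass through unchanged.
#'
#' @param image integer/numeric array (H, W, 3), values 0..255.
#' @param mask optional binary mask (H, W) (values 0/1 or 0/255); undergoes
#'   identical geometry, nearest-neighbour, re-binarised at 128 (or 0.5).
#' @param size target size (default 256).
#' @return list of class `standardized_image`: `pixels` (size x size x 3),
#'   `mask` (size x size, 0/1, or NULL), `pad` (top, bottom, left, right),
#'   `original_size`, `color_space` ("RGB").
#' @export
resize_and_pad <- function(image, mask = NULL, size = STD_SIZE) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("image must be an (H, W, 3) array")
  if (any(d[1:2] < 1L)) stop("empty image")
  H <- d[1]; W <- d[2]
  new_w <- size
  new_h <- as.integer(round_half_up(H * size / W))
  if (new_h > size) {                       # portrait: fit height instead
    new_h <- size
    new_w <- as.integer(round_half_up(W * size / H))
  }
  img <- array(as.numeric(image), dim = c(H, W, 3L, 1L))
  rs <- bilinear_resize(img, new_h, new_w)
  rs <- round(array(rs, dim = c(new_h, new_w, 3L)))
  out <- array(0L, dim = c(size, size, 3L))
  pad_h <- size - new_h; pad_w <- size - new_w
  top <- pad_h %/% 2L; bottom <- pad_h - top
  left <- pad_w %/% 2L; right <- pad_w - left
  out[top + seq_len(new_h), left + seq_len(new_w), ] <- as.integer(rs)
  mk <- NULL
  if (!is.null(mask)) {
    if (!identical(dim(mask)[1:2], d[1:2]))
      stop("mask geometry must match the image")
    mv <- if (max(mask) > 1) (mask >= 128) * 1 else (mask >= 0.5) * 1
    mr <- nearest_resize(matrix(mv, H, W), new_h, new_w)
    mk <- matrix(0, size, size)
    mk[top + seq_len(new_h), left + seq_len(new_w)] <- mr
  }
  structure(list(pixels = out, mask = mk,
                 pad = c(top = top, bottom = bottom, left = left,
                         right = right),
                 original_size = c(H, W), color_space = "RGB"),
            class = "standardized_image")
}

#' Convert a standardised image from RGB to HSV
#'
#' Standard RGB -> HSV conversion with all three channels rescaled to
#' 0..255.  Refuses to convert twice.
#'
#' @param image a `standardized_image` (RGB).
#' @return the same object with HSV pixels and `color_space = "HSV"`.
#' @export
rgb_to_hsv_image <- function(image) {
  stopifnot(inherits(image, "standardized_image"))
  if (image$color_space == "HSV") stop("image is already HSV")
  px <- image$pixels
  d <- dim(px)
  m <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsv_ <- grDevices::rgb2hsv(m, maxColorValue = 255)
  out <- array(0L, dim = d)
  for (k in 1:3) out[, , k] <- as.integer(round(hsv_[k, ] * 255))
  image$pixels <- out
  image$color_space <- "HSV"
  image
}

# Inverse used only to verify quantisation error in tests.
hsv_to_rgb_image <- function(image) {
  stopifnot(inherits(image, "standardized_image"),
            image$color_space == "HSV")
  px <- image$pixels / 255
  hex <- grDevices::hsv(pmin(px[, , 1], 1), px[, , 2], px[, , 3])
  rgb <- grDevices::col2rgb(hex)
  out <- array(0L, dim = dim(image$pixels))
  for (k in 1:3) out[, , k] <- as.integer(rgb[k, ])
  image$pixels <- out
  image$color_space <- "RGB"
  image
}

#' Undo standardisation geometry on a predicted mask
#'
#' Crops the padding recorded by [resize_and_pad()] and resizes the
#' content back to the original image geometry (nearest-neighbour).
#'
#' @param mask predicted binary mask at the standardised size.
#' @param std the `standardized_image` the prediction corresponds to.
#' @return binary mask at the original (H, W).
#' @export
unpad_mask <- function(mask, std) {
  stopifnot(inherits(std, "standardized_image"))
  d <- dim(std$pixels)
  if (!identical(dim(mask)[1:2], d[1:2]))
    stop("mask does not match the standardised size")
  p <- std$pad
  content <- mask[(p[["top"]] + 1):(d[1] - p[["bottom"]]),
                  (p[["left"]] + 1):(d[2] - p[["right"]]), drop = FALSE]
  out <- nearest_resize(content, std$original_size[1], std$original_size[2])
  (out >= 0.5) * 1
}

flip_one <- function(x, code) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  f <- switch(as.character(code),
              "0" = x,
              "1" = if (length(d) == 2L) x[, W:1, drop = FALSE]
                    else x[, W:1, , drop = FALSE],
              "2" = if (length(d) == 2L) x[H:1, , drop = FALSE]
                    else x[H:1, , , drop = FALSE],
              "3" = if (length(d) == 2L) x[H:1, W:1, drop = FALSE]
                    else x[H:1, W:1, , drop = FALSE],
              stop("flip code must be 0..3"))
  f
}

#' The four-member flip family
#'
#' Returns the original, horizontal flip, vertical flip, and the combined
#' flip of an image (mask transformed identically by the caller).
#'
#' @param image array (H, W) or (H, W, C).
#' @return list of 4 arrays, flip codes 0..3.
#' @export
flip_family <- function(image) {
  lapply(0:3, function(code) flip_one(image, code))
}

#' Build the 8x augmented training set
#'
#' For each standardised pair, emits the RGB and HSV versions, each with
#' the full flip family: exactly `8 * N` image/mask pairs in deterministic
#' order (source index, colour space RGB before HSV, flip code 0..3).
#' Masks are colour-space invariant and share the geometric transforms.
#'
#' @param pairs list of `standardized_image` objects with non-NULL masks.
#' @return list with `samples` (list of lists: image, mask, source,
#'   color_space, flip) and `manifest` (data.frame).
#' @export
build_training_set <- function(pairs) {
  stopifnot(length(pairs) >= 1)
  for (p in pairs) {
    if (!inherits(p, "standardized_image")) stop("pairs must be standardised")
    if (is.null(p$mask)) stop("every pair needs a mask")
  }
  samples <- vector("list", 8L * length(pairs))
  rows <- vector("list", 8L * length(pairs))
  k <- 0L
  for (i in seq_along(pairs)) {
    rgb <- pairs[[i]]
    hsv_img <- rgb_to_hsv_image(rgb)
    for (cs in c("RGB", "HSV")) {
      px <- if (cs == "RGB") rgb$pixels else hsv_img$pixels
      for (code in 0:3) {
        k <- k + 1L
        samples[[k]] <- list(image = flip_one(px, code),
                             mask = flip_one(rgb$mask, code),
                             source = i, color_space = cs, flip = code)
        rows[[k]] <- data.frame(source = i, color_space = cs, flip = code)
      }
    }
  }
  list(samples = samples, manifest = do.call(rbind, rows))
}
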