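# PNG reading and writing (8-bit grayscale / gray+alpha / RGB / RGBA,
# non-interlaced).  JPEG input is out of scope for this build; inputs are
# PNG throughout.

#' Read a PNG image
#'
#' @param path file path.
#' @return integer array (H, W, C) with values 0..255; C is 1 (gray),
#'   2 (gray+alpha), 3 (RGB) or 4 (RGBA).
#' @export
read_png <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  out <- cpp_png_decode(bytes)
  out$pixels
}

#' Write a PNG image
#'
#' @param pixels numeric or integer array (H, W, C) or matrix (H, W) with
#'   values 0..255 (rounded and clamped).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(pixels, path) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  storage.mode(pixels) <- "integer"
  bytes <- cpp_png_encode(pixels)
  writeBin(as.vector(bytes), path)
  invisible(path)
}
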