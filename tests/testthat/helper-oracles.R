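# Shared helpers: independent slow-path oracles used across test files.

# Explicit bilinear interpolation with half-pixel centers (matrix in/out).
naive_bilinear <- function(img, Ho, Wo) {
  Hi <- nrow(img); Wi <- ncol(img)
  out <- matrix(0, Ho, Wo)
  for (i in seq_len(Ho)) {
    for (j in seq_len(Wo)) {
      sy <- min(max((i - 0.5) * Hi / Ho - 0.5, 0), Hi - 1)
      sx <- min(max((j - 0.5) * Wi / Wo - 0.5, 0), Wi - 1)
      y0 <- if (Hi >= 2) min(floor(sy), Hi - 2) else 0
      x0 <- if (Wi >= 2) min(floor(sx), Wi - 2) else 0
      fy <- sy - y0; fx <- sx - x0
      y1 <- min(y0 + 1, Hi - 1); x1 <- min(x0 + 1, Wi - 1)
      out[i, j] <- img[y0 + 1, x0 + 1] * (1 - fy) * (1 - fx) +
        img[y1 + 1, x0 + 1] * fy * (1 - fx) +
        img[y0 + 1, x1 + 1] * (1 - fy) * fx +
        img[y1 + 1, x1 + 1] * fy * fx
    }
  }
  out
}

# Identity-MLP channel attention parameters (rho = 1, W = I, b = 0).
identity_mlp_params <- function(C) {
  list(W1 = diag(C), b1 = numeric(C), W2 = diag(C), b2 = numeric(C))
}

rand_array <- function(dims, seed) {
  set.seed(seed)
  array(rnorm(prod(dims)), dims)
}
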