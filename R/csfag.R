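# Channel Spatial Fast Attention-guided Filter.
#
# A fast guided filter whose per-window ridge-regularised least squares is
# weighted by squared attention values: for window w_k of radius r around
# pixel k the slope/intercept minimise
#
#     sum_{i in w_k} A_i^2 (W_k Gl_i + B_k - F_i)^2 + lambda W_k^2
#
# whose closed form with the attention weights a_i = A_i^2 absorbed into
# weighted window statistics is
#
#     W_k = (E_a[Gl F] - E_a[Gl] E_a[F]) / (Var_a[Gl] + lambda)
#     B_k = E_a[F] - W_k E_a[Gl].
#
# With uniform attention (A == 1) this reduces to the standard guided
# filter.  Coefficients are averaged over overlapping windows (plain box
# mean with exact border-clipped counts), bilinearly upsampled to the
# guide's resolution, and applied as O = Wh * G + Bh.
#
# Windows are clipped at image borders (no padding); sigma_k^2 is clamped
# at zero to absorb floating-point cancellation; lambda is applied to
# W_k^2 as written, not rescaled by window mass.

#' Filter configuration
#'
#' @param r window radius in pixels (default 4).
#' @param lambda ridge regulariser on the slope (default 0.001).
#' @param subsample_factor integer >= 1; the guide is bilinearly downscaled
#'   by this factor before the window statistics are computed.
#' @param weighted logical; `TRUE` (default) weights the window statistics
#'   by the squared attention map, `FALSE` is the strict as-printed mode in
#'   which the attention map does not enter the solve.
#' @return a list of class `csfag_config`.
#' @export
csfag_config <- function(r = 4L, lambda = 0.001, subsample_factor = 1L,
                         weighted = TRUE) {
  stopifnot(r >= 1L, lambda > 0, subsample_factor >= 1L)
  structure(list(r = as.integer(r), lambda = lambda,
                 subsample_factor = as.integer(subsample_factor),
                 weighted = isTRUE(weighted)),
            class = "csfag_config")
}

#' Bilinear guide subsampling
#'
#' Downscales a guide feature map by an integer factor with bilinear
#' interpolation (half-pixel centers).  `factor = 1` returns the input
#' unchanged.
#'
#' @param G array (H, W, C) or (H, W).
#' @param factor integer >= 1, at most the spatial extent.
#' @return the downscaled map.
#' @export
subsample_guide <- function(G, factor) {
  G <- check_feature_map(G, "G")
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  d <- dim(G)
  if (factor > min(d[1:2])) stop("factor larger than spatial extent")
  if (factor == 1L) return(G)
  out <- bilinear_resize(G, d[1] %/% factor, d[2] %/% factor)
  array(out, dim = dim(out)[1:3])
}

#' Attention-weighted window statistics
#'
#' Means, variance and cross moment of the low-resolution guide `Gl` and
#' filtered map `F` over box windows of radius `r`, either plain box means
#' (`weighted = FALSE` in `cfg`) or weighted by `a_i = A_i^2`.  Windows are
#' clipped exactly at image borders.  Computed with integral images.
#'
#' @param Gl,F arrays (h, w, C) of identical shape.
#' @param A attention map, (h, w) matrix in (0,1) (ignored when unweighted).
#' @param cfg a [csfag_config()].
#' @return list of class `csfag_stats` with per-pixel maps `mu` (weighted
#'   mean of Gl), `var` (weighted variance, clamped >= 0), `fbar` (weighted
#'   mean of F), `cross` (weighted mean of Gl*F), `mass` (window weight
#'   sums) and `counts` (clipped window pixel counts).
#' @export
weighted_box_stats <- function(Gl, F, A = NULL, cfg = csfag_config()) {
  Gl <- check_feature_map(Gl, "Gl"); F <- check_feature_map(F, "F")
  if (!identical(dim(Gl), dim(F))) stop("Gl and F must have the same shape")
  d <- dim(Gl); h <- d[1]; w <- d[2]; C <- d[3]
  r <- cfg$r
  counts <- box_counts(h, w, r)
  if (cfg$weighted) {
    if (is.null(A)) stop("weighted statistics need an attention map")
    if (!identical(dim(A)[1:2], d[1:2])) stop("A shape mismatch")
    a <- array(A^2, dim = c(h, w, 1L))
    mass <- boxsum(a, r)[, , 1]
    if (any(mass <= 0)) stop("window weight mass must be positive")
    ab <- array(rep(a, C), dim = d)
  } else {
    mass <- counts
    ab <- array(1, dim = d)
  }
  m3 <- array(rep(mass, C), dim = d)
  mu <- boxsum(ab * Gl, r) / m3
  fbar <- boxsum(ab * F, r) / m3
  cross <- boxsum(ab * Gl * F, r) / m3
  gg <- boxsum(ab * Gl * Gl, r) / m3
  va <- pmax(gg - mu^2, 0)
  structure(list(mu = mu, var = va, fbar = fbar, cross = cross,
                 mass = mass, counts = counts, r = r),
            class = "csfag_stats")
}

#' Per-window ridge least-squares coefficients
#'
#' Closed-form solution of the attention-weighted local linear model:
#' `Wk = (cross - mu*fbar) / (var + lambda)`, `Bk = fbar - Wk*mu`.
#'
#' @param stats a `csfag_stats` object from [weighted_box_stats()].
#' @param cfg a [csfag_config()] providing `lambda`.
#' @return list with per-pixel coefficient maps `Wk` and `Bk`.
#' @export
solve_coefficients <- function(stats, cfg = csfag_config()) {
  stopifnot(inherits(stats, "csfag_stats"))
  Wk <- (stats$cross - stats$mu * stats$fbar) / (stats$var + cfg$lambda)
  Bk <- stats$fbar - Wk * stats$mu
  if (!all(is.finite(Wk)) || !all(is.finite(Bk)))
    stop("non-finite coefficients")
  list(Wk = Wk, Bk = Bk)
}

#' Average coefficients over overlapping windows
#'
#' Unweighted box mean of the per-window coefficients with exact
#' border-clipped counts: `Wl(i) = mean_{k in Omega_i} Wk(k)`.
#'
#' @param Wk,Bk coefficient maps from [solve_coefficients()].
#' @param cfg a [csfag_config()] providing the radius.
#' @return list with `Wl` and `Bl`.
#' @export
aggregate_coefficients <- function(Wk, Bk, cfg = csfag_config()) {
  Wk <- check_feature_map(Wk, "Wk"); Bk <- check_feature_map(Bk, "Bk")
  if (!identical(dim(Wk), dim(Bk))) stop("Wk and Bk must have the same shape")
  d <- dim(Wk)
  n <- array(rep(box_counts(d[1], d[2], cfg$r), d[3]), dim = d)
  list(Wl = boxsum(Wk, cfg$r) / n, Bl = boxsum(Bk, cfg$r) / n)
}

#' Bilinearly upsample coefficient maps to the guide resolution
#'
#' @param Wl,Bl low-resolution coefficient maps.
#' @param target_shape integer vector c(H, W) of the guide.
#' @return list with `Wh` and `Bh` at the target shape.
#' @export
upsample_coefficients <- function(Wl, Bl, target_shape) {
  Wl <- check_feature_map(Wl, "Wl"); Bl <- check_feature_map(Bl, "Bl")
  H <- target_shape[1]; W <- target_shape[2]
  if (H < dim(Wl)[1] || W < dim(Wl)[2])
    stop("target shape must be at least the low-resolution shape")
  Wh <- bilinear_resize(Wl, H, W)
  Bh <- bilinear_resize(Bl, H, W)
  list(Wh = array(Wh, dim = dim(Wh)[1:3]), Bh = array(Bh, dim = dim(Bh)[1:3]))
}

# Core filter given an attention map (no attention learning involved).
# G: (H, W, C); F: (h, w, C) with (h, w) = (H, W) / subsample_factor;
# A: (h, w) matrix.  Returns O with G's shape.
csfag_filter <- function(G, F, A, cfg = csfag_config()) {
  G <- check_feature_map(G, "G"); F <- check_feature_map(F, "F")
  Gl <- subsample_guide(G, cfg$subsample_factor)
  if (!identical(dim(Gl), dim(F)))
    stop("F shape must equal G shape / subsample_factor")
  stats <- weighted_box_stats(Gl, F, A, cfg)
  co <- solve_coefficients(stats, cfg)
  ag <- aggregate_coefficients(co$Wk, co$Bk, cfg)
  up <- upsample_coefficients(ag$Wl, ag$Bl, dim(G)[1:2])
  up$Wh * G + up$Bh
}

#' Channel spatial fast attention-guided filtering
#'
#' Full module: subsample the guide, produce the fused attention map from
#' the filtered map and the low-resolution guide, solve the attention-
#' weighted local linear model on box windows, average and upsample the
#' coefficients, and apply them to the high-resolution guide.
#'
#' @param G guide feature map (H, W, C).
#' @param F filtered feature map (h, w, C), `h = H / subsample_factor`.
#' @param cfg a [csfag_config()].
#' @param attention_params weights from [make_attention_params()]; freshly
#'   initialised when omitted.
#' @return output feature map O with the shape of `G`.
#' @export
csfag_forward <- function(G, F, cfg = csfag_config(),
                          attention_params = NULL) {
  G <- check_feature_map(G, "G"); F <- check_feature_map(F, "F")
  Gl <- subsample_guide(G, cfg$subsample_factor)
  if (!identical(dim(Gl), dim(F)))
    stop("F shape must equal G shape / subsample_factor")
  if (is.null(attention_params))
    attention_params <- make_attention_params(dim(F)[3])
  A <- csfag_attention_fusion(F, Gl, attention_params)$A
  csfag_filter(G, F, A, cfg)
}

#' Brute-force reference for the attention-guided filter
#'
#' Independent slow-path implementation used for verification: an explicit
#' loop over every window solving the 2x2 weighted normal equations, then
#' explicit overlap averaging and explicit bilinear upsampling.  Shares no
#' code with the fast path.
#'
#' @param G,F,A,cfg as in [csfag_forward()]; `A` is the attention map
#'   (matrix) so the comparison is purely about the filter.
#' @return output feature map with the shape of `G`.
#' @export
csfag_bruteforce_oracle <- function(G, F, A, cfg = csfag_config()) {
  G <- check_feature_map(G, "G"); F <- check_feature_map(F, "F")
  dG <- dim(G)
  f <- cfg$subsample_factor
  # explicit bilinear resize (half-pixel), written independently
  naive_bilinear <- function(img, Ho, Wo) {
    Hi <- nrow(img); Wi <- ncol(img)
    out <- matrix(0, Ho, Wo)
    for (i in seq_len(Ho)) {
      for (j in seq_len(Wo)) {
        sy <- min(max((i - 0.5) * Hi / Ho - 0.5, 0), Hi - 1)
        sx <- min(max((j - 0.5) * Wi / Wo - 0.5, 0), Wi - 1)
        y0 <- min(floor(sy), Hi - 2); x0 <- min(floor(sx), Wi - 2)
        if (Hi == 1) y0 <- 0
        if (Wi == 1) x0 <- 0
        fy <- sy - y0; fx <- sx - x0
        y1 <- min(y0 + 1, Hi - 1); x1 <- min(x0 + 1, Wi - 1)
        out[i, j] <-
          img[y0 + 1, x0 + 1] * (1 - fy) * (1 - fx) +
          img[y1 + 1, x0 + 1] * fy * (1 - fx) +
          img[y0 + 1, x1 + 1] * (1 - fy) * fx +
          img[y1 + 1, x1 + 1] * fy * fx
      }
    }
    out
  }
  h <- dim(F)[1]; w <- dim(F)[2]; C <- dim(F)[3]
  r <- cfg$r; lam <- cfg$lambda
  O <- array(0, dim = dG)
  for (ch in seq_len(C)) {
    gl <- if (f == 1L) G[, , ch] else naive_bilinear(G[, , ch], h, w)
    fm <- F[, , ch]
    Wk <- matrix(0, h, w); Bk <- matrix(0, h, w)
    for (kx in seq_len(w)) {
      for (ky in seq_len(h)) {
        ys <- max(1, ky - r):min(h, ky + r)
        xs <- max(1, kx - r):min(w, kx + r)
        gv <- as.vector(gl[ys, xs]); fv <- as.vector(fm[ys, xs])
        av <- if (cfg$weighted) as.vector(A[ys, xs])^2 else rep(1, length(gv))
        # 2x2 normal equations of  sum_i a_i (W g_i + B - f_i)^2 + lam' W^2
        # with lam' = lam * sum(a), so that dividing through by the window
        # mass leaves lam unscaled next to the weighted variance (and the
        # uniform-weight case reproduces the printed closed form exactly).
        Sa <- sum(av); Sg <- sum(av * gv); Sf <- sum(av * fv)
        Sgg <- sum(av * gv * gv); Sgf <- sum(av * gv * fv)
        den <- (Sgg + lam * Sa) * Sa - Sg^2
        # match the fast path's variance clamp in the degenerate case
        varw <- Sgg / Sa - (Sg / Sa)^2
        if (varw < 0) {
          Wk[ky, kx] <- 0
          Bk[ky, kx] <- Sf / Sa
        } else {
          Wk[ky, kx] <- (Sa * Sgf - Sg * Sf) / den
          Bk[ky, kx] <- (Sf - Wk[ky, kx] * Sg) / Sa
        }
      }
    }
    Wl <- matrix(0, h, w); Bl <- matrix(0, h, w)
    for (ix in seq_len(w)) {
      for (iy in seq_len(h)) {
        ys <- max(1, iy - r):min(h, iy + r)
        xs <- max(1, ix - r):min(w, ix + r)
        Wl[iy, ix] <- mean(Wk[ys, xs])
        Bl[iy, ix] <- mean(Bk[ys, xs])
      }
    }
    Wh <- naive_bilinear(Wl, dG[1], dG[2])
    Bh <- naive_bilinear(Bl, dG[1], dG[2])
    O[, , ch] <- Wh * G[, , ch] + Bh
  }
  O
}
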