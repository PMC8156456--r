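# Deterministic generator of dermoscopy-like image/mask pairs: skin-tone
# background with a smooth illumination gradient, one star-convex lesion
# with a harmonically perturbed boundary, darker textured fill, and
# overlaid artifacts (hair curves, bright bubbles, optional ruler ticks).
# The mask is the exact rasterisation of the lesion region before any
# artifact is drawn, mirroring clinician ground truth which outlines the
# lesion, not occluders.
#
# All randomness comes from R's Mersenne-Twister stream seeded per sample;
# the caller's RNG state is saved and restored.

#' Synthetic generator parameters
#'
#' @param size image side in pixels (square).
#' @param area_range lesion area fraction range (amin, amax).
#' @param harmonics number of radial boundary harmonics (0 = perfect disc).
#' @param boundary_amp total relative amplitude of the radial perturbation.
#' @param hair_count,hair_thickness dark hair curves drawn over the image.
#' @param bubble_count bright circular bubble artifacts.
#' @param ruler_ticks draw a row of ruler tick marks.
#' @param noise_sd additive Gaussian pixel noise (8-bit units).
#' @return list of class `synthetic_params`.
#' @export
synthetic_params <- function(size = 128L,
                             area_range = c(0.08, 0.35),
                             harmonics = 4L,
                             boundary_amp = 0.18,
                             hair_count = 4L,
                             hair_thickness = 1L,
                             bubble_count = 3L,
                             ruler_ticks = FALSE,
                             noise_sd = 4) {
  stopifnot(length(area_range) == 2, area_range[1] > 0,
            area_range[2] > area_range[1], area_range[2] < 0.9,
            harmonics >= 0, hair_count >= 0, bubble_count >= 0,
            noise_sd >= 0)
  structure(list(size = as.integer(size), area_range = area_range,
                 harmonics = as.integer(harmonics),
                 boundary_amp = boundary_amp,
                 hair_count = as.integer(hair_count),
                 hair_thickness = as.integer(hair_thickness),
                 bubble_count = as.integer(bubble_count),
                 ruler_ticks = isTRUE(ruler_ticks),
                 noise_sd = noise_sd),
            class = "synthetic_params")
}

with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

clamp8 <- function(x) pmin(pmax(x, 0), 255)

# low-frequency scalar field for illumination / texture
smooth_field <- function(S, scale) {
  g <- matrix(rnorm(16 * 16), 16, 16)
  f <- bilinear_resize(array(g, dim = c(16L, 16L, 1L, 1L)), S, S)
  matrix(f, S, S) * scale
}

draw_disk <- function(canvas, cy, cx, rad, value, blend = 1) {
  S <- nrow(canvas)
  ys <- max(1, floor(cy - rad)):min(S, ceiling(cy + rad))
  xs <- max(1, floor(cx - rad)):min(S, ceiling(cx + rad))
  for (y in ys) for (x in xs)
    if ((y - cy)^2 + (x - cx)^2 <= rad^2)
      canvas[y, x] <- (1 - blend) * canvas[y, x] + blend * value
  canvas
}

#' Generate one synthetic dermoscopy sample
#'
#' @param params a [synthetic_params()] object.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return list of class `lesion_sample`: `image` (H, W, 3 integer, 0..255),
#'   `mask` (H, W, 0/1), `meta` (seed, area fraction, artifact inventory).
#' @export
generate_lesion_sample <- function(params = synthetic_params(), seed = 0L) {
  stopifnot(inherits(params, "synthetic_params"))
  with_preserved_rng(seed, {
    S <- params$size
    amin <- params$area_range[1]; amax <- params$area_range[2]
    # --- lesion geometry with rejection on the achieved area fraction ----
    mask <- NULL; af <- NA_real_
    for (attempt in seq_len(100)) {
      cy <- S * (0.5 + runif(1, -0.12, 0.12))
      cx <- S * (0.5 + runif(1, -0.12, 0.12))
      target_af <- runif(1, amin, amax)
      r0 <- sqrt(target_af * S * S / pi)
      K <- params$harmonics
      amp <- if (K > 0) runif(K, 0, params$boundary_amp / sqrt(seq_len(K)))
             else numeric(0)
      phase <- if (K > 0) runif(K, 0, 2 * pi) else numeric(0)
      yy <- matrix(seq_len(S) - cy, S, S)
      xx <- matrix(seq_len(S) - cx, S, S, byrow = TRUE)
      theta <- atan2(yy, xx)
      rad2 <- yy^2 + xx^2
      rb <- matrix(r0, S, S)
      if (K > 0) {
        pert <- matrix(0, S, S)
        for (k in seq_len(K))
          pert <- pert + amp[k] * sin(k * theta + phase[k])
        rb <- r0 * pmax(1 + pert, 0.2)
      }
      cand <- (rad2 <= rb^2) * 1
      af <- mean(cand)
      if (af >= amin && af <= amax) { mask <- cand; break }
    }
    if (is.null(mask))
      stop("could not reach the requested area fraction in 100 attempts")
    # --- background -------------------------------------------------------
    skin <- c(runif(1, 205, 235), runif(1, 155, 190), runif(1, 130, 165))
    illum <- smooth_field(S, scale = 10)
    img <- array(0, dim = c(S, S, 3))
    for (ch in 1:3) img[, , ch] <- skin[ch] + illum
    # --- lesion fill (darker, textured) ----------------------------------
    lesion_col <- c(runif(1, 95, 140), runif(1, 60, 95), runif(1, 40, 75))
    tex <- smooth_field(S, scale = 12)
    edge <- boxsum(array(mask, dim = c(S, S, 1L)), 2L)[, , 1] /
      boxsum(array(1, dim = c(S, S, 1L)), 2L)[, , 1]   # soft rim 0..1
    for (ch in 1:3) {
      base <- img[, , ch]
      les <- lesion_col[ch] + tex
      img[, , ch] <- base * (1 - edge) + les * edge
    }
    # --- artifacts (mask already frozen) ---------------------------------
    n_hair <- params$hair_count
    if (n_hair > 0) {
      dark <- runif(n_hair, 20, 60)
      for (hh in seq_len(n_hair)) {
        p0 <- runif(2, 1, S); p1 <- runif(2, 1, S); p2 <- runif(2, 1, S)
        ts <- seq(0, 1, length.out = 3 * S)
        py <- (1 - ts)^2 * p0[1] + 2 * ts * (1 - ts) * p1[1] + ts^2 * p2[1]
        px <- (1 - ts)^2 * p0[2] + 2 * ts * (1 - ts) * p1[2] + ts^2 * p2[2]
        th <- params$hair_thickness
        for (ch in 1:3) {
          sl <- img[, , ch]
          for (t in seq_along(ts)) {
            y <- round(py[t]); x <- round(px[t])
            ys <- max(1, y - th + 1):min(S, y + th - 1)
            xs <- max(1, x - th + 1):min(S, x + th - 1)
            sl[ys, xs] <- 0.35 * sl[ys, xs] + 0.65 * dark[hh]
          }
          img[, , ch] <- sl
        }
      }
    }
    n_bub <- params$bubble_count
    if (n_bub > 0) {
      for (bb in seq_len(n_bub)) {
        bc <- runif(2, S * 0.1, S * 0.9)
        br <- runif(1, 2, max(3, S / 40))
        bright <- runif(1, 230, 255)
        for (ch in 1:3)
          img[, , ch] <- draw_disk(img[, , ch], bc[1], bc[2], br, bright,
                                   blend = 0.7)
      }
    }
    if (params$ruler_ticks) {
      row <- round(S * 0.08)
      for (x in seq(5, S - 5, by = max(4, S %/% 32)))
        img[row:(row + max(2, S %/% 64)), x, ] <- 30
    }
    if (params$noise_sd > 0)
      img <- img + array(rnorm(length(img), sd = params$noise_sd),
                         dim = dim(img))
    img <- array(as.integer(round(clamp8(img))), dim = dim(img))
    structure(list(image = img, mask = mask,
                   meta = list(seed = seed, area_fraction = af,
                               hairs = n_hair, bubbles = n_bub)),
              class = "lesion_sample")
  })
}

#' Generate a dataset of synthetic samples
#'
#' Per-sample seeds are `seed + index - 1` for index 1..n.  When `out_dir`
#' is given, writes `img_%03d.png`, `mask_%03d.png` (mask as 0/255) and a
#' `manifest.csv`.
#'
#' @param n number of samples.
#' @param params a [synthetic_params()].
#' @param seed base seed.
#' @param out_dir optional output directory.
#' @return list with `samples` (list of `lesion_sample`) and `manifest`
#'   (data.frame).
#' @export
generate_dataset <- function(n, params = synthetic_params(), seed = 0L,
                             out_dir = NULL) {
  stopifnot(n >= 1)
  samples <- lapply(seq_len(n), function(i)
    generate_lesion_sample(params, seed + i - 1L))
  manifest <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(index = i, seed = seed + i - 1L,
               area_fraction = samples[[i]]$meta$area_fraction,
               image = sprintf("img_%03d.png", i),
               mask = sprintf("mask_%03d.png", i))
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_png(samples[[i]]$image, file.path(out_dir, manifest$image[i]))
      write_png(samples[[i]]$mask * 255L, file.path(out_dir, manifest$mask[i]))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}

#' Count 4-connected components of a binary mask
#'
#' Utility used to validate generated masks.
#'
#' @param mask binary matrix.
#' @return integer component count.
#' @export
mask_components <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  H <- nrow(m); W <- ncol(m)
  lab <- integer(H * W)
  stack <- integer(H * W)
  comp <- 0L
  for (start in which(m == 1L)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    sp <- 1L
    stack[1L] <- start
    lab[start] <- comp
    while (sp > 0L) {
      cur <- stack[sp]; sp <- sp - 1L
      y <- (cur - 1L) %% H + 1L
      x <- (cur - 1L) %/% H + 1L
      if (y > 1L) { i <- cur - 1L
        if (m[i] == 1L && lab[i] == 0L) { lab[i] <- comp; sp <- sp + 1L; stack[sp] <- i } }
      if (y < H) { i <- cur + 1L
        if (m[i] == 1L && lab[i] == 0L) { lab[i] <- comp; sp <- sp + 1L; stack[sp] <- i } }
      if (x > 1L) { i <- cur - H
        if (m[i] == 1L && lab[i] == 0L) { lab[i] <- comp; sp <- sp + 1L; stack[sp] <- i } }
      if (x < W) { i <- cur + H
        if (m[i] == 1L && lab[i] == 0L) { lab[i] <- comp; sp <- sp + 1L; stack[sp] <- i } }
    }
  }
  comp
}
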