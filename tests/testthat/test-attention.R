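test_that("channel attention matches hand-evaluated gates", {
  # zero input, identity MLP -> sigmoid(0) = 0.5
  x <- array(0, c(4, 4, 1))
  out <- channel_attention(x, rho = 1, params = identity_mlp_params(1))
  expect_equal(unname(out$state$weights), 0.5)
  expect_true(all(out$gated == 0))

  # channel 0 constant 1, channel 1 constant 0: logits [2, 0]
  x <- array(0, c(3, 5, 2)); x[, , 1] <- 1
  out <- channel_attention(x, rho = 1, params = identity_mlp_params(2))
  expect_equal(unname(out$state$logits), c(2, 0))
  expect_equal(unname(out$state$weights), c(1 / (1 + exp(-2)), 0.5),
               tolerance = 1e-12)
})

test_that("channel attention agrees with an independent scalar oracle", {
  set.seed(0)
  C <- 4; h <- 2
  x <- array(rnorm(C * 8 * 8), c(8, 8, C))
  params <- list(W1 = matrix(rnorm(h * C), h, C), b1 = rnorm(h),
                 W2 = matrix(rnorm(C * h), C, h), b2 = rnorm(C))
  out <- channel_attention(x, rho = 2, params = params)
  # independent re-computation: pool -> two matrix products -> sum -> sigmoid
  for (cc in seq_len(C)) {
    expect_equal(out$state$pooled_avg[cc], mean(x[, , cc]))
    expect_equal(out$state$pooled_max[cc], max(x[, , cc]))
  }
  mlp <- function(v) params$W2 %*% pmax(params$W1 %*% v + params$b1, 0) +
    params$b2
  logit <- mlp(out$state$pooled_avg) + mlp(out$state$pooled_max)
  w <- 1 / (1 + exp(-logit))
  expect_equal(unname(out$state$weights), as.numeric(w), tolerance = 1e-6)
  for (cc in seq_len(C))
    expect_equal(out$gated[, , cc], x[, , cc] * w[cc], tolerance = 1e-6)
})

test_that("spatial attention matches the pixel-loop oracle", {
  # zero input, zero bias -> 0.5 everywhere
  x <- array(0, c(5, 6, 3))
  out <- spatial_attention(x, 7)
  expect_true(all(abs(out$state$weights - 0.5) < 1e-12))

  # all channels equal -> pooled avg and max identical
  M <- matrix(rnorm(30), 5, 6)
  xe <- array(rep(M, 3), c(5, 6, 3))
  oute <- spatial_attention(xe, 3)
  expect_equal(oute$state$pooled_avg, M)
  expect_equal(oute$state$pooled_max, M)

  # random input, fixed conv weights, explicit per-pixel computation
  set.seed(1)
  x <- array(rnorm(3 * 6 * 6), c(6, 6, 3))
  k <- 3
  params <- list(W = array(rnorm(k * k * 2), c(k, k, 2, 1)), b = rnorm(1))
  out <- spatial_attention(x, k, params = params)
  favg <- apply(x, c(1, 2), mean)
  fmax <- apply(x, c(1, 2), max)
  pad <- (k - 1) / 2
  ap <- function(m) {
    p <- matrix(0, 6 + 2 * pad, 6 + 2 * pad)
    p[pad + 1:6, pad + 1:6] <- m
    p
  }
  pa <- ap(favg); pm <- ap(fmax)
  for (i in 1:6) for (j in 1:6) {
    s <- sum(pa[i:(i + k - 1), j:(j + k - 1)] * params$W[, , 1, 1]) +
      sum(pm[i:(i + k - 1), j:(j + k - 1)] * params$W[, , 2, 1]) + params$b
    expect_equal(out$state$weights[i, j], 1 / (1 + exp(-s)),
                 tolerance = 1e-6)
  }
  expect_error(spatial_attention(x, 4), "odd")
})

test_that("attention fusion composes the two attention stages", {
  # all-zero inputs with zero biases -> A = 0.5 everywhere
  Fm <- array(0, c(6, 6, 2)); Gl <- array(0, c(6, 6, 2))
  set.seed(2)
  params <- make_attention_params(2, rho = 1, ks = 7)
  for (br in c("caF", "caG")) {
    params$children[[br]]$params$b1[] <- 0
    params$children[[br]]$params$b2[] <- 0
  }
  for (br in c("saF", "saG")) params$children[[br]]$params$b[] <- 0
  params$children$fuse$params$b[] <- 0
  res <- csfag_attention_fusion(Fm, Gl, params)
  expect_true(all(abs(res$A - 0.5) < 1e-12))

  # strict range (0, 1) for arbitrary inputs
  set.seed(3)
  Fm <- array(rnorm(72) * 10, c(6, 6, 2))
  Gl <- array(rnorm(72) * 10, c(6, 6, 2))
  res <- csfag_attention_fusion(Fm, Gl, params)
  expect_true(min(res$A) > 0 && max(res$A) < 1)

  # composed oracle: channel attention then spatial attention per branch,
  # channel-mean, sum, relu, conv, sigmoid
  set.seed(2)
  Fm <- rand_array(c(8, 8, 2), 20); Gl <- rand_array(c(8, 8, 2), 21)
  set.seed(5)
  params <- make_attention_params(2, rho = 1, ks = 7)
  res <- csfag_attention_fusion(Fm, Gl, params)
  branch <- function(x, ca, sa) {
    pc <- list(W1 = ca$params$W1, b1 = ca$params$b1,
               W2 = ca$params$W2, b2 = ca$params$b2)
    g1 <- channel_attention(x, rho = 1, params = pc)$gated
    ps <- list(W = sa$params$W, b = sa$params$b)
    spatial_attention(g1, 7, params = ps)$gated
  }
  fF <- apply(branch(Fm, params$children$caF, params$children$saF),
              c(1, 2), mean)
  fG <- apply(branch(Gl, params$children$caG, params$children$saG),
              c(1, 2), mean)
  A1 <- pmax(fF + fG, 0)
  pad <- matrix(0, 10, 10); pad[2:9, 2:9] <- A1
  A2 <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    A2[i, j] <- sum(pad[i:(i + 2), j:(j + 2)] *
                      params$children$fuse$params$W[, , 1, 1]) +
      params$children$fuse$params$b
  expect_equal(res$A, 1 / (1 + exp(-A2)), tolerance = 1e-6)
  expect_error(csfag_attention_fusion(Fm, Gl[, , 1, drop = FALSE]), "shape")
})

test_that("gating contracts magnitudes and is channel-permutation-equivariant", {
  set.seed(6)
  for (trial in 1:5) {
    x <- array(rnorm(4 * 5 * 3) * 3, c(4, 5, 3))
    g1 <- channel_attention(x, rho = 1)$gated
    g2 <- spatial_attention(x, 7)$gated
    expect_true(all(abs(g1) <= abs(x) + 1e-12))
    expect_true(all(abs(g2) <= abs(x) + 1e-12))
  }
  # scalar-shared MLP weights: permuting channels permutes the gates
  C <- 4
  params <- list(W1 = 0.7 * diag(C), b1 = rep(0.1, C),
                 W2 = 1.3 * diag(C), b2 = rep(-0.2, C))
  x <- rand_array(c(6, 6, C), 7)
  perm <- c(3, 1, 4, 2)
  w_orig <- channel_attention(x, rho = 1, params = params)$state$weights
  w_perm <- channel_attention(x[, , perm], rho = 1,
                              params = params)$state$weights
  expect_equal(unname(w_perm), unname(w_orig[perm]), tolerance = 1e-12)
})

test_that("attention rejects degenerate inputs", {
  expect_error(channel_attention(array(NA_real_, c(2, 2, 1))), "non-finite")
  expect_error(channel_attention(matrix(numeric(0), 0, 0)), "empty|dim")
})
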