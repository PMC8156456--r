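test_that("guide subsampling is bilinear with half-pixel centers", {
  const <- array(3.7, c(8, 8, 2))
  expect_equal(subsample_guide(const, 2), array(3.7, c(4, 4, 2)))
  x <- rand_array(c(6, 6, 1), 1)
  expect_equal(subsample_guide(x, 1), x)
  ramp <- array(outer(1:4, 1:4, `+`), c(4, 4, 1))
  got <- subsample_guide(ramp, 2)
  expect_equal(got[, , 1], naive_bilinear(ramp[, , 1], 2, 2),
               tolerance = 1e-12)
  expect_error(subsample_guide(x, 7), "factor")
})

test_that("weighted box statistics match a brute-force window loop", {
  cfg <- csfag_config(r = 2)
  # constant inputs: mu = fbar = c, var = 0, cross = c^2, any weights
  Gl <- array(2.5, c(6, 6, 1)); Fm <- array(2.5, c(6, 6, 1))
  A <- matrix(runif(36, 0.2, 0.9), 6, 6)
  st <- weighted_box_stats(Gl, Fm, A, cfg)
  expect_equal(st$mu, array(2.5, c(6, 6, 1)))
  expect_equal(st$fbar, array(2.5, c(6, 6, 1)))
  expect_equal(max(abs(st$var)), 0, tolerance = 1e-12)
  expect_equal(st$cross, array(6.25, c(6, 6, 1)), tolerance = 1e-12)

  # A == 1 reproduces unweighted statistics exactly
  Gl <- rand_array(c(10, 10, 1), 30); Fm <- rand_array(c(10, 10, 1), 31)
  w1 <- weighted_box_stats(Gl, Fm, matrix(1, 10, 10), cfg)
  u <- weighted_box_stats(Gl, Fm, NULL,
                          csfag_config(r = 2, weighted = FALSE))
  expect_equal(w1$mu, u$mu, tolerance = 1e-12)
  expect_equal(w1$var, u$var, tolerance = 1e-12)
  expect_equal(w1$cross, u$cross, tolerance = 1e-12)

  # random weighted case against an explicit double loop
  set.seed(3)
  A <- matrix(runif(100, 0.05, 1), 10, 10)
  st <- weighted_box_stats(Gl, Fm, A, cfg)
  for (i in seq(1, 10, by = 3)) for (j in seq(1, 10, by = 3)) {
    ys <- max(1, i - 2):min(10, i + 2)
    xs <- max(1, j - 2):min(10, j + 2)
    a <- A[ys, xs]^2
    g <- Gl[ys, xs, 1]; f <- Fm[ys, xs, 1]
    expect_equal(st$mu[i, j, 1], sum(a * g) / sum(a), tolerance = 1e-10)
    expect_equal(st$fbar[i, j, 1], sum(a * f) / sum(a), tolerance = 1e-10)
    expect_equal(st$cross[i, j, 1], sum(a * g * f) / sum(a),
                 tolerance = 1e-10)
    expect_equal(st$var[i, j, 1],
                 max(sum(a * g * g) / sum(a) - (sum(a * g) / sum(a))^2, 0),
                 tolerance = 1e-10)
  }
})

test_that("coefficient solve is the weighted ridge closed form", {
  cfg <- csfag_config(r = 2, lambda = 0.001)
  # constant F: zero covariance -> Wk = 0, Bk = c
  Gl <- rand_array(c(8, 8, 1), 40)
  Fm <- array(1.7, c(8, 8, 1))
  A <- matrix(runif(64, 0.1, 1), 8, 8)
  co <- solve_coefficients(weighted_box_stats(Gl, Fm, A, cfg), cfg)
  expect_equal(max(abs(co$Wk)), 0, tolerance = 1e-10)
  expect_equal(co$Bk, Fm, tolerance = 1e-10)

  # self-guidance: Gl = F, lambda -> 0 gives Wk -> 1, Bk -> 0
  cfg0 <- csfag_config(r = 2, lambda = 1e-12)
  co <- solve_coefficients(weighted_box_stats(Gl, Gl, A, cfg0), cfg0)
  expect_equal(max(abs(co$Wk - 1)), 0, tolerance = 1e-6)
  expect_equal(max(abs(co$Bk)), 0, tolerance = 1e-6)

  # per-window 2x2 weighted normal equations oracle
  set.seed(4)
  Gl <- rand_array(c(10, 10, 1), 41); Fm <- rand_array(c(10, 10, 1), 42)
  A <- matrix(runif(100, 0.05, 1), 10, 10)
  cfg <- csfag_config(r = 2, lambda = 0.001)
  co <- solve_coefficients(weighted_box_stats(Gl, Fm, A, cfg), cfg)
  for (i in seq_len(10)) for (j in seq_len(10)) {
    ys <- max(1, i - 2):min(10, i + 2)
    xs <- max(1, j - 2):min(10, j + 2)
    a <- as.vector(A[ys, xs])^2
    g <- as.vector(Gl[ys, xs, 1]); f <- as.vector(Fm[ys, xs, 1])
    M <- rbind(c(sum(a * g * g) + cfg$lambda * sum(a), sum(a * g)),
               c(sum(a * g), sum(a)))
    rhs <- c(sum(a * g * f), sum(a * f))
    wb <- solve(M, rhs)
    expect_equal(co$Wk[i, j, 1], wb[1], tolerance = 1e-8)
    expect_equal(co$Bk[i, j, 1], wb[2], tolerance = 1e-8)
  }
})

test_that("coefficient aggregation is an exact clipped box mean", {
  cfg <- csfag_config(r = 1)
  w <- array(0.37, c(7, 7, 1))
  ag <- aggregate_coefficients(w, w, cfg)
  expect_equal(ag$Wl, w, tolerance = 1e-12)
  # interior impulse spreads as impulse / 9 over the 3x3 neighbourhood
  imp <- array(0, c(7, 7, 1)); imp[4, 4, 1] <- 1
  ag <- aggregate_coefficients(imp, imp, cfg)
  expect_equal(ag$Wl[3:5, 3:5, 1], matrix(1 / 9, 3, 3), tolerance = 1e-12)
  expect_equal(sum(ag$Wl[-(3:5), , 1]), 0)
  # random map against a double loop
  cfg <- csfag_config(r = 3)
  w <- rand_array(c(9, 11, 1), 50)
  ag <- aggregate_coefficients(w, w, cfg)
  for (i in c(1, 4, 9)) for (j in c(1, 6, 11)) {
    ys <- max(1, i - 3):min(9, i + 3)
    xs <- max(1, j - 3):min(11, j + 3)
    expect_equal(ag$Wl[i, j, 1], mean(w[ys, xs, 1]), tolerance = 1e-10)
  }
})

test_that("coefficient upsampling is bilinear", {
  w <- array(1.5, c(3, 3, 1))
  up <- upsample_coefficients(w, w, c(6, 6))
  expect_equal(up$Wh, array(1.5, c(6, 6, 1)), tolerance = 1e-12)
  w <- rand_array(c(4, 5, 1), 51)
  up <- upsample_coefficients(w, w, c(4, 5))
  expect_equal(up$Wh, w, tolerance = 1e-12)
  ramp <- array(outer(1:3, 1:3), c(3, 3, 1))
  up <- upsample_coefficients(ramp, ramp, c(6, 6))
  expect_equal(up$Wh[, , 1], naive_bilinear(ramp[, , 1], 6, 6),
               tolerance = 1e-12)
})

test_that("full filter: conservation, self-guidance, oracle equivalence", {
  cfg <- csfag_config(r = 2, lambda = 0.001, subsample_factor = 2)
  set.seed(5)
  G <- rand_array(c(16, 16, 1), 60)
  # constant F passes through exactly
  O <- csfag_forward(G, array(3, c(8, 8, 1)), cfg)
  expect_equal(max(abs(O - 3)), 0, tolerance = 1e-10)
  # self-guidance limit: A = 1, G = F, tiny lambda
  cfg1 <- csfag_config(r = 2, lambda = 1e-8, subsample_factor = 1)
  Gs <- rand_array(c(12, 12, 1), 61)
  O <- csagnet:::csfag_filter(Gs, Gs, matrix(1, 12, 12), cfg1)
  expect_lt(max(abs(O - Gs)), 1e-3)
  # random instance equals the brute-force oracle
  set.seed(5)
  ap <- make_attention_params(1, rho = 1, ks = 7)
  G <- rand_array(c(16, 16, 1), 62)
  Fm <- rand_array(c(8, 8, 1), 63)
  A <- csfag_attention_fusion(Fm, subsample_guide(G, 2), ap)$A
  fast <- csfag_forward(G, Fm, cfg, attention_params = ap)
  slow <- csfag_bruteforce_oracle(G, Fm, A, cfg)
  expect_lt(max(abs(fast - slow)), 1e-6)
})

test_that("fast path equals the oracle across random instances", {
  set.seed(77)
  for (trial in 1:12) {
    h <- sample(5:14, 1); w <- sample(5:14, 1)
    C <- sample(1:2, 1)
    f <- sample(1:2, 1)
    r <- sample(1:4, 1)
    cfg <- csfag_config(r = r, lambda = 10^runif(1, -4, -1),
                        subsample_factor = f)
    G <- array(rnorm(f * h * f * w * C), c(f * h, f * w, C))
    Fm <- array(rnorm(h * w * C), c(h, w, C))
    A <- matrix(runif(h * w, 0.05, 0.99), h, w)
    fast <- csagnet:::csfag_filter(G, Fm, A, cfg)
    slow <- csfag_bruteforce_oracle(G, Fm, A, cfg)
    expect_lt(max(abs(fast - slow)), 1e-6)
  }
})

test_that("lambda controls smoothing monotonically", {
  Gl <- rand_array(c(10, 10, 1), 70)
  Fm <- rand_array(c(10, 10, 1), 71)
  A <- matrix(runif(100, 0.2, 1), 10, 10)
  prev <- NULL
  for (lam in c(1e-4, 1e-2, 1, 100)) {
    cfg <- csfag_config(r = 2, lambda = lam)
    co <- solve_coefficients(weighted_box_stats(Gl, Fm, A, cfg), cfg)
    if (!is.null(prev)) expect_true(all(abs(co$Wk) <= prev + 1e-12))
    prev <- abs(co$Wk)
  }
  # lambda -> Inf: output approaches the window mean of F
  cfg <- csfag_config(r = 2, lambda = 1e12)
  O <- csagnet:::csfag_filter(Gl, Fm, A, cfg)
  st <- weighted_box_stats(Gl, Fm, A, cfg)
  mean_map <- aggregate_coefficients(st$fbar, st$fbar, cfg)$Wl
  expect_lt(max(abs(O - mean_map)), 1e-6)
})

test_that("output shape always matches the guide", {
  set.seed(80)
  for (trial in 1:5) {
    f <- sample(1:2, 1)
    h <- sample(4:9, 1); w <- sample(4:9, 1)
    cfg <- csfag_config(r = 2, subsample_factor = f)
    G <- array(rnorm(f * h * f * w * 2), c(f * h, f * w, 2))
    Fm <- array(rnorm(h * w * 2), c(h, w, 2))
    O <- csfag_forward(G, Fm, cfg)
    expect_identical(dim(O), dim(G))
  }
  expect_error(csfag_forward(array(0, c(8, 8, 1)), array(0, c(3, 3, 1)),
                             csfag_config(subsample_factor = 2)), "shape")
})
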