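tiny_cfg <- function(variant, size = 64L)
  net_config(variant, base_width = 4L, pyramid_widths = c(4L, 4L, 4L),
             growth = 4L, transition = 16L, csfag_widths = c(4L, 4L, 4L, 4L),
             rho = 4L, input_size = size)

test_that("forward pass honours the shape and probability contracts", {
  set.seed(1)
  m <- build_model(tiny_cfg("csag_dccnet", 256L))
  x <- array(runif(256 * 256 * 3), c(256, 256, 3, 1))
  out <- segnet_forward(m, x)
  expect_length(out$side_maps, 4)
  for (sm in out$side_maps) {
    expect_identical(dim(sm), c(256L, 256L, 2L, 1L))
    expect_lt(max(abs(sm[, , 1, ] + sm[, , 2, ] - 1)), 1e-5)
    expect_true(all(sm >= 0 & sm <= 1))
  }
  # final map is exactly the mean of the side maps
  ref <- (out$side_maps[[1]] + out$side_maps[[2]] + out$side_maps[[3]] +
            out$side_maps[[4]]) / 4
  expect_identical(out$final_map, ref)
  expect_identical(dim(out$mask), c(256L, 256L))
})

test_that("the unet variant has a single output and no side maps", {
  set.seed(2)
  m <- build_model(tiny_cfg("unet"))
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  out <- segnet_forward(m, x)
  expect_length(out$side_maps, 1)
  expect_identical(out$final_map, out$side_maps[[1]])
})

test_that("parameter counting is exact", {
  # closed form: a 3x3 conv, 3 -> 8 channels with bias
  set.seed(3)
  conv <- csagnet:::nn_conv(3L, 8L, bn = FALSE, act = "none")
  expect_identical(count_parameters(conv), 3L * 3L * 3L * 8L + 8L)
  # builder and closed-form config count agree across variants and widths
  for (v in csagnet:::VARIANTS) {
    cfg <- tiny_cfg(v)
    set.seed(4)
    expect_identical(count_parameters(build_model(cfg)),
                     as.integer(count_parameters_config(cfg)))
  }
})

test_that("multi-label loss matches hand arithmetic", {
  mk_bundle <- function(side_probs) list(side_maps = side_probs)
  S <- 2L
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  onehot <- array(0, c(S, S, 2, 1))
  onehot[, , 2, 1] <- y; onehot[, , 1, 1] <- 1 - y
  expect_lt(multi_label_loss(mk_bundle(list(onehot)), y), 1e-6)
  uniform <- array(0.5, c(S, S, 2, 1))
  expect_equal(multi_label_loss(mk_bundle(list(uniform)), y), log(2),
               tolerance = 1e-12)
  # two side maps with known probabilities
  p1 <- array(c(0.8, 0.3, 0.6, 0.1), c(S, S, 1, 1))
  probs1 <- array(0, c(S, S, 2, 1))
  probs1[, , 2, ] <- p1; probs1[, , 1, ] <- 1 - p1
  p2 <- array(c(0.55, 0.9, 0.2, 0.7), c(S, S, 1, 1))
  probs2 <- array(0, c(S, S, 2, 1))
  probs2[, , 2, ] <- p2; probs2[, , 1, ] <- 1 - p2
  ce <- function(p) -mean(y * log(p) + (1 - y) * log(1 - p))
  ref <- (ce(p1[, , 1, 1]) + ce(p2[, , 1, 1])) / 2
  expect_equal(multi_label_loss(mk_bundle(list(probs1, probs2)), y), ref,
               tolerance = 1e-9)
  expect_error(multi_label_loss(mk_bundle(list(uniform)),
                                matrix(2, 2, 2)), "binary")
})

test_that("one optimiser step decreases the loss on a fixed batch", {
  set.seed(5)
  m <- build_model(tiny_cfg("csag_dccnet"))
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  samp <- generate_lesion_sample(synthetic_params(size = 64L), seed = 3)
  y <- array(rep(samp$mask, 2), c(64, 64, 2))
  losses <- c()
  for (step in 1:2) {
    csagnet:::zero_grads(m)
    out <- segnet_forward(m, x, training = TRUE)
    lg <- csagnet:::multi_label_loss_grad(out, y)
    losses <- c(losses, lg$loss)
    csagnet:::segnet_backward(m, lg$grads)
    csagnet:::sgd_step(m, 1e-3)
  }
  out <- segnet_forward(m, x, training = TRUE)
  final <- csagnet:::multi_label_loss_grad(out, y)$loss
  expect_lt(final, losses[1])
})

test_that("network gradients agree with directional finite differences", {
  set.seed(6)
  m <- build_model(tiny_cfg("csag_dccnet", 32L))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  y <- (matrix(runif(32 * 32), 32, 32) > 0.6) * 1
  loss <- function() {
    out <- segnet_forward(m, x, training = TRUE)
    csagnet:::multi_label_loss_grad(out, y)$loss
  }
  csagnet:::zero_grads(m)
  out <- segnet_forward(m, x, training = TRUE)
  lg <- csagnet:::multi_label_loss_grad(out, y)
  csagnet:::segnet_backward(m, lg$grads)
  mods <- csagnet:::module_list(m)
  set.seed(7)
  dirs <- list(); gdot <- 0
  for (i in seq_along(mods)) {
    dirs[[i]] <- list()
    for (nm in names(mods[[i]]$params)) {
      p <- mods[[i]]$params[[nm]]
      d <- if (is.null(dim(p))) rnorm(length(p))
           else array(rnorm(length(p)), dim = dim(p))
      dirs[[i]][[nm]] <- d
      gdot <- gdot + sum(mods[[i]]$grads[[nm]] * d)
    }
  }
  eps <- 1e-7
  vals <- c()
  for (s in c(1, -1)) {
    for (i in seq_along(mods)) for (nm in names(mods[[i]]$params))
      mods[[i]]$params[[nm]] <- mods[[i]]$params[[nm]] +
        s * eps * dirs[[i]][[nm]]
    vals <- c(vals, loss())
    for (i in seq_along(mods)) for (nm in names(mods[[i]]$params))
      mods[[i]]$params[[nm]] <- mods[[i]]$params[[nm]] -
        s * eps * dirs[[i]][[nm]]
  }
  fd <- (vals[1] - vals[2]) / (2 * eps)
  expect_lt(abs(fd - gdot) / abs(gdot), 0.05)
})
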