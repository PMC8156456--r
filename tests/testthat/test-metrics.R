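test_that("confusion counts are exact pixel tallies", {
  gt <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(unclass(confusion(gt, gt))[c("FP", "FN")],
               list(FP = 0, FN = 0))
  inv <- confusion(1 - gt, gt)
  expect_equal(inv$TP + inv$TN, 0)
  # 4x4 toy with a hand-counted overlap
  gt <- matrix(0, 4, 4); gt[1:2, 1:4] <- 1          # 8 lesion pixels
  pr <- matrix(0, 4, 4); pr[1:2, 1:3] <- 1; pr[3, 1:2] <- 1
  cc <- confusion(pr, gt)
  expect_equal(unclass(cc)[c("TP", "FP", "FN", "TN")],
               list(TP = 6, FP = 2, FN = 2, TN = 6))
  expect_error(confusion(pr, gt[1:3, ]), "shape")
  expect_error(confusion(pr * 2, gt), "binary")
})

test_that("the six metrics evaluate the closed forms", {
  perfect <- compute_metrics(list(TP = 10, FP = 0, TN = 20, FN = 0))
  expect_equal(unlist(unclass(perfect)), c(SEN = 1, SPE = 1, ACC = 1,
                                           JAC = 1, DIC = 1, MCC = 1))
  m <- compute_metrics(list(TP = 6, FP = 2, FN = 2, TN = 90))
  expect_equal(m$SEN, 0.75)
  expect_equal(m$SPE, 90 / 92)
  expect_equal(m$ACC, 0.96)
  expect_equal(m$JAC, 0.6)
  expect_equal(m$DIC, 0.75)
  expect_equal(m$MCC, 536 / 736)
  # degenerate conventions
  allneg <- compute_metrics(list(TP = 0, FP = 0, FN = 0, TN = 16))
  expect_equal(allneg$SPE, 1)
  expect_equal(allneg$ACC, 1)
  expect_equal(allneg$SEN, 1)
  expect_equal(allneg$JAC, 1)
  expect_equal(allneg$DIC, 1)
  expect_equal(allneg$MCC, 0)
})

test_that("Dice-Jaccard identity holds on random count vectors", {
  set.seed(1)
  for (i in 1:1000) {
    cc <- as.list(rmultinom(1, 400, runif(4, 0.05, 1))[, 1])
    names(cc) <- c("TP", "FP", "TN", "FN")
    m <- compute_metrics(cc)
    if (cc$TP + cc$FP + cc$FN > 0)
      expect_equal(m$DIC, 2 * m$JAC / (1 + m$JAC), tolerance = 1e-12)
    expect_gte(m$MCC, -1); expect_lte(m$MCC, 1)
    expect_true(m$ACC >= min(m$SEN, m$SPE) - 1e-12 &&
                  m$ACC <= max(m$SEN, m$SPE) + 1e-12)
  }
})

test_that("per-image evaluation averages images, not pixels", {
  g1 <- matrix(c(1, 0, 0, 0), 2, 2)
  # image 1 perfect, image 2 half-right on the lesion
  p2 <- matrix(c(1, 1, 0, 0), 2, 2)
  df <- evaluate_per_image(list(g1, p2), list(g1, g1), percent = FALSE)
  expect_equal(nrow(df), 3)
  expect_equal(df$DIC[3], mean(df$DIC[1:2]))
  one <- evaluate_per_image(list(g1), list(g1), percent = FALSE)
  expect_equal(one[1, -1], one[2, -1], ignore_attr = TRUE)
  expect_error(evaluate_per_image(list(g1), list(g1, g1)), "length")
  # independent re-computation on synthetic pairs with a dilated predictor
  dil <- function(m) {
    d <- csagnet:::boxsum(array(m, c(dim(m), 1L)), 1L)[, , 1]
    (d > 0) * 1
  }
  gts <- lapply(0:2, function(s)
    generate_lesion_sample(synthetic_params(size = 32L), s)$mask)
  preds <- lapply(gts, dil)
  df <- evaluate_per_image(preds, gts, percent = FALSE)
  for (i in 1:3) {
    tp <- sum(preds[[i]] == 1 & gts[[i]] == 1)
    fp <- sum(preds[[i]] == 1 & gts[[i]] == 0)
    fn <- sum(preds[[i]] == 0 & gts[[i]] == 1)
    expect_equal(df$DIC[i], 2 * tp / (2 * tp + fp + fn), tolerance = 1e-12)
    expect_equal(df$SEN[i], tp / (tp + fn), tolerance = 1e-12)
  }
})

test_that("pooled-pixel metrics differ from the per-image mean", {
  g1 <- matrix(0, 4, 4); g1[1, 1] <- 1
  p1 <- matrix(0, 4, 4)                      # misses the 1-pixel lesion
  g2 <- matrix(1, 4, 4); g2[4, 4] <- 0
  p2 <- g2                                   # perfect on the big lesion
  df <- evaluate_per_image(list(p1, p2), list(g1, g2), percent = FALSE,
                           pooled = TRUE)
  expect_identical(rownames(df), c("1", "2", "mean", "pooled"))
  # pooled Dice from summed counts: TP=15, FN=1, FP=0
  expect_equal(df["pooled", "DIC"], 2 * 15 / (2 * 15 + 1), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(df["pooled", "DIC"], df["mean", "DIC"])))
})
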