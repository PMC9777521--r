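test_that("confusion counts match a per-pixel loop and sum to the total", {
  gt <- randomMask(c(8L, 8L), seed = 4)
  pred <- randomMask(c(8L, 8L), seed = 5)
  cc <- confusionCounts(pred, gt, 1L)
  expect_identical(cc, oracleConfusion(pred, gt, 1L))
  expect_identical(sum(cc), 64L)
  expect_identical(unname(confusionCounts(gt, gt, 1L)[c("FP", "FN")]),
                   c(0L, 0L))
  inv <- 1L - gt
  cc2 <- confusionCounts(inv, gt, 1L)
  expect_identical(unname(cc2[c("TP", "TN")]), c(0L, 0L))
  expect_error(confusionCounts(matrix(0L, 2, 2), matrix(0L, 3, 3)), "differ")
})

test_that("perfect and degenerate predictions score as expected", {
  gt <- matrix(0L, 16, 16); gt[4:8, 4:8] <- 1L
  s <- segmentationScores(gt, gt)
  expect_equal(s@globalAccuracy, 1)
  expect_equal(s@meanIoU, 1)
  expect_equal(s@weightedIoU, 1)
  expect_equal(s@meanBFScore, 1)
  allBg <- matrix(0L, 16, 16)
  s0 <- segmentationScores(allBg, gt)
  expect_equal(s0@globalAccuracy, mean(gt == 0L))
  expect_equal(s0@perClass$iou[s0@perClass$class == 1L], 0)
})

test_that("all scores equal the brute-force oracle on random fixtures", {
  for (seed in c(11, 12)) {
    gt <- matrix(0L, 16, 16)
    set.seed(seed)
    gt[sample(256, 60)] <- 1L
    pred <- matrix(0L, 16, 16)
    pred[sample(256, 70)] <- 1L
    tol <- 2
    s <- segmentationScores(pred, gt, bfTolerance = tol)
    ious <- recs <- bfs <- numeric(2)
    freqs <- numeric(2)
    for (k in 0:1) {
      cc <- oracleConfusion(pred, gt, k)
      ious[k + 1] <- cc["TP"] / (cc["TP"] + cc["FP"] + cc["FN"])
      recs[k + 1] <- cc["TP"] / (cc["TP"] + cc["FN"])
      bfs[k + 1] <- oracleBF(pred, gt, k, tol)
      freqs[k + 1] <- (cc["TP"] + cc["FN"]) / 256
    }
    expect_equal(s@globalAccuracy, mean(pred == gt))
    expect_equal(s@meanAccuracy, mean(recs))
    expect_equal(s@meanIoU, mean(ious))
    expect_equal(s@weightedIoU, sum(freqs * ious))
    expect_equal(s@meanBFScore, mean(bfs))
    expect_gte(s@weightedIoU, min(ious))
    expect_lte(s@weightedIoU, max(ious))
  }
})

test_that("F1 and dice coincide on binary masks", {
  for (seed in 21:23) {
    gt <- randomMask(c(12L, 12L), seed = seed)
    pred <- randomMask(c(12L, 12L), seed = seed + 100)
    s <- segmentationScores(pred, gt)
    expect_equal(s@perClass$f1, s@perClass$dice)
    cc <- confusionCounts(pred, gt, 1L)
    expect_equal(s@perClass$dice[s@perClass$class == 1L],
                 unname(2 * cc["TP"] / (2 * cc["TP"] + cc["FP"] + cc["FN"])))
  }
})

test_that("overlay colours encode the confusion categories exactly", {
  gt <- matrix(rep(c(0L, 1L), 32), 8, 8)             # checkerboard-ish
  pred <- randomMask(c(8L, 8L), seed = 31)
  ov <- renderOverlay(pred, gt)
  cyan <- ov[, , 1] == 0 & ov[, , 2] == 1 & ov[, , 3] == 1
  magenta <- ov[, , 1] == 1 & ov[, , 2] == 0 & ov[, , 3] == 1
  yellow <- ov[, , 1] == 1 & ov[, , 2] == 1 & ov[, , 3] == 0
  black <- ov[, , 1] == 0 & ov[, , 2] == 0 & ov[, , 3] == 0
  expect_true(all(cyan | magenta | yellow | black))  # exactly four colours
  cc <- confusionCounts(pred, gt, 1L)
  expect_identical(c(sum(cyan), sum(magenta), sum(yellow), sum(black)),
                   as.integer(cc[c("TP", "FP", "FN", "TN")]))
  expect_true(all(renderOverlay(gt, gt)[, , 2][gt == 1] == 1))
  expect_error(renderOverlay(gt + 1L, gt), "binary")
})

test_that("per-volume dice summaries match hand-assembled statistics", {
  gt <- array(0L, c(6, 6, 4)); gt[2:4, 2:4, 2:3] <- 1L
  ident <- perVolumeDice(list(gt, gt), list(gt, gt))
  expect_true(all(ident$dice == 1))
  expect_equal(ident$summary$q75 - ident$summary$q25, c(0, 0))
  # single volume: median equals that volume's dice
  pred <- gt; pred[2, 2, 2] <- 0L
  one <- perVolumeDice(list(pred), list(gt))
  cc <- confusionCounts(pred, gt, 1L)
  expect_equal(one$summary$median[one$summary$class == 1L],
               unname(2 * cc["TP"] / (2 * cc["TP"] + cc["FP"] + cc["FN"])))
  # five synthetic pairs vs individually assembled dice values
  set.seed(41)
  preds <- gts <- vector("list", 5)
  for (i in 1:5) {
    g <- array(sample(0:1, 27, replace = TRUE, prob = c(0.8, 0.2)), c(3, 3, 3))
    p <- array(sample(0:1, 27, replace = TRUE, prob = c(0.8, 0.2)), c(3, 3, 3))
    gts[[i]] <- g; preds[[i]] <- p
  }
  res <- perVolumeDice(preds, gts)
  byHand <- vapply(1:5, function(i) {
    cc <- oracleConfusion(preds[[i]], gts[[i]], 1L)
    unname(2 * cc["TP"] / (2 * cc["TP"] + cc["FP"] + cc["FN"]))
  }, 1)
  expect_equal(unname(res$dice[, "class1"]), byHand)
  q <- quantile(byHand, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(res$summary$median[res$summary$class == 1L], q[2])
  iqr <- q[3] - q[1]
  expect_equal(res$summary$whiskerLow[res$summary$class == 1L],
               min(byHand[byHand >= q[1] - 1.5 * iqr]))
})
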