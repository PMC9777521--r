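test_that("dice weights are inverse squared class areas", {
  G <- cbind(c(1, 1, 1, 1, 0), c(0, 0, 0, 0, 1))
  expect_identical(diceWeights(G), c(0.25, 1))
  # absent class contributes nothing
  G0 <- cbind(c(1, 1), c(0, 0))
  expect_identical(diceWeights(G0), c(0.5, 0))
  # brute-force count oracle on a random one-hot matrix
  set.seed(3)
  lab <- sample(0:2, 50, replace = TRUE)
  G <- matrix(0, 50, 3); G[cbind(1:50, lab + 1)] <- 1
  counts <- vapply(0:2, function(k) sum(lab == k), 1L)
  expect_equal(diceWeights(G), ifelse(counts > 0, 1 / counts, 0))
})

test_that("generalized dice loss identities hold", {
  G <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_lt(generalizedDiceLoss(G, G), 1e-4)                 # perfect overlap
  Pdisj <- cbind(c(0, 0, 1, 1), c(1, 1, 0, 0))               # fully disjoint
  expect_gt(generalizedDiceLoss(Pdisj, G), 1 - 1e-4)
  expect_error(generalizedDiceLoss(G[, 1, drop = FALSE], G), "identical")
})

test_that("loss equals the hand-evaluated value on the 4-element fixture", {
  # two classes, four elements; P rows sum to 1
  P <- cbind(c(0.8, 0.6, 0.3, 0.1), c(0.2, 0.4, 0.7, 0.9))
  G <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  # by hand: w = (1/2, 1/2)
  #   num = w1*(0.8+0.6) + w2*(0.7+0.9)           = 0.7 + 0.8        = 1.5
  #   den = w1*(0.64+0.36+0.09+0.01 + 2)
  #       + w2*(0.04+0.16+0.49+0.81 + 2)          = 1.55 + 1.75      = 3.3
  #   L   = 1 - 2*1.5/3.3                         = 1 - 10/11
  expect_equal(generalizedDiceLoss(P, G), 1 - 2 * 1.5 / 3.3,
               tolerance = 1e-4)
  # the smoothing constant moves the value by less than 1e-4
  exact <- 1 - 2 * 1.5 / 3.3
  expect_lt(abs(generalizedDiceLoss(P, G) - exact), 1e-4)
})

test_that("duplicating every element leaves the loss unchanged", {
  set.seed(8)
  lab <- sample(0:1, 30, replace = TRUE)
  G <- matrix(0, 30, 2); G[cbind(1:30, lab + 1)] <- 1
  p <- runif(30)
  P <- cbind(p, 1 - p)
  expect_equal(generalizedDiceLoss(rbind(P, P), rbind(G, G)),
               generalizedDiceLoss(P, G), tolerance = 1e-6)
})

test_that("loss decreases as P moves toward G along a convex path", {
  set.seed(12)
  lab <- sample(0:1, 40, replace = TRUE)
  G <- matrix(0, 40, 2); G[cbind(1:40, lab + 1)] <- 1
  P0 <- matrix(0.5, 40, 2)
  losses <- vapply(seq(0, 1, by = 0.25), function(t)
    generalizedDiceLoss((1 - t) * P0 + t * G, G), 1)
  expect_true(all(diff(losses) < 0))
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(5)
  lab <- sample(0:1, 12, replace = TRUE)
  G <- matrix(0, 12, 2); G[cbind(1:12, lab + 1)] <- 1
  p <- runif(12, 0.1, 0.9)
  P <- cbind(p, 1 - p)
  r <- aidunet:::gdlWithGrad(P, G)
  eps <- 1e-6
  for (ix in sample(length(P), 6)) {
    Pp <- P; Pp[ix] <- Pp[ix] + eps
    Pm <- P; Pm[ix] <- Pm[ix] - eps
    num <- (generalizedDiceLoss(Pp, G) - generalizedDiceLoss(Pm, G)) / (2 * eps)
    expect_equal(r$dP[ix], num, tolerance = 1e-4)
  }
})

test_that("array inputs flatten batch and spatial axes into elements", {
  set.seed(2)
  Parr <- array(runif(4 * 4 * 2), c(4, 4, 2))
  Parr[, , 2] <- 1 - Parr[, , 1]
  Garr <- array(0, c(4, 4, 2))
  fg <- matrix(runif(16) > 0.7, 4, 4)
  Garr[, , 1][!fg] <- 1; Garr[, , 2][fg] <- 1
  expect_identical(generalizedDiceLoss(Parr, Garr),
                   generalizedDiceLoss(matrix(Parr, 16, 2),
                                       matrix(Garr, 16, 2)))
})
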