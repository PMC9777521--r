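forwardNetPublic <- function(m, X, B) aidunet:::forwardNet(m@net, X, B, FALSE)

test_that("forward pass preserves spatial extent and emits probabilities", {
  cfg <- tinyArch(K = 2, d = 1, nf = 2, inChannels = 3, extent = c(16, 16))
  m <- buildModel(planLayers(cfg), seed = 7)
  X <- matrix(0, prod(cfg@inputExtent), 3)          # zero-filled patch
  P <- forwardNetPublic(m, X, 1)
  expect_identical(dim(P), c(as.integer(prod(cfg@inputExtent)), 2L))
  expect_true(all(P >= 0))
  expect_equal(max(abs(rowSums(P) - 1)), 0, tolerance = 1e-12)
})

test_that("3D shape propagation: 64x64x32 x 4 channels in, same extent out", {
  cfg <- archConfig(K = 2, d = 1, nf = 2, dims = 3, inChannels = 4,
                    numClasses = 2, inputExtent = c(64, 64, 32), dropout = 0)
  m <- buildModel(planLayers(cfg), seed = 1)
  X <- matrix(0, prod(cfg@inputExtent), 4)
  P <- forwardNetPublic(m, X, 1)
  expect_identical(nrow(P), as.integer(prod(c(64L, 64L, 32L))))
  expect_identical(ncol(P), 2L)
})

test_that("concatenation preserves per-channel variance; addition doubles it", {
  set.seed(42)
  n <- 1e4
  A <- matrix(rnorm(n * 2, sd = c(1, 2)), n, 2, byrow = TRUE)
  B <- matrix(rnorm(n * 2, sd = c(1, 2)), n, 2, byrow = TRUE)
  vin <- c(apply(A, 2, var), apply(B, 2, var))
  CC <- aidunet:::concatForward(A, B)
  expect_equal(apply(CC, 2, var), vin, tolerance = 0.05)
  AD <- aidunet:::addForward(A, B)                  # independent inputs
  expect_equal(apply(AD, 2, var), vin[1:2] + vin[3:4], tolerance = 0.05)
})

test_that("planned counts equal materialized trainable scalars across the matrix", {
  for (K in 1:3) for (d in 0:K) for (dims in 2:3) {
    cfg <- tinyArch(K = K, d = d, nf = 3, dims = dims, inChannels = 2)
    g <- planLayers(cfg)
    m <- buildModel(g, seed = 1)
    expect_identical(countParameters(g), countParameters(m),
                     info = sprintf("K=%d d=%d dims=%d", K, d, dims))
  }
})

smokeFixture <- function(n = 8, extent = c(16, 16), seed = 5) {
  makeDataset(fixtureSpec(count = n, extent = extent, seed = seed))$samples
}

test_that("zero learning rate leaves the weights untouched", {
  cfg <- tinyArch(K = 1, d = 1, nf = 2, inChannels = 3, extent = c(16, 16))
  m <- buildModel(planLayers(cfg), seed = 3)
  before <- lapply(m@net$nodes, function(nd) nd$params)
  trainModel(m, smokeFixture(), trainConfig(epochs = 1, batchSize = 4,
             learningRate = 0, seed = 1, validationFraction = 0.25))
  after <- lapply(m@net$nodes, function(nd) nd$params)
  expect_identical(before, after)
})

test_that("identical seeds reproduce identical training histories", {
  cfg <- tinyArch(K = 1, d = 1, nf = 2, inChannels = 3, extent = c(16, 16),
                  dropout = 0.2)
  ds <- smokeFixture()
  tc <- trainConfig(epochs = 2, batchSize = 4, seed = 9,
                    validationFraction = 0.25)
  h1 <- trainModel(buildModel(planLayers(cfg), seed = 5), ds, tc)$history
  h2 <- trainModel(buildModel(planLayers(cfg), seed = 5), ds, tc)$history
  expect_identical(h1, h2)
})

test_that("loss decreases over the first epochs at a small learning rate", {
  cfg <- tinyArch(K = 1, d = 1, nf = 2, inChannels = 3, extent = c(16, 16))
  m <- buildModel(planLayers(cfg), seed = 11)
  h <- trainModel(m, smokeFixture(), trainConfig(epochs = 3, batchSize = 4,
       learningRate = 1e-3, seed = 2, validationFraction = 0.25))$history
  expect_true(all(diff(h$trainLoss) <= 0))
})

test_that("a background-pinned model predicts an all-background mask", {
  cfg <- tinyArch(K = 1, d = 0, nf = 2, inChannels = 1, extent = c(16, 16))
  m <- backgroundModel(cfg)
  img <- array(runif(24 * 40), c(24, 40, 1))
  plan <- planPatches(c(24, 40), c(16, 16),
                      mask = {
                        mk <- matrix(0L, 24, 40); mk[10:12, 20:22] <- 1L; mk
                      })
  pred <- predictMask(m, img, plan)
  expect_identical(dim(pred), c(24L, 40L))
  expect_true(all(pred == 0L))
})

test_that("overlapping patch scores are resolved by averaging", {
  cfg <- tinyArch(K = 1, d = 0, nf = 2, inChannels = 1, extent = c(16, 16))
  m <- buildModel(planLayers(cfg), seed = 8)
  # foreground spread so wide that no patch holds it -> overlapping tiling
  mask <- matrix(0L, 16, 24); mask[1, 1] <- 1L; mask[16, 24] <- 1L
  plan <- planPatches(c(16, 24), c(16, 16), mask)
  expect_true(plan@overlap)
  img <- array(runif(16 * 24), c(16, 24, 1))
  pred <- predictMask(m, img, plan)
  # independent restitching: average the per-patch probabilities by hand
  pairs <- extractPatches(img, NULL, plan)
  probs <- aidunet:::predictProbBatch(m, lapply(pairs, `[[`, "image"))
  scores <- array(0, c(16, 24, 2)); counts <- matrix(0, 16, 24)
  for (k in seq_along(probs)) {
    o <- plan@patchOrigins[k, ]
    ys <- (o[1] + 1):(o[1] + 16); xs <- (o[2] + 1):(o[2] + 16)
    scores[ys, xs, ] <- scores[ys, xs, ] + probs[[k]]
    counts[ys, xs] <- counts[ys, xs] + 1
  }
  manual <- apply(scores / as.vector(counts), c(1, 2), which.max) - 1L
  expect_identical(pred, array(as.integer(manual), c(16L, 24L)))
})

test_that("checkpoint save/load round-trips weights and predictions", {
  cfg <- tinyArch(K = 1, d = 1, nf = 2, inChannels = 1, extent = c(16, 16))
  m <- buildModel(planLayers(cfg), seed = 4)
  tmp <- tempfile(fileext = ".rds")
  saveModel(m, tmp)
  m2 <- loadModel(tmp)
  X <- matrix(runif(256), 256, 1)
  expect_identical(forwardNetPublic(m, X, 1), forwardNetPublic(m2, X, 1))
})
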