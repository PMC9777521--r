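test_that("closed-form complexity orders match the geometric sums", {
  expect_identical(complexityUNet(5), 63)
  expect_identical(complexityUNet(0), 1)
  # brute-force summation oracle
  expect_identical(complexityUNet(3), sum(2^(0:3)))
  cs <- complexityAid(3, 2)
  expect_identical(cs@order, 29)
  expect_identical(cs@s1 + cs@s2, cs@order)
  # term-by-term sums of both series for K = 2, d = 1
  cs21 <- complexityAid(2, 1)
  expect_identical(cs21@s1, sum(2^(0:2)))
  expect_identical(cs21@s2, sum(2^(1:2)))
  expect_identical(cs21@order, sum(2^(0:2)) + sum(2^(1:2)))
  # degenerate sub-path
  expect_lte(complexityAid(1, 0)@order, complexityUNet(1) + 2^1)
  expect_error(complexityUNet(-1), "non-negative")
  expect_error(complexityAid(2, 3), "maximum")
})

test_that("splitting depth into a sub-path always lowers the order", {
  for (K in 1:10) {
    for (d in 0:K) {
      ord <- complexityAid(K, d)@order
      if (d >= 1) expect_lt(ord, complexityUNet(K + d))
    }
    # degenerate consistency of the d = 0 case
    expect_lte(complexityAid(K, 0)@order, complexityUNet(K) + 2^K)
  }
})

test_that("planned level sequence follows the nested-excursion schedule", {
  g <- planLayers(archConfig(K = 2, d = 1, inputExtent = c(64, 64)))
  expect_identical(g@blocks$level[g@blocks$role != "head"],
                   c(0L, 1L, 2L, 1L, 2L, 1L, 0L))
  expect_identical(g@blocks$role[g@blocks$role != "head"],
                   c("contract", "contract", "contract", "sub-expand",
                     "sub-contract", "expand", "expand"))
  # filter ladder: 2^(nf + level)
  cfg <- g@config
  expect_identical(g@blocks$filters[g@blocks$role != "head"],
                   2L^(cfg@nf + g@blocks$level[g@blocks$role != "head"]))
})

test_that("d = 0 degenerates to a conventional U-Net", {
  g <- planLayers(archConfig(K = 3, d = 0, inputExtent = c(64, 64)))
  expect_false(any(grepl("sub", g@blocks$role)))
  expect_identical(g@blocks$level[g@blocks$role != "head"],
                   c(0:3, 2:0))
})

test_that("equal total depth K + d gives equal block counts", {
  g31 <- planLayers(archConfig(K = 3, d = 1, inputExtent = c(64, 64)))
  g22 <- planLayers(archConfig(K = 2, d = 2, inputExtent = c(64, 64)))
  expect_identical(nrow(g31@blocks), nrow(g22@blocks))
})

test_that("plan rejects extents that break the pooling ladder", {
  expect_error(archConfig(K = 3, d = 0, inputExtent = c(64, 60)),
               "axis 2")
})

test_that("parameter counts equal an independent per-block recount", {
  for (K in 1:3) for (d in 0:K) for (dims in 2:3) {
    cfg <- tinyArch(K = K, d = d, nf = 3L, dims = dims, inChannels = 3L)
    g <- planLayers(cfg)
    expect_identical(countParameters(g), recountParameters(g),
                     info = sprintf("K=%d d=%d dims=%d", K, d, dims))
  }
  # the trivial anchor: one 1x1 conv, 1 -> 1 channel, with bias
  h <- planLayers(tinyArch())@layers
  headConv <- h[h$kind == "conv" & h$kernel == 1L, ]
  expect_identical(headConv$params,
                   headConv$inCh * headConv$outCh + headConv$outCh)
})

test_that("counts grow strictly with width and depth, and nesting saves", {
  ext <- c(64, 64)
  pOf <- function(K, d, nf) countParameters(planLayers(
    archConfig(K = K, d = d, nf = nf, inputExtent = ext)))
  expect_lt(pOf(2, 1, 3), pOf(2, 1, 4))
  expect_lt(pOf(2, 1, 4), pOf(2, 1, 5))
  expect_lt(pOf(1, 1, 4), pOf(2, 1, 4))
  expect_lt(pOf(2, 1, 4), pOf(3, 1, 4))
  # for equal total depth, the nested split always undercuts the U-Net
  for (N in 2:4) for (K in ceiling(N / 2):(N - 1)) {
    expect_lt(pOf(K, N - K, 4), pOf(N, 0, 4))
  }
})

test_that("layer-graph JSON round-trips the architecture", {
  g <- planLayers(archConfig(K = 2, d = 2, inputExtent = c(64, 64)))
  js <- jsonlite::fromJSON(layerGraphJSON(g))
  expect_identical(js$arch$K, 2L)
  expect_equal(js$learnable_parameters, countParameters(g))
  expect_identical(nrow(js$blocks), nrow(g@blocks))
  d <- describeArchitecture(K = 2, d = 2, inputExtent = c(64, 64))
  expect_identical(d$parameters, countParameters(g))
})
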