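#' Worst-case complexity order of a conventional U-Net
#'
#' The per-level cost of a U-Net grows geometrically with ratio 2 as the
#' filter count doubles at each contracting step, so the worst-case order of
#' a network with `depth` down-sampling steps is the geometric sum
#' `sum(2^n, n = 0..depth) = 2^(depth+1) - 1`.
#'
#' @param depth contracting-path depth, a non-negative integer.
#' @return The integer order `2^(depth+1) - 1`.
#' @examples
#' complexityUNet(5) # 63
#' @seealso [complexityAid()]
#' @export
complexityUNet <- function(depth) {
  if (length(depth) != 1L || is.na(depth) || depth < 0 || depth != floor(depth))
    stop("'depth' must be a single non-negative integer", call. = FALSE)
  2^(depth + 1) - 1
}

#' Worst-case complexity order of an AID-U-Net
#'
#' An AID-U-Net splits a total depth `N = K + d` into a direct path of depth
#' `K` and a nested sub-path of depth `d`. Its worst-case order is the sum
#' of two geometric series: `s1 = 2^(K+1) - 1` over levels `0..K` of the
#' direct path and `s2 = 2^(K+1) - 2^(K-d)` over levels `K..K-d` of the
#' sub-path, i.e. `order = 2^(K+2) - 2^(K-d) - 1`. For `d >= 1` this is
#' strictly below `complexityUNet(K + d)` — the architectural argument for
#' nesting sub-paths instead of deepening the direct path.
#'
#' @param K direct-path depth, a positive integer.
#' @param d sub-path depth, a non-negative integer no larger than `K`.
#' @return A [ComplexitySummary-class] with slots `s1`, `s2` and `order`.
#' @examples
#' complexityAid(3, 2) # order 29; compare complexityUNet(5) = 63
#' @export
complexityAid <- function(K, d) {
  if (length(K) != 1L || is.na(K) || K < 1 || K != floor(K))
    stop("'K' must be a single positive integer", call. = FALSE)
  if (length(d) != 1L || is.na(d) || d < 0 || d != floor(d))
    stop("'d' must be a single non-negative integer", call. = FALSE)
  if (d > K)
    stop(sprintf(
      "sub-path depth d = %d exceeds its admissible maximum K = %d", d, K),
      call. = FALSE)
  s1 <- 2^(K + 1) - 1
  s2 <- 2^(K + 1) - 2^(K - d)
  new("ComplexitySummary", K = as.integer(K), d = as.integer(d),
      s1 = s1, s2 = s2, order = s1 + s2)
}

# Block schedule of an AID-U-Net: direct contract 0..K, sub-expand down to
# K-d, sub-contract back to K, direct expand up to 0. d = 0 yields a plain
# U-Net of depth K.
blockSchedule <- function(K, d) {
  roles <- c(rep("contract", K + 1L),
             if (d > 0L) rep(c("sub-expand", "sub-contract"), each = d),
             rep("expand", K))
  levels <- c(0L:K,
              if (d > 0L) c(seq(K - 1L, K - d), seq(K - d + 1L, K)),
              seq(K - 1L, 0L))
  data.frame(id = seq_along(roles), role = roles, level = levels)
}

#' Plan the layer graph of an AID-U-Net
#'
#' Expands an [ArchConfig-class] into the full block and primitive-layer
#' structure of the network, without materializing any weights.
#'
#' The recipe per block:
#' * contracting (and sub-contracting) block at level `l`:
#'   3x3 convolution to `2^(nf+l)` filters, batch normalization, ReLU,
#'   second 3x3 convolution, ReLU, dropout; consecutive contracting blocks
#'   are connected by 2x2 max-pooling.
#' * expansive (and sub-expansive) block at level `l`: 2x2 stride-2
#'   up-convolution halving the channels, concatenation with the direct
#'   contracting block at the same level, 3x3 convolution back to
#'   `2^(nf+l)` filters, batch normalization, ReLU, second 3x3 convolution,
#'   ReLU, dropout.
#' * head: 1x1 convolution to `numClasses` followed by a per-pixel softmax.
#'
#' All convolutions use "same" padding. The sub-expansive path ascends from
#' the bottleneck, the sub-contracting path descends back to level `K`, and
#' the direct expansive path up-convolves from the sub-contracting output.
#'
#' @param config a valid [ArchConfig-class].
#' @return A [LayerGraph-class].
#' @examples
#' g <- planLayers(archConfig(K = 2, d = 1, inputExtent = c(64, 64)))
#' g@blocks$level # 0 1 2 1 2 1 0
#' @export
planLayers <- function(config) {
  validObject(config)
  K <- config@K; d <- config@d; nf <- config@nf; nd <- config@dims
  div <- 2L^K
  bad <- which(config@inputExtent %% div != 0L)
  if (length(bad))
    stop(sprintf("input extent axis %d (%d) is not divisible by 2^K = %d",
                 bad[1], config@inputExtent[bad[1]], div), call. = FALSE)
  kk <- 3L^nd; kk2 <- 2L^nd
  filt <- function(l) 2L^(nf + l)
  blocks <- blockSchedule(K, d)
  blocks$filters <- filt(blocks$level)

  layers <- list(); conns <- list()
  addLayer <- function(block, kind, kernel, inCh, outCh, params)
    layers[[length(layers) + 1L]] <<- data.frame(
      block = block, kind = kind, kernel = kernel,
      inCh = inCh, outCh = outCh, params = params)
  addConn <- function(from, to, type)
    conns[[length(conns) + 1L]] <<- data.frame(from = from, to = to, type = type)

  contractBlock <- function(id, cin, f) {
    addLayer(id, "conv", 3L, cin, f, kk * cin * f + f)
    addLayer(id, "bn", 0L, f, f, 2L * f)
    addLayer(id, "relu", 0L, f, f, 0L)
    addLayer(id, "conv", 3L, f, f, kk * f * f + f)
    addLayer(id, "relu", 0L, f, f, 0L)
    addLayer(id, "dropout", 0L, f, f, 0L)
  }
  expandBlock <- function(id, csrc, f, skipCh) {
    addLayer(id, "upconv", 2L, csrc, f, kk2 * csrc * f + f)
    addLayer(id, "concat", 0L, f + skipCh, f + skipCh, 0L)
    addLayer(id, "conv", 3L, f + skipCh, f, kk * (f + skipCh) * f + f)
    addLayer(id, "bn", 0L, f, f, 2L * f)
    addLayer(id, "relu", 0L, f, f, 0L)
    addLayer(id, "conv", 3L, f, f, kk * f * f + f)
    addLayer(id, "relu", 0L, f, f, 0L)
    addLayer(id, "dropout", 0L, f, f, 0L)
  }

  inCh <- integer(nrow(blocks))
  # direct contracting path (block ids 1..K+1, levels 0..K)
  for (i in 1:(K + 1L)) {
    l <- blocks$level[i]
    cin <- if (l == 0L) config@inChannels else filt(l - 1L)
    inCh[i] <- cin
    contractBlock(i, cin, filt(l))
    if (i > 1L) addConn(i - 1L, i, "pool")
  }
  prev <- K + 1L
  if (d > 0L) {
    for (j in 1:d) {                       # sub-expansive excursion
      i <- K + 1L + j; l <- blocks$level[i]
      csrc <- blocks$filters[prev]
      inCh[i] <- csrc
      expandBlock(i, csrc, filt(l), skipCh = filt(l))
      addConn(prev, i, "upconv")
      addConn(l + 1L, i, "concat-skip")    # contract block at same level
      prev <- i
    }
    for (j in 1:d) {                       # sub-contracting return
      i <- K + 1L + d + j; l <- blocks$level[i]
      cin <- blocks$filters[prev]
      inCh[i] <- cin
      contractBlock(i, cin, filt(l))
      addConn(prev, i, "pool")
      prev <- i
    }
  }
  for (j in 1:K) {                         # direct expansive path
    i <- K + 1L + 2L * d + j; l <- blocks$level[i]
    csrc <- blocks$filters[prev]
    inCh[i] <- csrc
    expandBlock(i, csrc, filt(l), skipCh = filt(l))
    addConn(prev, i, "upconv")
    addConn(l + 1L, i, "concat-skip")
    prev <- i
  }
  headId <- nrow(blocks) + 1L
  blocks <- rbind(blocks, data.frame(id = headId, role = "head", level = 0L,
                                     filters = config@numClasses))
  inCh <- c(inCh, filt(0L))
  addLayer(headId, "conv", 1L, filt(0L), config@numClasses,
           filt(0L) * config@numClasses + config@numClasses)
  addLayer(headId, "softmax", 0L, config@numClasses, config@numClasses, 0L)
  addConn(prev, headId, "feed")

  blocks$inChannels <- inCh
  layers <- do.call(rbind, layers)
  conns <- do.call(rbind, conns)
  # pools between blocks count as primitive layers too
  npool <- sum(conns$type == "pool")
  new("LayerGraph", config = config, blocks = blocks, layers = layers,
      connections = conns,
      totalLayerCount = as.integer(nrow(layers) + npool))
}

#' Count learnable parameters
#'
#' Counts every trainable scalar of a planned graph or materialized model:
#' convolution and up-convolution kernels with their biases, and the
#' batch-normalization scale/shift pair per channel. Non-trainable running
#' statistics are excluded. For a [LayerGraph-class] the count is analytic;
#' for an [AidUNetModel-class] the actual weight arrays are tallied, and the
#' two always agree.
#'
#' @param object a [LayerGraph-class] or [AidUNetModel-class].
#' @return Integer-valued parameter count.
#' @examples
#' countParameters(planLayers(archConfig(K = 2, d = 2, inputExtent = c(64, 64))))
#' @export
setGeneric("countParameters", function(object) standardGeneric("countParameters"))

#' @rdname countParameters
setMethod("countParameters", "LayerGraph", function(object)
  sum(object@layers$params))

#' Serialize a LayerGraph to JSON
#'
#' Emits the block list (roles, levels, filters), the primitive-layer table,
#' the connections and summary counts as a JSON string, so architectures can
#' be printed, stored and diffed.
#'
#' @param graph a [LayerGraph-class].
#' @param pretty pretty-print the JSON.
#' @return A JSON string (class `json`).
#' @export
layerGraphJSON <- function(graph, pretty = TRUE) {
  cfg <- graph@config
  jsonlite::toJSON(list(
    arch = list(K = cfg@K, d = cfg@d, nf = cfg@nf, dims = cfg@dims,
                in_channels = cfg@inChannels, num_classes = cfg@numClasses,
                input_extent = cfg@inputExtent, dropout = cfg@dropout),
    blocks = graph@blocks,
    layers = graph@layers,
    connections = graph@connections,
    total_layer_count = graph@totalLayerCount,
    learnable_parameters = countParameters(graph)
  ), auto_unbox = TRUE, pretty = pretty, digits = NA)
}

#' Describe an architecture
#'
#' Convenience wrapper used by the command-line `describe` subcommand:
#' plans the graph and returns its JSON together with the parameter count
#' and the closed-form complexity order.
#'
#' @inheritParams archConfig
#' @param ... further arguments passed to [archConfig()].
#' @return A list with elements `config`, `graph`, `json`, `parameters`,
#'   `parametersPretty` and `complexity`.
#' @export
describeArchitecture <- function(K, d = 0L, nf = 5L, dims = 2L, ...) {
  cfg <- archConfig(K = K, d = d, nf = nf, dims = dims, ...)
  g <- planLayers(cfg)
  n <- countParameters(g)
  list(config = cfg, graph = g, json = layerGraphJSON(g), parameters = n,
       parametersPretty = formatParamCount(n),
       complexity = if (d > 0L) complexityAid(K, d) else
         structure(complexityUNet(K), names = "order"))
}
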