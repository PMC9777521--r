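# shared fixture builders; everything is generated in code under fixed seeds

tinyArch <- function(K = 1L, d = 0L, nf = 2L, dims = 2L, inChannels = 1L,
                     numClasses = 2L, extent = NULL, dropout = 0) {
  if (is.null(extent))
    extent <- if (dims == 2L) c(8L, 8L) else c(8L, 8L, 8L)
  archConfig(K = K, d = d, nf = nf, dims = dims, inChannels = inChannels,
             numClasses = numClasses, inputExtent = extent, dropout = dropout)
}

# deterministic random label mask
randomMask <- function(extent, nclass = 2L, seed = 1L) {
  set.seed(seed)
  array(sample(0:(nclass - 1L), prod(extent), replace = TRUE), extent)
}

# a model whose head is pinned so every pixel scores class 0 overwhelmingly
backgroundModel <- function(cfg) {
  m <- buildModel(planLayers(cfg), seed = 1)
  head <- m@net$nodes[[m@net$outputNode - 1L]]
  stopifnot(head$type == "conv", head$meta$kernel == 1L)
  head$params$W[] <- 0
  head$params$b <- c(50, rep(0, cfg@numClasses - 1L))
  m
}

# independent parameter recount: walks the planned blocks (not the layer
# table) and re-derives every kernel/channel product from first principles
recountParameters <- function(graph) {
  cfg <- graph@config
  kk <- 3^cfg@dims; kk2 <- 2^cfg@dims
  filters <- function(l) 2^(cfg@nf + l)
  total <- 0
  blocks <- graph@blocks
  for (i in seq_len(nrow(blocks))) {
    role <- blocks$role[i]; f <- blocks$filters[i]; cin <- blocks$inChannels[i]
    if (role %in% c("contract", "sub-contract")) {
      total <- total + (kk * cin * f + f) + 2 * f + (kk * f * f + f)
    } else if (role %in% c("expand", "sub-expand")) {
      skip <- filters(blocks$level[i])
      total <- total + (kk2 * cin * f + f) +              # up-convolution
        (kk * (f + skip) * f + f) + 2 * f + (kk * f * f + f)
    } else {                                              # head: 1x1 conv
      total <- total + cin * f + f
    }
  }
  total
}
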