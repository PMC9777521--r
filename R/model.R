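# Materialization of a LayerGraph as an executable computation graph.
# Nodes live in a single environment so that training updates in place.

newNode <- function(id, type, inputs, sp, cout, meta = list()) {
  nd <- new.env(parent = emptyenv())
  nd$id <- id; nd$type <- type; nd$inputs <- inputs
  nd$sp <- sp; nd$cout <- cout; nd$meta <- meta
  nd$params <- list(); nd$grads <- list(); nd$opt <- list()
  nd
}

#' Build a runnable model from a planned layer graph
#'
#' Materializes every primitive layer of a [LayerGraph-class] with
#' variance-scaled (fan-in) weight initialization under `seed`. The forward
#' pass maps a batch of patches of the configured input extent and channel
#' count to per-pixel class probabilities of identical spatial extent
#' (softmax over the class axis); concatenations merge along the channel
#' axis. Works for both 2D and 3D graphs.
#'
#' @param graph a [LayerGraph-class] from [planLayers()].
#' @param seed integer seed for weight initialization.
#' @return An [AidUNetModel-class].
#' @examples
#' cfg <- archConfig(K = 1, d = 0, nf = 2, inChannels = 1, inputExtent = c(8, 8))
#' m <- buildModel(planLayers(cfg), seed = 1)
#' countParameters(m)
#' @export
buildModel <- function(graph, seed = 42L) {
  cfg <- graph@config
  nd <- cfg@dims
  kk <- 3L^nd; kk2 <- 2L^nd
  set.seed(as.integer(seed))
  net <- new.env(parent = emptyenv())
  net$nodes <- list()
  net$geom <- new.env(parent = emptyenv())
  net$t <- 0L
  addNode <- function(type, inputs, sp, cout, meta = list()) {
    id <- length(net$nodes) + 1L
    net$nodes[[id]] <- newNode(id, type, inputs, sp, cout, meta)
    id
  }
  initConv <- function(id, kern, cin, cout) {
    nodep <- net$nodes[[id]]
    kkk <- kern^nd
    sd <- sqrt(2 / (kkk * cin))
    nodep$params <- list(
      W = array(stats::rnorm(kkk * cin * cout, sd = sd), c(kkk, cin, cout)),
      b = numeric(cout))
  }
  initUpconv <- function(id, cin, cout) {
    nodep <- net$nodes[[id]]
    sd <- sqrt(2 / cin)   # each output position sees one kernel tap
    nodep$params <- list(
      W = array(stats::rnorm(kk2 * cin * cout, sd = sd), c(kk2, cin, cout)),
      b = numeric(cout))
  }
  initBn <- function(id, c) {
    nodep <- net$nodes[[id]]
    nodep$params <- list(gamma = rep(1, c), beta = numeric(c))
    nodep$state <- new.env(parent = emptyenv())
    nodep$state$runMean <- numeric(c)
    nodep$state$runVar <- rep(1, c)
  }
  spAt <- function(level) cfg@inputExtent %/% (2L^level)

  blocks <- graph@blocks
  conns <- graph@connections
  blockOut <- integer(nrow(blocks))

  convChain <- function(src, sp, cin, f, p) {
    c1 <- addNode("conv", src, sp, f, list(kernel = 3L, cin = cin))
    initConv(c1, 3L, cin, f)
    b1 <- addNode("bn", c1, sp, f); initBn(b1, f)
    r1 <- addNode("relu", b1, sp, f)
    c2 <- addNode("conv", r1, sp, f, list(kernel = 3L, cin = f))
    initConv(c2, 3L, f, f)
    r2 <- addNode("relu", c2, sp, f)
    addNode("dropout", r2, sp, f, list(p = p))
  }

  for (i in seq_len(nrow(blocks))) {
    role <- blocks$role[i]; level <- blocks$level[i]
    f <- blocks$filters[i]; sp <- spAt(level)
    inc <- conns[conns$to == i, , drop = FALSE]
    if (role %in% c("contract", "sub-contract")) {
      if (nrow(inc) == 0L) {
        src <- addNode("input", integer(), sp, cfg@inChannels)
        cin <- cfg@inChannels
      } else {
        fromBlk <- inc$from[inc$type == "pool"]
        src <- addNode("pool", blockOut[fromBlk], sp, blocks$filters[fromBlk])
        cin <- blocks$filters[fromBlk]
      }
      blockOut[i] <- convChain(src, sp, cin, f, cfg@dropout)
    } else if (role %in% c("expand", "sub-expand")) {
      fromBlk <- inc$from[inc$type == "upconv"]
      skipBlk <- inc$from[inc$type == "concat-skip"]
      csrc <- blocks$filters[fromBlk]
      up <- addNode("upconv", blockOut[fromBlk], sp, f, list(cin = csrc))
      initUpconv(up, csrc, f)
      skipF <- blocks$filters[skipBlk]
      cc <- addNode("concat", c(up, blockOut[skipBlk]), sp, f + skipF,
                    list(nA = f))
      blockOut[i] <- convChain(cc, sp, f + skipF, f, cfg@dropout)
    } else {                                       # head
      fromBlk <- inc$from[inc$type == "feed"]
      cin <- blocks$filters[fromBlk]
      h <- addNode("conv", blockOut[fromBlk], sp, cfg@numClasses,
                   list(kernel = 1L, cin = cin))
      initConv(h, 1L, cin, cfg@numClasses)
      blockOut[i] <- addNode("softmax", h, sp, cfg@numClasses)
    }
  }
  net$outputNode <- blockOut[nrow(blocks)]
  new("AidUNetModel", graph = graph, net = net, initSeed = as.integer(seed))
}

geomGet <- function(net, kind, sp, B) {
  key <- paste(kind, paste(sp, collapse = "x"), B, sep = "|")
  g <- net$geom[[key]]
  if (is.null(g)) {
    g <- switch(kind,
      conv = convIndexSet(sp, B),
      pool = poolIndexSet(sp, B),
      upconv = upconvIndexSet(sp, B))
    net$geom[[key]] <- g
  }
  g
}

# Forward pass. X: (B * prod(inputExtent)) x inChannels matrix.
forwardNet <- function(net, X, B, train = FALSE) {
  for (node in net$nodes) {
    ins <- lapply(node$inputs, function(j) net$nodes[[j]]$out)
    node$out <- switch(node$type,
      input = X,
      conv = {
        ix <- if (node$meta$kernel == 1L) NULL else
          geomGet(net, "conv", net$nodes[[node$inputs]]$sp, B)
        r <- convForward(ins[[1]], node$params$W, node$params$b, ix)
        node$cache <- list(G = r$G, ix = ix)
        r$Y
      },
      bn = {
        r <- bnForward(ins[[1]], node$params$gamma, node$params$beta,
                       node$state, train)
        node$cache <- r$cache
        r$Y
      },
      relu = {
        node$cache <- list(X = ins[[1]])
        reluForward(ins[[1]])
      },
      dropout = {
        r <- dropoutForward(ins[[1]], node$meta$p, train)
        node$cache <- list(mask = r$mask)
        r$Y
      },
      pool = {
        px <- geomGet(net, "pool", net$nodes[[node$inputs]]$sp, B)
        r <- poolForward(ins[[1]], px)
        node$cache <- list(amax = r$amax, px = px)
        r$Y
      },
      upconv = {
        ux <- geomGet(net, "upconv", net$nodes[[node$inputs]]$sp, B)
        ux$B <- B
        node$cache <- list(X = ins[[1]], ux = ux)
        upconvForward(ins[[1]], node$params$W, node$params$b, ux)
      },
      concat = concatForward(ins[[1]], ins[[2]]),
      softmax = {
        Y <- softmaxForward(ins[[1]])
        node$cache <- list(Y = Y)
        Y
      },
      stop("unknown node type ", node$type))
  }
  net$nodes[[net$outputNode]]$out
}

# Backward pass from dOut (gradient w.r.t. the softmax output).
backwardNet <- function(net, dOut) {
  n <- length(net$nodes)
  for (node in net$nodes) node$dout <- NULL
  net$nodes[[net$outputNode]]$dout <- dOut
  accum <- function(j, g) {
    tgt <- net$nodes[[j]]
    tgt$dout <- if (is.null(tgt$dout)) g else tgt$dout + g
  }
  for (i in rev(seq_len(n))) {
    node <- net$nodes[[i]]
    dY <- node$dout
    if (is.null(dY)) next
    switch(node$type,
      input = NULL,
      conv = {
        r <- convBackward(dY, node$cache$G, node$params$W, node$cache$ix)
        node$grads <- list(W = r$dW, b = r$db)
        accum(node$inputs, r$dX)
      },
      bn = {
        r <- bnBackward(dY, node$params$gamma, node$cache)
        node$grads <- list(gamma = r$dgamma, beta = r$dbeta)
        accum(node$inputs, r$dX)
      },
      relu = accum(node$inputs, reluBackward(dY, node$cache$X)),
      dropout = {
        g <- if (is.null(node$cache$mask)) dY else dY * node$cache$mask
        accum(node$inputs, g)
      },
      pool = {
        accum(node$inputs,
              poolBackward(dY, node$cache$amax, node$cache$px, node$cout))
      },
      upconv = {
        r <- upconvBackward(dY, node$cache$X, node$params$W, node$cache$ux)
        node$grads <- list(W = r$dW, b = r$db)
        accum(node$inputs, r$dX)
      },
      concat = {
        r <- concatBackward(dY, node$meta$nA)
        accum(node$inputs[1], r$dA)
        accum(node$inputs[2], r$dB)
      },
      softmax = accum(node$inputs, softmaxBackward(dY, node$cache$Y)))
    node$dout <- NULL
  }
  invisible(NULL)
}

optimStep <- function(net, lr, optimizer = "adam",
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  net$t <- net$t + 1L
  t <- net$t
  for (node in net$nodes) {
    if (!length(node$params)) next
    for (nm in names(node$params)) {
      g <- node$grads[[nm]]
      if (is.null(g)) next
      if (optimizer == "sgd") {
        node$params[[nm]] <- node$params[[nm]] - lr * g
      } else {
        st <- node$opt[[nm]]
        if (is.null(st)) st <- list(m = g * 0, v = g * 0)
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g * g
        node$opt[[nm]] <- st
        mhat <- st$m / (1 - beta1^t)
        vhat <- st$v / (1 - beta2^t)
        node$params[[nm]] <- node$params[[nm]] -
          lr * mhat / (sqrt(vhat) + eps)
      }
    }
    node$grads <- list()
  }
  invisible(NULL)
}

clearCaches <- function(net) {
  for (node in net$nodes) {
    node$cache <- NULL
    node$out <- NULL
    node$dout <- NULL
  }
  invisible(NULL)
}

#' @rdname countParameters
setMethod("countParameters", "AidUNetModel", function(object) {
  sum(vapply(object@net$nodes,
             function(nd) sum(lengths(nd$params)), numeric(1)))
})

# stack a list of (sp..., C) arrays into the engine's batch matrix
stackBatch <- function(images, nsp, C) {
  do.call(rbind, lapply(images, function(im) matrix(as.vector(im), nsp, C)))
}

oneHot <- function(labels, M) {
  G <- matrix(0, length(labels), M)
  G[cbind(seq_along(labels), labels + 1L)] <- 1
  G
}

# run one batch of patch arrays through the model, eval mode
predictProbBatch <- function(model, patches) {
  cfg <- model@graph@config
  nsp <- prod(cfg@inputExtent)
  X <- stackBatch(patches, nsp, cfg@inChannels)
  P <- forwardNet(model@net, X, length(patches), train = FALSE)
  lapply(seq_along(patches), function(b)
    array(P[((b - 1) * nsp + 1):(b * nsp), ],
          c(cfg@inputExtent, cfg@numClasses)))
}

#' Predict a label mask for a full image
#'
#' Runs every patch of `plan` through the model in inference mode, averages
#' the per-class probabilities where patches overlap, takes the per-pixel
#' argmax and places the result back at the crop offset of the original
#' image geometry. Pixels outside the crop window are labelled background
#' (0).
#'
#' @param model an [AidUNetModel-class].
#' @param image numeric array of shape `(extent..., channels)`.
#' @param plan a [PatchPlan-class] produced for this image's extent, with
#'   patch extent equal to the model's input extent.
#' @param batchSize number of patches evaluated per forward pass.
#' @return An integer array of the original spatial extent with class
#'   labels `0 .. numClasses - 1`.
#' @export
predictMask <- function(model, image, plan, batchSize = 8L) {
  cfg <- model@graph@config
  nd <- cfg@dims
  ext <- spatialExtent(image, nd)
  if (!identical(as.integer(ext), plan@imageExtent))
    stop("image extent does not match the patch plan", call. = FALSE)
  if (!identical(as.integer(plan@patchExtent), cfg@inputExtent))
    stop("patch extent of the plan does not match the model input",
         call. = FALSE)
  pairs <- extractPatches(image, NULL, plan)
  M <- cfg@numClasses
  scores <- array(0, c(plan@cropExtent, M))
  counts <- array(0, plan@cropExtent)
  norig <- nrow(plan@patchOrigins)
  for (start in seq(1L, norig, by = batchSize)) {
    take <- start:min(start + batchSize - 1L, norig)
    probs <- predictProbBatch(model, lapply(pairs[take], `[[`, "image"))
    for (k in seq_along(take)) {
      o <- plan@patchOrigins[take[k], ]
      idx <- lapply(seq_len(nd), function(a) (o[a] + 1):(o[a] + plan@patchExtent[a]))
      sArgs <- c(list(scores), idx, list(seq_len(M)))
      cArgs <- c(list(counts), idx)
      sl <- do.call(`[`, sArgs)
      do.call(`[<-`, c(list(scores), idx, list(seq_len(M)),
                       list(sl + probs[[k]]))) -> scores
      do.call(`[<-`, c(list(counts), idx,
                       list(do.call(`[`, cArgs) + 1))) -> counts
    }
  }
  clearCaches(model@net)
  avg <- scores / as.vector(counts)               # recycles over classes
  flat <- matrix(avg, prod(plan@cropExtent), M)
  lab <- max.col(flat, ties.method = "first") - 1L
  cropMask <- array(as.integer(lab), plan@cropExtent)
  out <- array(0L, plan@imageExtent)
  idx <- lapply(seq_len(nd), function(a)
    (plan@cropOffset[a] + 1):(plan@cropOffset[a] + plan@cropExtent[a]))
  do.call(`[<-`, c(list(out), idx, list(cropMask)))
}

spatialExtent <- function(arr, nd) {
  d <- dim(arr)
  if (is.null(d)) stop("expected an array", call. = FALSE)
  if (length(d) == nd) d else d[seq_len(nd)]
}
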