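# Layer engine for the tiny trainable classifiers.
#
# A model is an ordered list of layer descriptors. Every descriptor carries
# `type`, `name`, optionally `paramShapes` (named list of array dims) and -
# when the model is materialized - `params` (the arrays themselves).
# Composite layers (naive inception block, dense block) keep their member
# convolutions under `sublayers`. Activation layout is (H, W, C, N); dense
# activations are (features, N) matrices.
#
# Paper-scale backbones are represented with the same descriptors but
# without materialized weights: they exist for architecture accounting and
# shape propagation, and error out of the numeric paths.

samePad <- function(k) (k - 1L) %/% 2L

mkConv <- function(name, kh, kw, cin, cout, stride = 1L, pad = samePad(kh),
                   bias = TRUE) {
  shapes <- list(W = c(kh, kw, cin, cout))
  if (bias) shapes$b <- cout
  list(type = "conv", name = name, kh = kh, kw = kw, cin = cin, cout = cout,
       stride = as.integer(stride), pad = as.integer(pad), bias = bias,
       paramShapes = shapes)
}

mkBatchNorm <- function(name, channels, scale = TRUE) {
  shapes <- list(beta = channels, movingMean = channels, movingVar = channels)
  if (scale) shapes <- c(list(gamma = channels), shapes)
  list(type = "batchnorm", name = name, channels = channels, scale = scale,
       paramShapes = shapes)
}

mkDense <- function(name, nin, nout) {
  list(type = "dense", name = name, nin = nin, nout = nout,
       paramShapes = list(W = c(nin, nout), b = nout))
}

mkPool <- function(name, kind = "max", k = 2L, stride = k, pad = 0L) {
  list(type = paste0(kind, "pool"), name = name, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
}

mkLayer <- function(type, name, ...) c(list(type = type, name = name), list(...))

# ---- weight materialization -------------------------------------------------

initParamArray <- function(pname, shape, fanIn) {
  if (pname %in% c("b", "beta", "movingMean")) {
    array(0, dim = shape)
  } else if (pname == "movingVar") {
    array(1, dim = shape)
  } else if (pname == "gamma") {
    array(1, dim = shape)
  } else {
    # He initialization for conv/dense kernels
    array(rnorm(prod(shape), sd = sqrt(2 / fanIn)), dim = shape)
  }
}

materializeLayer <- function(ly) {
  if (!is.null(ly$sublayers))
    ly$sublayers <- lapply(ly$sublayers, materializeLayer)
  if (!is.null(ly$paramShapes)) {
    fanIn <- switch(ly$type,
                    conv = ly$kh * ly$kw * ly$cin,
                    dense = ly$nin,
                    1)
    ly$params <- lapply(names(ly$paramShapes), function(p)
      initParamArray(p, ly$paramShapes[[p]], fanIn))
    names(ly$params) <- names(ly$paramShapes)
  }
  ly
}

#' Materialize a model's weight arrays
#'
#' Allocates and randomly initializes every stored parameter array
#' (He-scaled kernels, zero biases, unit batch-norm variance). Tiny models
#' are materialized by [buildClassifier()] already; paper-scale models are
#' built shape-only and can be materialized here when a numeric forward pass
#' is wanted.
#'
#' @param model a [CNNClassifier-class].
#' @param seed integer RNG seed for the initialization draws.
#' @return the model with `params` filled in on every layer.
#' @export
materializeWeights <- function(model, seed = 1L) {
  withLocalSeed(seed, {
    model@layers <- lapply(model@layers, materializeLayer)
  })
  model
}

needParams <- function(ly) {
  if (is.null(ly$params))
    stop("layer '", ly$name, "' has no materialized weights; ",
         "run materializeWeights() first")
  ly$params
}

# ---- forward ----------------------------------------------------------------

convF <- function(ly, x) {
  p <- needParams(ly)
  b <- if (ly$bias) as.numeric(p$b) else numeric(ly$cout)
  .convForward(x, p$W, b, ly$stride, ly$pad)
}

layerForward <- function(ly, x, training = FALSE) {
  switch(ly$type,
    conv = list(out = convF(ly, x), cache = list(x = x)),
    relu = {
      out <- x * (x > 0)
      list(out = out, cache = list(mask = x > 0))
    },
    maxpool = {
      r <- .maxPoolForward(x, ly$k, ly$k, ly$stride, ly$pad)
      list(out = r$out, cache = list(argmax = r$argmax, inDim = dim(x)))
    },
    flatten = {
      d <- dim(x)
      out <- x
      dim(out) <- c(prod(d[1:3]), d[4])
      list(out = out, cache = list(inDim = d))
    },
    gap = {
      d <- dim(x)
      out <- apply(x, c(3, 4), mean)
      dim(out) <- c(d[3], d[4])
      list(out = out, cache = list(inDim = d))
    },
    dropout = {
      if (training && ly$rate > 0) {
        mask <- (runif(length(x)) >= ly$rate) / (1 - ly$rate)
        dim(mask) <- dim(x)
        list(out = x * mask, cache = list(mask = mask))
      } else {
        list(out = x, cache = list(mask = NULL))
      }
    },
    dense = {
      p <- needParams(ly)
      out <- crossprod(p$W, x) + as.numeric(p$b)
      list(out = out, cache = list(x = x))
    },
    inception = inceptionForward(ly, x),
    dense_block = denseBlockForward(ly, x),
    stop("no forward pass for layer type '", ly$type, "'")
  )
}

inceptionForward <- function(ly, x) {
  sub <- ly$sublayers
  b1 <- convF(sub$conv1, x)
  b3 <- convF(sub$conv3, x)
  b5 <- convF(sub$conv5, x)
  pl <- .maxPoolForward(x, 3L, 3L, 1L, 1L)
  d <- dim(x)
  widths <- c(dim(b1)[3], dim(b3)[3], dim(b5)[3], d[3])
  out <- array(0, c(d[1], d[2], sum(widths), d[4]))
  off <- cumsum(c(0, widths))
  out[, , (off[1] + 1):off[2], ] <- b1
  out[, , (off[2] + 1):off[3], ] <- b3
  out[, , (off[3] + 1):off[4], ] <- b5
  out[, , (off[4] + 1):off[5], ] <- pl$out
  list(out = out,
       cache = list(x = x, widths = widths, poolArgmax = pl$argmax))
}

denseBlockForward <- function(ly, x) {
  comps <- list(x)            # input plus each layer's output
  convInputs <- vector("list", length(ly$sublayers))
  masks <- vector("list", length(ly$sublayers))
  for (i in seq_along(ly$sublayers)) {
    inp <- abind4(comps)
    convInputs[[i]] <- inp
    pre <- convF(ly$sublayers[[i]], inp)
    masks[[i]] <- pre > 0
    comps[[i + 1]] <- pre * masks[[i]]
  }
  list(out = abind4(comps),
       cache = list(convInputs = convInputs, masks = masks,
                    widths = vapply(comps, function(a) dim(a)[3], integer(1))))
}

# concatenate (H, W, C, N) arrays along the channel axis
abind4 <- function(arrs) {
  if (length(arrs) == 1L) return(arrs[[1L]])
  d <- dim(arrs[[1L]])
  cs <- vapply(arrs, function(a) dim(a)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  off <- 0L
  for (a in arrs) {
    ca <- dim(a)[3]
    out[, , (off + 1L):(off + ca), ] <- a
    off <- off + ca
  }
  out
}

# ---- backward ---------------------------------------------------------------

# returns list(dx = ..., grads = named list matching params or NULL)
layerBackward <- function(ly, dout, cache) {
  switch(ly$type,
    conv = {
      p <- needParams(ly)
      r <- .convBackward(cache$x, p$W, dout, ly$stride, ly$pad)
      grads <- list(W = r$dw)
      if (ly$bias) grads$b <- r$db
      list(dx = r$dx, grads = grads)
    },
    relu = list(dx = dout * cache$mask, grads = NULL),
    maxpool = list(dx = .maxPoolBackward(cache$argmax, dout,
                                         as.integer(cache$inDim)),
                   grads = NULL),
    flatten = { dim(dout) <- cache$inDim; list(dx = dout, grads = NULL) },
    gap = {
      d <- cache$inDim
      dx <- array(rep(dout, each = d[1] * d[2]) / (d[1] * d[2]), d)
      list(dx = dx, grads = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask, grads = NULL)
    },
    dense = {
      p <- needParams(ly)
      list(dx = p$W %*% dout,
           grads = list(W = cache$x %*% t(dout),
                        b = rowSums(dout)))
    },
    inception = inceptionBackward(ly, dout, cache),
    dense_block = denseBlockBackward(ly, dout, cache),
    stop("no backward pass for layer type '", ly$type, "'")
  )
}

sliceChannels <- function(a, from, to) a[, , from:to, , drop = FALSE]

inceptionBackward <- function(ly, dout, cache) {
  sub <- ly$sublayers
  w <- cache$widths
  off <- cumsum(c(0, w))
  x <- cache$x
  grads <- list()
  dx <- array(0, dim(x))
  branchNames <- c("conv1", "conv3", "conv5")
  for (i in 1:3) {
    lySub <- sub[[branchNames[i]]]
    p <- needParams(lySub)
    db <- sliceChannels(dout, off[i] + 1L, off[i + 1L])
    r <- .convBackward(x, p$W, db, lySub$stride, lySub$pad)
    grads[[branchNames[i]]] <- list(W = r$dw, b = r$db)
    dx <- dx + r$dx
  }
  dpool <- sliceChannels(dout, off[4] + 1L, off[5])
  dx <- dx + .maxPoolBackward(cache$poolArgmax, dpool, as.integer(dim(x)))
  list(dx = dx, grads = NULL, subGrads = grads)
}

denseBlockBackward <- function(ly, dout, cache) {
  w <- cache$widths
  off <- cumsum(c(0, w))
  nl <- length(ly$sublayers)
  compGrads <- vector("list", nl + 1L)
  for (i in seq_len(nl + 1L))
    compGrads[[i]] <- sliceChannels(dout, off[i] + 1L, off[i + 1L])
  grads <- list()
  for (i in nl:1) {
    lySub <- ly$sublayers[[i]]
    p <- needParams(lySub)
    dpre <- compGrads[[i + 1L]] * cache$masks[[i]]
    r <- .convBackward(cache$convInputs[[i]], p$W, dpre, lySub$stride,
                      lySub$pad)
    grads[[lySub$name]] <- list(W = r$dw, b = r$db)
    # scatter the input gradient back onto components 1..i
    for (j in seq_len(i)) {
      compGrads[[j]] <- compGrads[[j]] +
        sliceChannels(r$dx, off[j] + 1L, off[j + 1L])
    }
  }
  list(dx = compGrads[[1L]], grads = NULL, subGrads = grads)
}

# ---- model-level passes -----------------------------------------------------

# Forward through all layers. Returns logits plus, when keepCaches, the
# per-layer caches and outputs (needed by backprop and grad-CAM).
forwardModel <- function(layers, x, training = FALSE, keepCaches = FALSE) {
  caches <- if (keepCaches) vector("list", length(layers)) else NULL
  outputs <- if (keepCaches) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    r <- layerForward(layers[[i]], x, training = training)
    x <- r$out
    if (keepCaches) {
      caches[[i]] <- r$cache
      outputs[[i]] <- x
    }
  }
  list(logits = x, caches = caches, outputs = outputs)
}

# Backward from the logits gradient down to (but not through) layer
# `stopAt`; stopAt = 0 reaches the input. Returns per-layer gradients and
# the gradient flowing out of layer stopAt's output.
backwardModel <- function(layers, caches, dlogits, stopAt = 0L) {
  grads <- vector("list", length(layers))
  dout <- dlogits
  for (i in rev(seq_along(layers))) {
    if (i <= stopAt) break
    r <- layerBackward(layers[[i]], dout, caches[[i]])
    # single-bracket assignment keeps NULL gradients as list slots
    grads[i] <- list(if (!is.null(r$subGrads)) r$subGrads else r$grads)
    dout <- r$dx
  }
  list(grads = grads, dx = dout)
}

softmaxProbs <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

# mean cross-entropy over the batch plus the logits gradient
softmaxCrossEntropy <- function(logits, labels) {
  n <- ncol(logits)
  probs <- softmaxProbs(logits)
  idx <- cbind(labels + 1L, seq_len(n))
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = probs)
}
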