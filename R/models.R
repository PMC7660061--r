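# Classifier construction: canonical paper-scale backbones and tiny
# trainable variants built from the same architectural motifs, all ending in
# the same head: flatten -> dropout -> dense(2) -> softmax.

#' Build a naive inception block
#'
#' Four parallel branches over the same input — a 1x1 convolution, a 3x3
#' convolution, a 5x5 convolution, and a 3x3 stride-1 max-pool pass-through
#' — concatenated along channels. All convolutions are stride 1 with
#' size-preserving padding and biases, so the output spatial size equals the
#' input and the output channel count is `w1 + w3 + w5 + inChannels`.
#'
#' @param inChannels input channel count.
#' @param branchWidths integer vector `(w1, w3, w5)` of branch widths.
#' @param name layer name.
#' @return a composite layer descriptor usable inside a tiny model.
#' @examples
#' blk <- buildInceptionBlock(8, c(4, 4, 4))
#' countParameters(list(blk))   # (1*1*8*4+4) + (3*3*8*4+4) + (5*5*8*4+4)
#' @export
buildInceptionBlock <- function(inChannels, branchWidths = c(8L, 8L, 8L),
                                name = "inception") {
  if (length(branchWidths) != 3L || any(branchWidths < 1L))
    stop("branchWidths must be three positive widths (w1, w3, w5)")
  if (inChannels < 1L) stop("inChannels must be >= 1")
  sub <- list(
    conv1 = mkConv(paste0(name, "_1x1"), 1L, 1L, inChannels, branchWidths[1]),
    conv3 = mkConv(paste0(name, "_3x3"), 3L, 3L, inChannels, branchWidths[2]),
    conv5 = mkConv(paste0(name, "_5x5"), 5L, 5L, inChannels, branchWidths[3])
  )
  mkLayer("inception", name, sublayers = sub,
          outChannels = sum(branchWidths) + inChannels)
}

#' Build a dense block
#'
#' A densely connected stack: every member layer is a biased 3x3 convolution
#' (followed by ReLU) whose input is the concatenation of the block input
#' and all preceding member outputs; the block output concatenates the input
#' with every member output, so the channel count grows by
#' `growth * nLayers`.
#'
#' @param inChannels input channel count.
#' @param growth channels added per member layer.
#' @param nLayers number of member layers.
#' @param name layer name.
#' @return a composite layer descriptor usable inside a tiny model.
#' @examples
#' blk <- buildDenseBlock(16, growth = 8, nLayers = 4)
#' blk$outChannels
#' @export
buildDenseBlock <- function(inChannels, growth = 8L, nLayers = 4L,
                            name = "dense_block") {
  if (growth < 1L || nLayers < 1L) stop("growth and nLayers must be >= 1")
  sub <- vector("list", nLayers)
  for (i in seq_len(nLayers)) {
    cin <- inChannels + (i - 1L) * growth
    sub[[i]] <- mkConv(sprintf("%s_conv%d", name, i), 3L, 3L, cin, growth)
  }
  names(sub) <- vapply(sub, `[[`, character(1), "name")
  mkLayer("dense_block", name, sublayers = sub,
          outChannels = inChannels + growth * nLayers)
}

# ---- tiny backbones ---------------------------------------------------------
# All operate on 64x64x3 inputs and end at a 4x4 feature map so that the
# three heads have identical capacity (flatten 512 -> dense 2).

tinyVGGBackbone <- function(inputSide) {
  st <- newStack(inputSide, inputSide, 3L)
  widths <- c(8L, 16L, 32L, 32L)
  for (i in seq_along(widths)) {
    stConv(st, sprintf("conv%d", i), widths[i], 3L)
    pushLayer(st, mkLayer("relu", sprintf("relu%d", i)))
    stPool(st, sprintf("pool%d", i), "max", 2L, 2L)
  }
  st
}

tinyInceptionBackbone <- function(inputSide) {
  st <- newStack(inputSide, inputSide, 3L)
  stConv(st, "conv1", 8L, 3L)
  pushLayer(st, mkLayer("relu", "relu1"))
  stPool(st, "pool1", "max", 2L, 2L)
  stConv(st, "conv2", 16L, 3L)
  pushLayer(st, mkLayer("relu", "relu2"))
  stPool(st, "pool2", "max", 2L, 2L)
  blk <- buildInceptionBlock(st$c, c(8L, 8L, 8L), name = "inception1")
  st$c <- blk$outChannels
  pushLayer(st, blk)
  pushLayer(st, mkLayer("relu", "relu3"))
  stPool(st, "pool3", "max", 2L, 2L)
  stConv(st, "conv3", 32L, 3L)
  pushLayer(st, mkLayer("relu", "relu4"))
  stPool(st, "pool4", "max", 2L, 2L)
  st
}

tinyDenseNetBackbone <- function(inputSide) {
  st <- newStack(inputSide, inputSide, 3L)
  stConv(st, "conv1", 8L, 3L)
  pushLayer(st, mkLayer("relu", "relu1"))
  stPool(st, "pool1", "max", 2L, 2L)
  stConv(st, "conv2", 16L, 3L)
  pushLayer(st, mkLayer("relu", "relu2"))
  stPool(st, "pool2", "max", 2L, 2L)
  blk <- buildDenseBlock(st$c, growth = 8L, nLayers = 4L, name = "dense1")
  st$c <- blk$outChannels
  pushLayer(st, blk)
  stPool(st, "pool3", "max", 2L, 2L)
  stConv(st, "transition", 32L, 1L)
  pushLayer(st, mkLayer("relu", "relu3"))
  stPool(st, "pool4", "max", 2L, 2L)
  st
}

# ---- classifier assembly ----------------------------------------------------

#' Build a two-class CNN frame classifier
#'
#' Assembles a backbone feature extractor and the classification head used
#' throughout the package: flatten, dropout, and a dense layer to 2 units
#' whose softmax gives the (without PS, with PS) score vector.
#'
#' At `scale = "paper"` the backbone is the canonical published feature
#' extractor (VGG16 13-conv stack ending at 7x7x512; DenseNet-121 ending at
#' 7x7x1024; Inception-v3 ending at 5x5x2048 on 224x224 inputs). These
#' models are built shape-only — use them for architecture accounting
#' ([countParameters()], [modelSummary()]) or call [materializeWeights()]
#' for a numeric forward pass. At `scale = "tiny"` the backbone is a small
#' trainable stack built from the same motifs (a linear conv stack, a naive
#' inception block, or a dense block) on 64x64 inputs, with weights
#' materialized and ready for [trainModel()]. Built classifiers center their
#' [0, 1] inputs around zero (subtracting 0.5) before the first convolution.
#'
#' @param architecture "vgg", "inception" or "densenet".
#' @param scale "paper" or "tiny".
#' @param inputSide input side length; fixed to 224 at paper scale,
#'   default 64 for tiny models.
#' @param dropoutRate head dropout probability in [0, 1); default 0.5.
#' @param initMode "random" (reproducible local initialization) —
#'   placeholder for future pretrained-weight support.
#' @param seed RNG seed for weight initialization of tiny models.
#' @return a [CNNClassifier-class].
#' @examples
#' vgg <- buildClassifier("vgg", scale = "paper")
#' countParameters(vgg)
#' tiny <- buildClassifier("densenet", scale = "tiny", seed = 1)
#' dim(predictProba(tiny, array(0.5, c(64, 64, 3, 2))))
#' @export
buildClassifier <- function(architecture = c("vgg", "inception", "densenet"),
                            scale = c("tiny", "paper"), inputSide = NULL,
                            dropoutRate = 0.5, initMode = "random",
                            seed = 1L) {
  architecture <- match.arg(architecture)
  scale <- match.arg(scale)
  if (initMode != "random")
    stop("only initMode = 'random' is supported")
  if (is.null(inputSide)) inputSide <- if (scale == "paper") 224L else 64L
  inputSide <- as.integer(inputSide)
  if (scale == "paper" && inputSide != 224L)
    stop("paper scale implies inputSide = 224")

  st <- if (scale == "paper") {
    switch(architecture,
           vgg = buildVGGBackbone(inputSide),
           densenet = buildDenseNetBackbone(inputSide),
           inception = buildInceptionBackbone(inputSide))
  } else {
    switch(architecture,
           vgg = tinyVGGBackbone(inputSide),
           inception = tinyInceptionBackbone(inputSide),
           densenet = tinyDenseNetBackbone(inputSide))
  }
  flatDim <- st$h * st$w * st$c
  pushLayer(st, mkLayer("flatten", "flatten"))
  pushLayer(st, mkLayer("dropout", "dropout", rate = dropoutRate))
  for (i in length(st$layers) - c(1L, 0L))
    st$layers[[i]]$outShape <- flatDim
  dense <- mkDense("dense", flatDim, 2L)
  dense$outShape <- 2L
  st$layers[[length(st$layers) + 1L]] <- dense

  model <- new("CNNClassifier", architecture = architecture, scale = scale,
               inputSide = inputSide, dropoutRate = dropoutRate,
               layers = st$layers, inputCenter = 0.5, trained = FALSE)
  validObject(model)
  if (scale == "tiny") model <- materializeWeights(model, seed = seed)
  model
}

#' Class probabilities for a batch of frames
#'
#' Runs the forward pass in evaluation mode (dropout off) and applies the
#' softmax.
#'
#' @param model a materialized [CNNClassifier-class].
#' @param x an `side x side x 3 x N` activation array in [0, 1], or a single
#'   `side x side x 3` frame.
#' @return an `N x 2` matrix of score vectors; columns are `s0` (without
#'   pathological site) and `s1` (with), each row summing to 1.
#' @export
predictProba <- function(model, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  logits <- forwardModel(model@layers, x - model@inputCenter,
                         training = FALSE)$logits
  probs <- t(softmaxProbs(logits))
  colnames(probs) <- c("s0", "s1")
  probs
}

#' Per-layer model summary table
#'
#' One row per layer with its output shape and stored-parameter count,
#' mirroring the layout of a network-description table
#' (layer / output shape / number of parameters).
#'
#' @param model a [CNNClassifier-class].
#' @return a data.frame with columns `layer`, `type`, `outputShape`,
#'   `parameters`.
#' @examples
#' head(modelSummary(buildClassifier("vgg", scale = "paper")))
#' @export
modelSummary <- function(model) {
  rows <- lapply(model@layers, function(ly) {
    shp <- ly$outShape
    data.frame(layer = ly$name, type = ly$type,
               outputShape = paste(shp, collapse = " x "),
               parameters = countParameters(list(ly)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# backbone/head split used by the accounting checks: the head starts at the
# flatten layer
backboneLayers <- function(model) {
  idx <- which(vapply(model@layers, `[[`, character(1), "type") == "flatten")
  model@layers[seq_len(idx - 1L)]
}

headLayers <- function(model) {
  idx <- which(vapply(model@layers, `[[`, character(1), "type") == "flatten")
  model@layers[idx:length(model@layers)]
}
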