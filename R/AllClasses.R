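#' CNNClassifier: a convolutional two-class frame classifier
#'
#' S4 container for one member of the classification ensemble: a backbone
#' feature extractor followed by flatten, dropout and a two-unit dense layer
#' whose softmax output is the two-class score vector (without / with a
#' pathological site). Paper-scale models carry the canonical VGG16,
#' DenseNet-121 and Inception-v3 feature extractors (used for architecture
#' accounting and shape propagation); tiny models are trainable on 64x64
#' frames with the package's built-in engine.
#'
#' @slot architecture one of "vgg", "inception", "densenet".
#' @slot scale "paper" (224x224 canonical backbone) or "tiny" (64x64).
#' @slot inputSide input image side length in pixels.
#' @slot dropoutRate dropout probability of the head, in [0, 1).
#' @slot layers ordered list of layer descriptors (internal representation);
#'   trainable layers hold their weight arrays in `$params`.
#' @slot inputCenter value subtracted from the [0, 1] input intensities
#'   before the first convolution (0.5 for built classifiers, centering the
#'   inputs around zero; 0 leaves inputs untouched).
#' @slot trained logical; set by [trainModel()].
#'
#' @seealso [buildClassifier()], [countParameters()], [trainModel()]
#' @export
setClass("CNNClassifier",
  representation(
    architecture = "character",
    scale        = "character",
    inputSide    = "integer",
    dropoutRate  = "numeric",
    layers       = "list",
    inputCenter  = "numeric",
    trained      = "logical"
  ),
  prototype(trained = FALSE, inputCenter = 0)
)

setValidity("CNNClassifier", function(object) {
  msg <- character()
  if (!object@architecture %in% c("vgg", "inception", "densenet"))
    msg <- c(msg, "architecture must be 'vgg', 'inception' or 'densenet'")
  if (!object@scale %in% c("paper", "tiny"))
    msg <- c(msg, "scale must be 'paper' or 'tiny'")
  if (object@scale == "paper" && object@inputSide != 224L)
    msg <- c(msg, "paper scale implies inputSide = 224")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1)")
  if (length(object@layers) == 0L)
    msg <- c(msg, "model has no layers")
  if (length(msg)) msg else TRUE
})

#' ActivationMap: a grad-CAM saliency heatmap
#'
#' Normalized gradient-weighted class activation map at the model-input
#' resolution. Values lie in [0, 1]; unless the rectified raw map was
#' identically zero (`allZero = TRUE`), the maximum value is exactly 1.
#'
#' @slot heatmap numeric matrix (input height x width) in [0, 1].
#' @slot targetClass integer, 0 (without PS) or 1 (with PS).
#' @slot sourceLayer name of the convolutional stage the map was drawn from.
#' @slot allZero logical flag: the rectified raw map was identically zero.
#'
#' @seealso [gradCAM()]
#' @export
setClass("ActivationMap",
  representation(
    heatmap     = "matrix",
    targetClass = "integer",
    sourceLayer = "character",
    allZero     = "logical"
  )
)

setValidity("ActivationMap", function(object) {
  h <- object@heatmap
  if (any(h < -1e-12) || any(h > 1 + 1e-12))
    return("heatmap values must lie in [0, 1]")
  if (!object@targetClass %in% c(0L, 1L))
    return("targetClass must be 0 or 1")
  if (!object@allZero && max(h) < 1 - 1e-9)
    return("non-zero heatmap must be normalized to max 1")
  TRUE
})

#' @describeIn CNNClassifier architecture name accessor.
#' @param object a `CNNClassifier`.
#' @export
setGeneric("architecture", function(object) standardGeneric("architecture"))

#' @rdname CNNClassifier
#' @export
setMethod("architecture", "CNNClassifier", function(object) object@architecture)

#' @describeIn CNNClassifier input side length accessor.
#' @export
setGeneric("inputSide", function(object) standardGeneric("inputSide"))

#' @rdname CNNClassifier
#' @export
setMethod("inputSide", "CNNClassifier", function(object) object@inputSide)

#' @describeIn CNNClassifier ordered list of layer descriptors.
#' @export
setGeneric("modelLayers", function(object) standardGeneric("modelLayers"))

#' @rdname CNNClassifier
#' @export
setMethod("modelLayers", "CNNClassifier", function(object) object@layers)

#' Count stored parameters of a model or layer list
#'
#' Counts every stored parameter array — convolution kernels and biases,
#' dense weights, and batch-normalization scale/shift plus moving statistics.
#' Including the (non-trainable) moving statistics matches the accounting
#' convention under which the published sizes of the three canonical
#' backbones are stated.
#'
#' @param object a `CNNClassifier`, or a list of layer descriptors.
#' @return integer-valued numeric: the total number of stored parameters.
#' @examples
#' m <- buildClassifier("vgg", scale = "tiny", seed = 1)
#' countParameters(m)
#' @export
setGeneric("countParameters", function(object) standardGeneric("countParameters"))

#' @rdname countParameters
#' @export
setMethod("countParameters", "CNNClassifier",
          function(object) countParameters(object@layers))

#' @rdname countParameters
#' @export
setMethod("countParameters", "list", function(object) {
  total <- 0
  for (ly in object) {
    if (!is.null(ly$sublayers)) total <- total + countParameters(ly$sublayers)
    shp <- ly$paramShapes
    if (!is.null(shp)) total <- total + sum(vapply(shp, prod, numeric(1)))
  }
  total
})

#' @rdname CNNClassifier
#' @export
setMethod("show", "CNNClassifier", function(object) {
  cat(sprintf("CNNClassifier: %s (%s scale)\n", object@architecture, object@scale))
  cat(sprintf("  input: %d x %d x 3, dropout %.2f, %s\n",
              object@inputSide, object@inputSide, object@dropoutRate,
              if (object@trained) "trained" else "untrained"))
  cat(sprintf("  layers: %d, parameters: %s\n", length(object@layers),
              format(countParameters(object), big.mark = ",")))
  invisible(object)
})

#' @rdname ActivationMap
#' @param object an `ActivationMap`.
#' @export
setMethod("show", "ActivationMap", function(object) {
  cat(sprintf("ActivationMap (%d x %d) for class %d from layer '%s'%s\n",
              nrow(object@heatmap), ncol(object@heatmap), object@targetClass,
              object@sourceLayer,
              if (object@allZero) " [all-zero rectified map]" else ""))
  invisible(object)
})

#' @describeIn ActivationMap heatmap matrix accessor.
#' @export
setGeneric("camHeatmap", function(object) standardGeneric("camHeatmap"))

#' @rdname ActivationMap
#' @export
setMethod("camHeatmap", "ActivationMap", function(object) object@heatmap)
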