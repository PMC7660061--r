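# Gradient-weighted class activation mapping: which regions of a frame
# drive the classifier's decision. The channel weights are the spatial mean
# of the target-class logit gradient at a convolutional stage; the map is
# the rectified, channel-weighted sum of that stage's feature maps,
# upsampled to the input resolution and min-max normalized.

convStageIndices <- function(layers) {
  which(vapply(layers, function(ly)
    ly$type %in% c("conv", "inception", "dense_block"), logical(1)))
}

#' Gradient-weighted class activation map
#'
#' @param model a materialized [CNNClassifier-class].
#' @param image a `side x side x 3` preprocessed frame (values in [0, 1]) at
#'   the model's input size.
#' @param targetClass 0 (without pathological site) or 1 (with).
#' @param sourceLayer name of the convolutional stage to draw the map from;
#'   default is the model's last convolutional stage.
#' @return an [ActivationMap-class]. If the rectified raw map is identically
#'   zero the heatmap is all zeros and the `allZero` flag is set.
#' @examples
#' m <- buildClassifier("vgg", scale = "tiny", seed = 1)
#' fr <- generateFrame(frameSpec(64, 64, label = 0, seed = 2))
#' cam <- gradCAM(m, fr$image, targetClass = 1)
#' range(camHeatmap(cam))
#' @export
gradCAM <- function(model, image, targetClass = 1L, sourceLayer = NULL) {
  layers <- model@layers
  stages <- convStageIndices(layers)
  if (length(stages) == 0L)
    stop("model has no convolutional stage to draw a class activation map from")
  if (is.null(sourceLayer)) {
    src <- stages[length(stages)]
  } else {
    nm <- vapply(layers, `[[`, character(1), "name")
    src <- which(nm == sourceLayer)
    if (length(src) != 1L || !(src %in% stages))
      stop("sourceLayer must name a convolutional stage of the model")
  }
  targetClass <- as.integer(targetClass)
  if (!targetClass %in% c(0L, 1L)) stop("targetClass must be 0 or 1")

  x <- image - model@inputCenter
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  fw <- forwardModel(layers, x, training = FALSE, keepCaches = TRUE)
  dlogits <- matrix(0, nrow = 2L, ncol = 1L)
  dlogits[targetClass + 1L, 1L] <- 1
  bw <- backwardModel(layers, fw$caches, dlogits, stopAt = src)

  acts <- fw$outputs[[src]]      # H x W x C x 1 feature maps
  grads <- bw$dx                 # same shape: d logit / d activation
  weights <- apply(grads[, , , 1L, drop = FALSE], 3L, mean)
  raw <- matrix(0, dim(acts)[1], dim(acts)[2])
  for (c in seq_along(weights))
    raw <- raw + weights[c] * acts[, , c, 1L]
  raw <- pmax(raw, 0)

  side <- model@inputSide
  up <- bilinearResize(array(raw, c(dim(raw), 1L))[, , c(1, 1, 1)],
                       side)[, , 1L]
  up <- pmax(up, 0)
  mx <- max(up)
  allZero <- mx <= 0
  if (!allZero) up <- up / mx
  new("ActivationMap", heatmap = up, targetClass = targetClass,
      sourceLayer = layers[[src]]$name, allZero = allZero)
}

#' Render a heatmap overlay on a frame
#'
#' Purely cosmetic blending of an activation map over the frame with a
#' perceptually uniform colormap at fixed alpha; the numeric contract lives
#' entirely in [gradCAM()].
#'
#' @param image `side x side x 3` frame in [0, 1].
#' @param cam an [ActivationMap-class] (or a heatmap matrix in [0, 1]).
#' @param alpha blend weight of the colormap layer.
#' @return a `side x side x 3` array in [0, 1].
#' @export
renderOverlay <- function(image, cam, alpha = 0.5) {
  h <- if (is(cam, "ActivationMap")) camHeatmap(cam) else cam
  pal <- hcl.colors(256L, "viridis")
  idx <- pmin(pmax(floor(h * 255) + 1L, 1L), 256L)
  rgb <- col2rgb(pal[idx]) / 255
  out <- image
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * image[, , ch] +
      alpha * matrix(rgb[ch, ], nrow(h), ncol(h))
  pmin(pmax(out, 0), 1)
}
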