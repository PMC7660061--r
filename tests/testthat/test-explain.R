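test_that("grad-CAM heatmaps have input resolution and unit range", {
  m <- buildClassifier("vgg", scale = "tiny", seed = 3)
  img <- generateFrame(positiveSpec(seed = 4))$image
  cam <- gradCAM(m, img, targetClass = 1)
  expect_s4_class(cam, "ActivationMap")
  h <- camHeatmap(cam)
  expect_equal(dim(h), c(64, 64))
  expect_true(all(h >= 0 & h <= 1))
  if (!cam@allZero) expect_equal(max(h), 1)
})

test_that("toy model heatmap matches the hand-derived closed form", {
  # identity 1x1 conv on one channel -> global average pool -> dense(2).
  # For class c the activation gradient is W[1, c] / (H * W) everywhere, so
  # the map is relu(W[1, c] * x) normalized: the rectified input itself
  # when W[1, c] > 0, and all zeros when W[1, c] < 0.
  side <- 8L
  conv <- EndoEnsemble:::mkConv("id", 1L, 1L, 1L, 1L)
  conv$params <- list(W = array(1, c(1, 1, 1, 1)), b = array(0, 1))
  conv$outShape <- c(side, side, 1L)
  gapL <- EndoEnsemble:::mkLayer("gap", "gap")
  dense <- EndoEnsemble:::mkDense("head", 1L, 2L)
  dense$params <- list(W = matrix(c(-2, 3), 1, 2), b = c(0, 0))
  model <- new("CNNClassifier", architecture = "vgg", scale = "tiny",
               inputSide = side, dropoutRate = 0,
               layers = list(conv, gapL, dense), trained = TRUE)

  set.seed(12)
  x <- matrix(runif(side * side), side, side)    # non-negative activations
  img <- array(x, c(side, side, 1L))

  cam1 <- gradCAM(model, img, targetClass = 1)   # weight +3: the input itself
  expected <- x / max(x)
  expect_equal(camHeatmap(cam1), expected, tolerance = 1e-9)
  expect_false(cam1@allZero)

  cam0 <- gradCAM(model, img, targetClass = 0)   # weight -2: all rectified away
  expect_true(cam0@allZero)
  expect_true(all(camHeatmap(cam0) == 0))
})

test_that("normalization is idempotent and scale-invariant in the logits", {
  m <- buildClassifier("inception", scale = "tiny", seed = 5)
  img <- generateFrame(positiveSpec(seed = 6, kind = "vascular"))$image
  cam <- gradCAM(m, img, targetClass = 1)
  h <- camHeatmap(cam)
  expect_equal(h / max(h, 1e-12), h, tolerance = 1e-12)

  # scaling the head weights scales the logits but not the normalized map
  m2 <- m
  dense <- length(m2@layers)
  m2@layers[[dense]]$params$W <- m2@layers[[dense]]$params$W * 7
  m2@layers[[dense]]$params$b <- m2@layers[[dense]]$params$b * 7
  cam2 <- gradCAM(m2, img, targetClass = 1)
  expect_equal(camHeatmap(cam2), h, tolerance = 1e-9)
})

test_that("source layer can be chosen by name and must be convolutional", {
  m <- buildClassifier("vgg", scale = "tiny", seed = 7)
  img <- generateFrame(positiveSpec(seed = 8))$image
  cam <- gradCAM(m, img, targetClass = 1, sourceLayer = "conv2")
  expect_equal(cam@sourceLayer, "conv2")
  expect_error(gradCAM(m, img, sourceLayer = "pool1"), "convolutional stage")
})

test_that("trained-model heatmaps concentrate inside the lesion box", {
  mkFrame <- function(seed, positive) {
    if (positive) {
      set.seed(seed)
      top <- sample(10:38, 1); left <- sample(10:38, 1)
      spec <- frameSpec(64, 64, label = 1, lesionKind = "polyp",
                        lesionBox = cropBox(top, top + 16, left, left + 16),
                        seed = seed)
    } else {
      spec <- frameSpec(64, 64, label = 0, seed = seed)
    }
    c(generateFrame(spec), list(spec = spec))
  }
  n <- 60
  frames <- c(lapply(1:n, mkFrame, positive = TRUE),
              lapply((n + 1):(2 * n), mkFrame, positive = FALSE))
  side <- 32L
  x <- array(0, c(side, side, 3, 2 * n))
  boxes <- vector("list", 2 * n)
  for (i in seq_along(frames)) {
    pp <- preprocessFrame(frames[[i]]$image, outSize = side)
    x[, , , i] <- pp$image
    if (!is.null(frames[[i]]$spec$lesionBox))
      boxes[[i]] <- transformBox(frames[[i]]$spec$lesionBox, pp$box, side)
  }
  y <- rep(c(1L, 0L), each = n)
  m <- buildClassifier("vgg", scale = "tiny", inputSide = side, seed = 3)
  tr <- trainModel(m, x, y, trainConfig(initialLr = 3e-3, epochs = 12,
                                        seed = 7))
  expect_gte(tail(tr$history$accuracy, 1), 0.9)

  hits <- 0L
  for (i in 1:50) {
    h <- camHeatmap(gradCAM(tr$model, x[, , , i], targetClass = 1))
    b <- boxes[[i]]
    inside <- h[(b$top + 1):b$bottom, (b$left + 1):b$right]
    mask <- matrix(TRUE, side, side)
    mask[(b$top + 1):b$bottom, (b$left + 1):b$right] <- FALSE
    hits <- hits + (mean(inside) > mean(h[mask]))
  }
  # the lesion should out-score the background in at least 80% of frames
  expect_gte(hits, 40L)
})

test_that("overlay rendering stays in range and preserves shape", {
  m <- buildClassifier("vgg", scale = "tiny", seed = 3)
  img <- generateFrame(positiveSpec(seed = 4))$image
  cam <- gradCAM(m, img, targetClass = 1)
  ov <- renderOverlay(img, cam)
  expect_equal(dim(ov), dim(img))
  expect_true(all(ov >= 0 & ov <= 1))
})
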