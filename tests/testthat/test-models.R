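test_that("naive inception block concatenates branches and counts parameters", {
  blk <- buildInceptionBlock(8, c(4, 4, 4))
  expect_equal(blk$outChannels, 20)          # 4 + 4 + 4 + 8 pass-through
  # biased convs: (1*1*8*4+4) + (3*3*8*4+4) + (5*5*8*4+4) = 36 + 292 + 804
  expect_equal(countParameters(list(blk)), 1132)
  expect_error(buildInceptionBlock(8, c(0, 4, 4)), "positive")

  # spatial size is preserved through the block
  m <- buildClassifier("inception", scale = "tiny", seed = 2)
  idx <- which(vapply(m@layers, `[[`, character(1), "type") == "inception")
  ly <- m@layers[[idx]]
  prev <- m@layers[[idx - 1L]]$outShape
  expect_equal(ly$outShape[1:2], prev[1:2])
  expect_equal(ly$outShape[3], sum(c(8, 8, 8)) + prev[3])
})

test_that("dense block grows channels by growth per member layer", {
  blk <- buildDenseBlock(16, growth = 8, nLayers = 4)
  expect_equal(blk$outChannels, 16 + 4 * 8)
  cins <- vapply(blk$sublayers, `[[`, numeric(1), "cin")
  expect_equal(unname(cins), c(16, 24, 32, 40))
})

test_that("paper-scale backbones match the published sizes and shapes", {
  cases <- list(
    vgg = list(backbone = 14714688, head = 50178, shape = c(7, 7, 512)),
    densenet = list(backbone = 7037504, head = 100354, shape = c(7, 7, 1024)),
    inception = list(backbone = 21802784, head = 102402, shape = c(5, 5, 2048)))
  for (arch in names(cases)) {
    m <- buildClassifier(arch, scale = "paper")
    bb <- EndoEnsemble:::backboneLayers(m)
    expect_equal(countParameters(bb), cases[[arch]]$backbone)
    expect_equal(countParameters(EndoEnsemble:::headLayers(m)),
                 cases[[arch]]$head)
    expect_equal(bb[[length(bb)]]$outShape, cases[[arch]]$shape)
    # additivity of the parameter count over the backbone/head split
    expect_equal(countParameters(m),
                 cases[[arch]]$backbone + cases[[arch]]$head)
  }
})

test_that("dense head of k inputs to 2 units has 2k + 2 parameters", {
  expect_equal(countParameters(list(EndoEnsemble:::mkDense("d", 25088, 2))),
               50178)
  expect_equal(countParameters(list(EndoEnsemble:::mkDense("d", 2, 2))), 6)
})

test_that("tiny models emit finite two-class probabilities summing to 1", {
  x <- generateFrame(frameSpec(64, 64, label = 0, seed = 17))$image
  for (arch in c("vgg", "inception", "densenet")) {
    m <- buildClassifier(arch, scale = "tiny", seed = 4)
    p <- predictProba(m, x)
    expect_equal(dim(p), c(1L, 2L))
    expect_true(all(is.finite(p)))
    expect_equal(sum(p), 1)
  }
})

test_that("unknown architectures and invalid specs are rejected", {
  expect_error(buildClassifier("resnet"), "arg")
  expect_error(buildClassifier("vgg", scale = "paper", inputSide = 64),
               "224")
})

test_that("model summary mirrors layer / output shape / parameter columns", {
  m <- buildClassifier("vgg", scale = "paper")
  s <- modelSummary(m)
  expect_named(s, c("layer", "type", "outputShape", "parameters"))
  expect_equal(sum(s$parameters), countParameters(m))
  expect_equal(s$outputShape[nrow(s)], "2")
})

test_that("backward pass matches finite-difference gradients", {
  set.seed(99)
  m <- buildClassifier("densenet", scale = "tiny", inputSide = 16L,
                       dropoutRate = 0, seed = 6)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- c(0L, 1L)
  layers <- m@layers
  fw <- EndoEnsemble:::forwardModel(layers, x, keepCaches = TRUE)
  ls <- EndoEnsemble:::softmaxCrossEntropy(fw$logits, y)
  bw <- EndoEnsemble:::backwardModel(layers, fw$caches, ls$dlogits)
  paths <- EndoEnsemble:::paramPaths(layers)
  lossAt <- function(lys) EndoEnsemble:::softmaxCrossEntropy(
    EndoEnsemble:::forwardModel(lys, x)$logits, y)$loss
  for (k in sample(seq_along(paths), 5)) {
    pt <- paths[[k]]
    p <- EndoEnsemble:::getParam(layers, pt)
    i <- sample(length(p), 1)
    eps <- 1e-5
    p2 <- p; p2[i] <- p[i] + eps
    lp <- lossAt(EndoEnsemble:::setParam(layers, pt, p2))
    p2[i] <- p[i] - eps
    lm <- lossAt(EndoEnsemble:::setParam(layers, pt, p2))
    expect_equal(EndoEnsemble:::getGrad(bw$grads, pt)[i],
                 (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
})
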