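# Canonical published feature extractors, encoded as layer descriptors for
# architecture accounting and shape propagation.
#
# Conventions matter for the parameter totals and are therefore encoded
# exactly as in the published reference implementations:
#   * VGG16: biased 3x3 convolutions, no batch norm.
#   * DenseNet-121: bias-free convolutions; batch norm with scale and shift
#     plus moving mean/variance (4 stored arrays per channel).
#   * Inception-v3: bias-free convolutions; batch norm without the scale
#     parameter (3 stored arrays per channel).
# Counting every stored array, including the non-trainable moving
# statistics, reproduces the published totals of all three backbones.

tfOut <- function(n, k, stride, padding) {
  if (padding == "same") as.integer(ceiling(n / stride))
  else as.integer(floor((n - k) / stride) + 1L)
}

# builder state helpers: a mutable environment tracking (h, w, c) and layers
newStack <- function(h, w, c) {
  st <- new.env(parent = emptyenv())
  st$h <- h; st$w <- w; st$c <- c
  st$layers <- list()
  st
}

pushLayer <- function(st, ly) {
  ly$outShape <- c(st$h, st$w, st$c)
  st$layers[[length(st$layers) + 1L]] <- ly
  invisible(st)
}

stConv <- function(st, name, cout, kh, kw = kh, stride = 1L,
                   padding = "same", bias = TRUE) {
  ly <- mkConv(name, kh, kw, st$c, cout, stride = stride,
               pad = if (padding == "same") samePad(kh) else 0L, bias = bias)
  ly$padding <- padding
  st$h <- tfOut(st$h, kh, stride, padding)
  st$w <- tfOut(st$w, kw, stride, padding)
  st$c <- cout
  pushLayer(st, ly)
}

stBN <- function(st, name, scale = TRUE) {
  pushLayer(st, mkBatchNorm(name, st$c, scale = scale))
}

stPool <- function(st, name, kind, k, stride, padding = "valid") {
  ly <- mkPool(name, kind, k, stride,
               pad = if (padding == "same") samePad(k) else 0L)
  st$h <- tfOut(st$h, k, stride, padding)
  st$w <- tfOut(st$w, k, stride, padding)
  pushLayer(st, ly)
}

# ---- VGG16 ------------------------------------------------------------------

buildVGGBackbone <- function(inputSide = 224L) {
  st <- newStack(inputSide, inputSide, 3L)
  widths <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                 c(512, 512, 512), c(512, 512, 512))
  for (b in seq_along(widths)) {
    for (i in seq_along(widths[[b]]))
      stConv(st, sprintf("block%d_conv%d", b, i), widths[[b]][i], 3L)
    stPool(st, sprintf("block%d_pool", b), "max", 2L, 2L)
  }
  st
}

# ---- DenseNet-121 -----------------------------------------------------------

buildDenseNetBackbone <- function(inputSide = 224L, growth = 32L,
                                  blockSizes = c(6L, 12L, 24L, 16L)) {
  st <- newStack(inputSide, inputSide, 3L)
  stConv(st, "stem_conv", 64L, 7L, stride = 2L, padding = "same",
         bias = FALSE)
  stBN(st, "stem_bn")
  stPool(st, "stem_pool", "max", 3L, 2L, padding = "same")
  for (b in seq_along(blockSizes)) {
    for (i in seq_len(blockSizes[b])) {
      nm <- sprintf("dense%d_layer%d", b, i)
      stBN(st, paste0(nm, "_bn1"))
      cin <- st$c
      stConv(st, paste0(nm, "_bottleneck"), 4L * growth, 1L, bias = FALSE)
      stBN(st, paste0(nm, "_bn2"))
      stConv(st, paste0(nm, "_conv"), growth, 3L, bias = FALSE)
      # dense connectivity: the block's running channel count grows by
      # `growth`; encode the concatenation by resetting the tracked width
      st$c <- cin + growth
      pushLayer(st, mkLayer("concat", paste0(nm, "_concat")))
    }
    if (b < length(blockSizes)) {
      stBN(st, sprintf("transition%d_bn", b))
      stConv(st, sprintf("transition%d_conv", b), st$c %/% 2L, 1L,
             bias = FALSE)
      stPool(st, sprintf("transition%d_pool", b), "avg", 2L, 2L)
    }
  }
  stBN(st, "final_bn")
  st
}

# ---- Inception-v3 -----------------------------------------------------------

# conv + batch-norm unit (bias-free conv, scale-free BN)
stConvBN <- function(st, name, cout, kh, kw = kh, stride = 1L,
                     padding = "same") {
  stConv(st, paste0(name, "_conv"), cout, kh, kw, stride = stride,
         padding = padding, bias = FALSE)
  stBN(st, paste0(name, "_bn"), scale = FALSE)
}

# a parallel branch: convBN specs applied sequentially from the block input
inceptionBranch <- function(st, specs) {
  h <- st$h; w <- st$w; c <- st$c
  for (sp in specs) {
    stConvBN(st, sp$name, sp$cout, sp$kh, sp$kw,
             stride = if (is.null(sp$stride)) 1L else sp$stride,
             padding = if (is.null(sp$padding)) "same" else sp$padding)
  }
  out <- c(st$h, st$w, st$c)
  st$h <- h; st$w <- w; st$c <- c     # rewind for the next branch
  out
}

# close a block: branches were emitted; set the concatenated output shape
closeBlock <- function(st, name, branchShapes, poolChannels = NULL) {
  hs <- vapply(branchShapes, `[`, integer(1), 1L)
  st$h <- hs[1L]; st$w <- vapply(branchShapes, `[`, integer(1), 2L)[1L]
  st$c <- sum(vapply(branchShapes, `[`, integer(1), 3L))
  pushLayer(st, mkLayer("concat", name))
}

cbSpec <- function(name, cout, kh, kw = kh, stride = NULL, padding = NULL) {
  list(name = name, cout = cout, kh = kh, kw = kw, stride = stride,
       padding = padding)
}

buildInceptionBackbone <- function(inputSide = 224L) {
  st <- newStack(inputSide, inputSide, 3L)
  stConvBN(st, "stem1", 32L, 3L, stride = 2L, padding = "valid")
  stConvBN(st, "stem2", 32L, 3L, padding = "valid")
  stConvBN(st, "stem3", 64L, 3L)
  stPool(st, "stem_pool1", "max", 3L, 2L)
  stConvBN(st, "stem4", 80L, 1L, padding = "valid")
  stConvBN(st, "stem5", 192L, 3L, padding = "valid")
  stPool(st, "stem_pool2", "max", 3L, 2L)

  # three 35x35 blocks (5x5-style factorized mixture)
  poolWidths <- c(32L, 64L, 64L)
  for (m in 1:3) {
    p <- sprintf("mixed%d", m - 1L)
    shapes <- list(
      inceptionBranch(st, list(cbSpec(paste0(p, "_b1"), 64L, 1L))),
      inceptionBranch(st, list(cbSpec(paste0(p, "_b5a"), 48L, 1L),
                               cbSpec(paste0(p, "_b5b"), 64L, 5L))),
      inceptionBranch(st, list(cbSpec(paste0(p, "_b3a"), 64L, 1L),
                               cbSpec(paste0(p, "_b3b"), 96L, 3L),
                               cbSpec(paste0(p, "_b3c"), 96L, 3L))),
      inceptionBranch(st, list(cbSpec(paste0(p, "_pool"), poolWidths[m], 1L)))
    )
    closeBlock(st, p, shapes)
  }

  # grid reduction to 17x17
  shapes <- list(
    inceptionBranch(st, list(cbSpec("mixed3_b3", 384L, 3L, stride = 2L,
                                    padding = "valid"))),
    inceptionBranch(st, list(cbSpec("mixed3_dbl_a", 64L, 1L),
                             cbSpec("mixed3_dbl_b", 96L, 3L),
                             cbSpec("mixed3_dbl_c", 96L, 3L, stride = 2L,
                                    padding = "valid"))),
    { h <- st$h; w <- st$w; c <- st$c
      stPool(st, "mixed3_pool", "max", 3L, 2L)
      out <- c(st$h, st$w, st$c); st$h <- h; st$w <- w; st$c <- c; out }
  )
  closeBlock(st, "mixed3", shapes)

  # four 17x17 blocks with factorized 7x7 branches
  c7s <- c(128L, 160L, 160L, 192L)
  for (m in 1:4) {
    p <- sprintf("mixed%d", m + 3L)
    c7 <- c7s[m]
    shapes <- list(
      inceptionBranch(st, list(cbSpec(paste0(p, "_b1"), 192L, 1L))),
      inceptionBranch(st, list(cbSpec(paste0(p, "_b7a"), c7, 1L),
                               cbSpec(paste0(p, "_b7b"), c7, 1L, 7L),
                               cbSpec(paste0(p, "_b7c"), 192L, 7L, 1L))),
      inceptionBranch(st, list(cbSpec(paste0(p, "_dbl_a"), c7, 1L),
                               cbSpec(paste0(p, "_dbl_b"), c7, 7L, 1L),
                               cbSpec(paste0(p, "_dbl_c"), c7, 1L, 7L),
                               cbSpec(paste0(p, "_dbl_d"), c7, 7L, 1L),
                               cbSpec(paste0(p, "_dbl_e"), 192L, 1L, 7L))),
      inceptionBranch(st, list(cbSpec(paste0(p, "_pool"), 192L, 1L)))
    )
    closeBlock(st, p, shapes)
  }

  # grid reduction to 5x5 (for 224x224 input; 8x8 at the 299 design size)
  shapes <- list(
    inceptionBranch(st, list(cbSpec("mixed8_b3a", 192L, 1L),
                             cbSpec("mixed8_b3b", 320L, 3L, stride = 2L,
                                    padding = "valid"))),
    inceptionBranch(st, list(cbSpec("mixed8_b7a", 192L, 1L),
                             cbSpec("mixed8_b7b", 192L, 1L, 7L),
                             cbSpec("mixed8_b7c", 192L, 7L, 1L),
                             cbSpec("mixed8_b7d", 192L, 3L, stride = 2L,
                                    padding = "valid"))),
    { h <- st$h; w <- st$w; c <- st$c
      stPool(st, "mixed8_pool", "max", 3L, 2L)
      out <- c(st$h, st$w, st$c); st$h <- h; st$w <- w; st$c <- c; out }
  )
  closeBlock(st, "mixed8", shapes)

  # two final blocks with split 3x3 branches
  for (m in 1:2) {
    p <- sprintf("mixed%d", m + 8L)
    shapes <- list(
      inceptionBranch(st, list(cbSpec(paste0(p, "_b1"), 320L, 1L))),
      inceptionBranch(st, list(cbSpec(paste0(p, "_b3a"), 384L, 1L),
                               cbSpec(paste0(p, "_b3b1"), 384L, 1L, 3L))),
      inceptionBranch(st, list(cbSpec(paste0(p, "_b3a2"), 384L, 1L),
                               cbSpec(paste0(p, "_b3b2"), 384L, 3L, 1L))),
      inceptionBranch(st, list(cbSpec(paste0(p, "_dbl_a"), 448L, 1L),
                               cbSpec(paste0(p, "_dbl_b"), 384L, 3L),
                               cbSpec(paste0(p, "_dbl_c"), 384L, 1L, 3L))),
      inceptionBranch(st, list(cbSpec(paste0(p, "_dbl_a2"), 448L, 1L),
                               cbSpec(paste0(p, "_dbl_b2"), 384L, 3L),
                               cbSpec(paste0(p, "_dbl_d"), 384L, 3L, 1L))),
      inceptionBranch(st, list(cbSpec(paste0(p, "_pool"), 192L, 1L)))
    )
    # the two split 3x3 pairs share their leading 1x1/3x3 convolutions: drop
    # the duplicated stems from the layer list but keep their branch output
    # channels in the concatenation
    dropDuplicateStems(st, p)
    shapes <- list(shapes[[1]],
                   c(shapes[[2]][1:2], 384L + 384L),
                   c(shapes[[4]][1:2], 384L + 384L),
                   shapes[[6]])
    closeBlock(st, p, shapes)
  }
  st
}

# remove the duplicated shared-stem convBN units emitted for the split
# branches of the final blocks (they exist once in the real network)
dropDuplicateStems <- function(st, prefix) {
  dup <- paste0(prefix, c("_b3a2_conv", "_b3a2_bn", "_dbl_a2_conv",
                          "_dbl_a2_bn", "_dbl_b2_conv", "_dbl_b2_bn"))
  keep <- vapply(st$layers, function(l) !(l$name %in% dup), logical(1))
  st$layers <- st$layers[keep]
  invisible(st)
}
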