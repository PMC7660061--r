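test_that("projection profiles are exact row/column luma means", {
  # constant image: every entry equals the constant gray level
  img <- array(128 / 255, c(4, 6, 3))
  p <- projectionProfiles(img)
  expect_equal(p$rowProfile, rep(128, 4))
  expect_equal(p$colProfile, rep(128, 6))

  # block image: direct column means
  img <- array(0, c(6, 6, 3))
  img[, 3:6, ] <- 200 / 255
  p <- projectionProfiles(img)
  expect_equal(p$colProfile, c(0, 0, 200, 200, 200, 200))
  expect_equal(p$rowProfile, rep(mean(c(0, 0, 200, 200, 200, 200)), 6))

  # single pixel: both profiles are the BT.601 luma
  img <- array(c(30, 90, 150) / 255, c(1, 1, 3))
  p <- projectionProfiles(img)
  luma <- 0.299 * 30 + 0.587 * 90 + 0.114 * 150
  expect_equal(p$rowProfile, luma)
  expect_equal(p$colProfile, luma)

  expect_error(projectionProfiles(array(0, c(0, 3, 3))), "non-empty")
})

test_that("foreground bounds span the first-to-last above-threshold indices", {
  p <- structure(list(rowProfile = c(0, 150, 150, 0),
                      colProfile = c(0, 0, 200, 200, 200, 200)),
                 class = "ProjectionProfiles")
  fb <- foregroundBounds(p, 0.1)
  expect_false(fb$fallbackUsed)
  expect_equal(fb$box$left, 2)    # threshold 20: columns 3..6 exceed
  expect_equal(fb$box$right, 6)
  expect_equal(fb$box$top, 1)
  expect_equal(fb$box$bottom, 3)

  # uniform bright profiles: full frame without the fallback
  pu <- structure(list(rowProfile = rep(200, 5), colProfile = rep(200, 7)),
                  class = "ProjectionProfiles")
  fb <- foregroundBounds(pu, 0.1)
  expect_false(fb$fallbackUsed)
  expect_equal(unlist(fb$box[c("top", "bottom", "left", "right")],
                      use.names = FALSE), c(0, 5, 0, 7))

  # all-zero profiles: full frame via the fallback
  pz <- structure(list(rowProfile = rep(0, 5), colProfile = rep(0, 7)),
                  class = "ProjectionProfiles")
  fb <- foregroundBounds(pz, 0.1)
  expect_true(fb$fallbackUsed)
  expect_equal(fb$box$bottom, 5)
  expect_equal(fb$box$right, 7)

  expect_error(foregroundBounds(pu, 0), "thresholdFraction")
})

test_that("preprocessFrame returns the contracted shape and range", {
  fr <- generateFrame(frameSpec(64, 64, label = 0, seed = 13))
  out <- preprocessFrame(fr$image, 0.10, 48L)
  expect_equal(dim(out$image), c(48, 48, 3))
  expect_true(all(out$image >= 0 & out$image <= 1))
})

test_that("recovered crop box is within 2 px of the true dark-border interior", {
  for (seed in 1:6) {
    spec <- frameSpec(96, 96, label = 0, borderWidth = 20L, seed = seed)
    img <- generateFrame(spec)$image
    fb <- foregroundBounds(projectionProfiles(img), 0.10)
    expect_lte(abs(fb$box$top - 20), 2)
    expect_lte(abs(fb$box$left - 20), 2)
    expect_lte(abs(fb$box$bottom - 76), 2)
    expect_lte(abs(fb$box$right - 76), 2)
  }
})

test_that("cropping is idempotent on an already-cropped bright frame", {
  spec <- frameSpec(64, 64, label = 0, borderWidth = 12L, seed = 21)
  img <- generateFrame(spec)$image
  first <- foregroundBounds(projectionProfiles(img), 0.10)
  crop <- EndoEnsemble:::applyCrop(img, first$box)
  second <- foregroundBounds(projectionProfiles(crop), 0.10)
  d <- dim(crop)
  expect_equal(unlist(second$box[c("top", "bottom", "left", "right")],
                      use.names = FALSE), c(0, d[1], 0, d[2]))
})

test_that("raising the threshold never enlarges the crop box", {
  img <- generateFrame(frameSpec(80, 80, label = 0, borderWidth = 14L,
                                 seed = 31))$image
  p <- projectionProfiles(img)
  prev <- foregroundBounds(p, 0.02)$box
  for (f in c(0.05, 0.1, 0.2, 0.4, 0.6, 0.8)) {
    cur <- foregroundBounds(p, f)$box
    expect_gte(cur$top, prev$top)
    expect_gte(cur$left, prev$left)
    expect_lte(cur$bottom, prev$bottom)
    expect_lte(cur$right, prev$right)
    prev <- cur
  }
})

test_that("recovered foreground always contains the ground-truth lesion box", {
  kinds <- c("polyp", "vascular")
  for (seed in 1:8) {
    box <- cropBox(10 + seed, 26 + seed, 12, 30)
    spec <- frameSpec(64, 64, label = 1, lesionKind = kinds[1 + seed %% 2],
                      lesionBox = box, borderWidth = 8L, seed = seed)
    img <- generateFrame(spec)$image
    fb <- foregroundBounds(projectionProfiles(img), 0.10)
    expect_true(EndoEnsemble:::boxContains(fb$box, spec$lesionBox))
  }
})
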