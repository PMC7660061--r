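test_that("negative frames carry the -1 sentinel and positives their box", {
  neg <- generateFrame(frameSpec(64, 64, label = 0, seed = 3))
  expect_equal(unlist(neg$record[c("x", "y", "w", "h")], use.names = FALSE),
               rep(-1L, 4))
  pos <- generateFrame(positiveSpec())
  expect_equal(pos$record$x, 20)
  expect_equal(pos$record$y, 24)
  expect_equal(pos$record$w, 16)
  expect_equal(pos$record$h, 16)
})

test_that("same seed regenerates bit-identical frames, different seeds differ", {
  a <- generateFrame(frameSpec(64, 64, label = 0, seed = 7))
  b <- generateFrame(frameSpec(64, 64, label = 0, seed = 7))
  expect_identical(a$image, b$image)
  c <- generateFrame(frameSpec(64, 64, label = 0, seed = 8))
  expect_gt(sum(a$image != c$image), 0)
})

test_that("border band is dark and interior matches the foreground level", {
  spec <- frameSpec(96, 96, label = 0, borderWidth = 20L,
                    foregroundMean = 180, foregroundNoiseSd = 12, seed = 9)
  img <- generateFrame(spec)$image
  g <- EndoEnsemble:::grayLevels(img)
  border <- g
  border[21:76, 21:76] <- NA
  expect_lt(mean(border, na.rm = TRUE), 15)
  interior <- g[21:76, 21:76]
  expect_gte(mean(interior), 180 - 3 * 12)
  expect_lte(mean(interior), 180 + 3 * 12)
})

test_that("frame spec invariants are enforced by name", {
  expect_error(frameSpec(64, 64, label = 1, lesionKind = "none", seed = 1),
               "label = 1 iff lesionKind")
  expect_error(frameSpec(64, 64, label = 0, lesionKind = "polyp",
                         lesionBox = cropBox(20, 30, 20, 30), seed = 1),
               "label = 1 iff lesionKind")
  expect_error(frameSpec(64, 64, label = 1, lesionKind = "polyp",
                         lesionBox = cropBox(0, 30, 20, 30), seed = 1),
               "strictly inside")
  expect_error(frameSpec(64, 64, label = 0, borderWidth = 40, seed = 1),
               "borderWidth")
})

test_that("dataset generation conserves counts and is byte-deterministic", {
  d1 <- file.path(tempdir(), "ds-det-1")
  d2 <- file.path(tempdir(), "ds-det-2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generateDataset(3, 5, 0.5, seed = 42, outDir = d1)
  m2 <- generateDataset(3, 5, 0.5, seed = 42, outDir = d2)
  expect_equal(m1$total, 15)
  perSeq <- vapply(m1$sequences, `[[`, numeric(1), "frames")
  expect_equal(sum(perSeq), m1$total)
  for (s in sprintf("seq_%02d", 1:3)) {
    f1 <- file.path(d1, s, "annotations.tsv")
    f2 <- file.path(d2, s, "annotations.tsv")
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
  ds <- loadDataset(d1)
  expect_equal(nrow(ds$frames), 15)
  expect_equal(sum(ds$frames$label),
               sum(vapply(m1$sequences, `[[`, numeric(1), "positives")))
})

test_that("positive fraction is respected within binomial sampling error", {
  d <- file.path(tempdir(), "ds-frac")
  unlink(d, recursive = TRUE)
  generateDataset(5, 40, 0.5, seed = 77, outDir = d)
  k <- sum(loadDataset(d)$frames$label)
  # 200 Bernoulli(0.5) draws: 3 sigma is ~21 frames around 100
  expect_gte(k, 100 - 22)
  expect_lte(k, 100 + 22)
})

test_that("degenerate positive fraction makes every record positive", {
  d <- file.path(tempdir(), "ds-allpos")
  unlink(d, recursive = TRUE)
  generateDataset(2, 10, 1.0, seed = 3, outDir = d)
  ds <- loadDataset(d)
  expect_true(all(ds$frames$label == 1))
  expect_true(all(ds$frames$w >= 1 & ds$frames$h >= 1))
})

test_that("fold splits are patient-disjoint, complementary and exchanged", {
  ids <- sprintf("s%02d", 1:10)
  folds <- makeFoldSplits(ids)
  f1 <- folds[[1]]; f2 <- folds[[2]]
  expect_equal(f1$trainSequences, ids[1:5])
  expect_equal(f1$testSequences, ids[6:10])
  expect_equal(f2$trainSequences, f1$testSequences)
  expect_equal(f2$testSequences, f1$trainSequences)
  for (f in folds) {
    expect_length(intersect(f$trainSequences, f$testSequences), 0)
    expect_setequal(c(f$trainSequences, f$testSequences), ids)
  }
  two <- makeFoldSplits(c("A", "B"))
  expect_equal(two[[1]]$trainSequences, "A")
  expect_equal(two[[1]]$testSequences, "B")
  expect_error(makeFoldSplits("only"), "at least 2")
})

test_that("annotation round-trip preserves records and rejects mixed rows", {
  dir <- smallDatasetDir()
  ann <- readAnnotations(file.path(dir, "seq_01", "annotations.tsv"))
  expect_true(all(ann$label %in% c(0, 1)))
  bad <- tempfile(fileext = ".tsv")
  writeLines("f1\t5\t-1\t3\t3", bad)
  expect_error(readAnnotations(bad), "invariant")
})
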